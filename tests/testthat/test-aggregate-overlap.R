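test_that("background subtraction makes segmentation offset-invariant", {
  base <- matrix(50, 64, 64)
  blobs <- matrix(0, 64, 64)
  for (ctr in list(c(15, 15), c(40, 25), c(25, 50))) {
    blobs[disc_matrix(64, ctr[1], ctr[2], 4)] <- 150
  }
  ch1 <- make_channel(base + blobs)
  ch2 <- make_channel(base + blobs + 40)
  m1 <- segment_structures(ch1, sigma = 1, background_sigma = 20)
  m2 <- segment_structures(ch2, sigma = 1, background_sigma = 20)
  expect_equal(m1$pixels, m2$pixels)
  expect_gt(sum(m1$pixels), 0)
})

test_that("background subtraction suppresses a gradient background", {
  grad <- matrix(rep(seq(20, 180, length.out = 64), each = 64), 64, 64)
  blob <- disc_matrix(64, 32, 20, 5)
  px <- pmin(grad + blob * 70, 255)
  ch <- make_channel(px)
  plain <- segment_structures(ch, sigma = 1)
  corrected <- segment_structures(ch, sigma = 1, background_sigma = 15)
  blob_box <- matrix(FALSE, 64, 64); blob_box[24:40, 12:28] <- TRUE
  # naive threshold captures the bright gradient side far from the blob
  expect_gt(sum(plain$pixels & !blob_box), 0)
  # corrected mask concentrates on the blob
  expect_true(all(which(corrected$pixels) %in% which(blob_box)))
  expect_gt(sum(corrected$pixels & blob_box), 20)
})

test_that("without blur or background term segment_structures is binarize", {
  set.seed(5)
  px <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  ch <- make_channel(px)
  a <- segment_structures(ch, sigma = 0, threshold_method = "absolute",
                          absolute_threshold = 120)
  b <- binarize(ch, sigma = 0, method = "absolute",
                absolute_threshold = 120)
  expect_equal(a$pixels, b$pixels)
})

test_that("ROI restriction keeps exactly the objects planted inside", {
  px <- matrix(FALSE, 100, 100)
  centers <- expand.grid(r = seq(10, 90, by = 16), c = seq(10, 90, by = 16))
  for (i in seq_len(nrow(centers)))
    px[centers$r[i] + (-1:1), centers$c[i] + (-1:1)] <- TRUE
  lab <- label_components(binary_mask(px), 8L)
  inside <- centers$r <= 50 & centers$c <= 50

  roi_px <- matrix(FALSE, 100, 100); roi_px[1:52, 1:52] <- TRUE
  kept <- restrict_to_roi(lab, roi_mask(roi_px), "centroid")
  expect_equal(kept$n, sum(inside))
  expect_equal(attr(kept, "n_removed"), sum(!inside))

  full <- restrict_to_roi(lab, roi_mask(matrix(TRUE, 100, 100)))
  expect_equal(full$labels, lab$labels)
  empty <- restrict_to_roi(lab, roi_mask(matrix(FALSE, 100, 100)))
  expect_equal(empty$n, 0L)

  expect_error(restrict_to_roi(lab, roi_mask(matrix(TRUE, 10, 10))),
               class = "eq_dim_mismatch")
})

test_that("overlap statistics: subset, disjoint and empty cases", {
  agg <- matrix(FALSE, 64, 64)
  agg[disc_matrix(64, 20, 20, 4)] <- TRUE
  agg[disc_matrix(64, 45, 45, 5)] <- TRUE
  golgi_all <- matrix(TRUE, 64, 64)
  roi <- roi_mask(matrix(TRUE, 64, 64))

  sub <- overlap_area_stats(binary_mask(agg), binary_mask(golgi_all), roi,
                            0.1, "sub")
  expect_equal(sub$n_aggregates, 2L)
  expect_equal(sub$overlap_frequency, 1.0)
  expect_equal(sum(sub$overlap_areas_um2), sum(agg) * 0.01)

  disj <- overlap_area_stats(binary_mask(agg),
                             binary_mask(matrix(FALSE, 64, 64)), roi,
                             0.1, "disj")
  expect_equal(disj$overlap_frequency, 0.0)

  none <- overlap_area_stats(binary_mask(matrix(FALSE, 64, 64)),
                             binary_mask(golgi_all), roi, 0.1, "none")
  expect_equal(none$n_aggregates, 0L)
  expect_true(none$undefined_frequency)
  expect_true(is.na(none$overlap_frequency))
})

test_that("overlap area is bounded by both mask areas within the ROI", {
  set.seed(77)
  for (rep in 1:100) {
    a <- matrix(runif(64 * 64) < runif(1, 0.05, 0.4), 64, 64)
    g <- matrix(runif(64 * 64) < runif(1, 0.05, 0.4), 64, 64)
    roi_px <- matrix(FALSE, 64, 64)
    r0 <- sample(1:32, 1); c0 <- sample(1:32, 1)
    roi_px[r0:(r0 + 31), c0:(c0 + 31)] <- TRUE
    st <- overlap_area_stats(binary_mask(a), binary_mask(g),
                             roi_mask(roi_px), 1, "rand")
    total_overlap <- sum(st$overlap_areas_um2)
    expect_lte(total_overlap, sum(a))
    expect_lte(total_overlap, sum(g))
  }
})

test_that("genotype comparison mirrors the frequency-ratio construction", {
  mk <- function(freq, n = 100L, size = 2) structure(
    list(genotype = "x", n_aggregates = n, mean_area_um2 = size,
         sd_area_um2 = 0.5, n_overlapping = round(freq * n),
         overlap_frequency = freq, undefined_frequency = FALSE,
         overlap_areas_um2 = numeric(0)),
    class = "AggregateStats")
  same <- compare_genotypes(mk(0.4), mk(0.4))
  expect_equal(same$frequency_ratio, 1.0)
  expect_equal(same$size_ratio, 1.0)
  expect_equal(same$count_ratio, 1.0)

  seven <- compare_genotypes(mk(0.7), mk(0.1))
  expect_equal(seven$frequency_ratio, 7.0)

  inf <- compare_genotypes(mk(0.5), mk(0))
  expect_true(inf$infinite_frequency_ratio)
  expect_equal(inf$frequency_ratio, Inf)
})

test_that("polygon ROI files rasterize to the enclosed region", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 10", "10 40", "40 40", "40 10"), path)
  roi <- read_roi(path, dim = c(64, 64))
  expect_equal(roi$source, "polygon-file")
  expect_true(all(roi$pixels[15:35, 15:35]))
  expect_false(any(roi$pixels[45:64, ]))
  # area close to the 30x30 square
  expect_lt(abs(sum(roi$pixels) - 900), 70)
})
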