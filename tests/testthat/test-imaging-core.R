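test_that("TIFF round trip preserves pixels and channel mapping", {
  set.seed(101)
  px1 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  px2 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(list(make_channel(px1, "Arm"), make_channel(px2, "GM130")),
              path)
  chans <- read_image(path, c(Arm = 1, GM130 = 2), pixel_size_um = 0.2)
  expect_named(chans, c("Arm", "GM130"))
  expect_equal(chans$Arm$pixels, px1, ignore_attr = TRUE)
  expect_equal(chans$GM130$pixels, px2, ignore_attr = TRUE)
  expect_equal(chans$Arm$pixel_size_um, 0.2)

  # 16-bit round trip
  px16 <- matrix(sample(0:65535, 32 * 32, TRUE), 32, 32)
  path16 <- withr::local_tempfile(fileext = ".tif")
  write_image(image_channel(px16, "deep", 0.1, 16L), path16)
  back <- read_image(path16, c(deep = 1), 0.1)
  expect_equal(back$deep$pixels, px16, ignore_attr = TRUE)
  expect_equal(back$deep$bit_depth, 16L)

  expect_error(read_image(path, c(X = 5), 0.2), class = "eq_channel_index")
  expect_error(read_image("no/such/file.tif", c(A = 1), 0.2),
               class = "eq_io_error")
})

test_that("binarize thresholds strictly and records provenance", {
  px <- matrix(0, 32, 32)
  px[10:14, 10:14] <- 200
  m <- binarize(make_channel(px), sigma = 0, method = "absolute",
                absolute_threshold = 100)
  expect_equal(sum(m$pixels), 25)
  expect_true(all(which(m$pixels) ==
                    which(px > 100)))
  expect_match(m$provenance, "threshold=100")

  # ties at the threshold are background
  tie <- binarize(make_channel(px), sigma = 0, method = "absolute",
                  absolute_threshold = 200)
  expect_equal(sum(tie$pixels), 0)

  expect_error(binarize(make_channel(matrix(0, 32, 32)), method = "otsu"),
               class = "eq_degenerate_threshold")
})

test_that("Otsu matches an exhaustive between-class-variance search", {
  set.seed(7)
  for (rep in 1:5) {
    lo <- sample(20:60, 1); hi <- sample(180:240, 1)
    px <- matrix(c(pmax(round(rnorm(512, lo, 8)), 0),
                   pmin(round(rnorm(512, hi, 8)), 255)), 32, 32)
    got <- binarize(make_channel(px), sigma = 0, method = "otsu")
    expect_equal(got$pixels, exhaustive_otsu_mask(px),
                 info = sprintf("modes %d/%d", lo, hi))
    expect_equal(sum(got$pixels), 512)
  }
})

test_that("raising an absolute threshold never adds foreground", {
  set.seed(11)
  px <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  ch <- make_channel(px)
  prev <- binarize(ch, sigma = 1, method = "absolute",
                   absolute_threshold = 0)$pixels
  for (t in c(40, 90, 150, 220)) {
    cur <- binarize(ch, sigma = 1, method = "absolute",
                    absolute_threshold = t)$pixels
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("component labeling honours connectivity and matches flood fill", {
  z <- matrix(FALSE, 5, 5); z[2, 2] <- TRUE; z[3, 3] <- TRUE
  expect_equal(label_components(binary_mask(z), 4L)$n, 2L)
  expect_equal(label_components(binary_mask(z), 8L)$n, 1L)
  expect_equal(label_components(binary_mask(matrix(FALSE, 8, 8)), 8L)$n, 0L)

  set.seed(23)
  for (rep in 1:30) {
    m <- matrix(runif(24 * 24) < runif(1, 0.2, 0.7), 24, 24)
    for (conn in c(4L, 8L)) {
      got <- label_components(binary_mask(m), conn)
      oracle <- flood_fill_label(m, conn)
      expect_equal(got$n, max(oracle))
      expect_true(same_partition(got$labels, oracle))
    }
  }
})

test_that("region properties: areas, bboxes, circularity ordering", {
  px <- matrix(FALSE, 32, 32); px[3:12, 5:14] <- TRUE
  lab <- label_components(binary_mask(px), 8L)
  rp <- region_properties(lab, 0.2)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$area_px, 100L)
  expect_equal(rp$area_um2, 4.0)  # 100 * 0.2^2
  expect_equal(c(rp$min_row, rp$min_col, rp$max_row, rp$max_col),
               c(3L, 5L, 12L, 14L))
  expect_false(rp$touches_border)
  expect_equal(c(rp$centroid_r, rp$centroid_c), c(7.5, 9.5))

  corner <- matrix(FALSE, 20, 20); corner[1:4, 1:4] <- TRUE
  expect_true(region_properties(label_components(binary_mask(corner), 8L),
                                1)$touches_border)

  # disc vs elongated bar of comparable area
  disc <- disc_matrix(40, 20, 20, 15)
  bar <- matrix(FALSE, 70, 70); bar[30:32, 5:64] <- TRUE
  circ_disc <- region_properties(label_components(binary_mask(disc), 8L),
                                 1)$circularity
  circ_bar <- region_properties(label_components(binary_mask(bar), 8L),
                                1)$circularity
  expect_gte(circ_disc, 0.85)
  expect_lte(circ_disc, 1.0)
  expect_gt(circ_disc, circ_bar)

  expect_error(region_properties(lab, 0), class = "eq_calibration_error")
})

test_that("region areas conserve the mask pixel count", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(runif(32 * 32) < 0.4, 32, 32)
    lab <- label_components(binary_mask(m), sample(c(4L, 8L), 1))
    expect_equal(sum(region_properties(lab, 1)$area_px), sum(m))
  }
})

test_that("disc circularity beats high-aspect bars across radii", {
  for (radius in c(5, 8, 12)) {
    disc <- disc_matrix(2 * radius + 6, radius + 3, radius + 3, radius)
    area <- sum(disc)
    w <- max(2L, round(sqrt(area / 5)))  # aspect ratio ~5
    len <- ceiling(area / w)
    bar <- matrix(FALSE, w + 10, len + 10)
    bar[6:(5 + w), 6:(5 + len)] <- TRUE
    cd <- region_properties(label_components(binary_mask(disc), 8L),
                            1)$circularity
    cb <- region_properties(label_components(binary_mask(bar), 8L),
                            1)$circularity
    expect_gt(cd, cb)
  }
})
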