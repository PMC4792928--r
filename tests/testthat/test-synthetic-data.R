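test_that("every generator is bit-identical under a fixed seed", {
  e1 <- generate_epithelium(n_cells = 36, image_size = 200, seed = 4)
  e2 <- generate_epithelium(n_cells = 36, image_size = 200, seed = 4)
  expect_identical(e1$channel$pixels, e2$channel$pixels)
  expect_identical(e1$truth$planted$labels, e2$truth$planted$labels)

  p1 <- generate_puncta_field(n_ref = 50, n_other = 50, image_size = 300,
                              coloc_fraction = 0.4, seed = 8)
  p2 <- generate_puncta_field(n_ref = 50, n_other = 50, image_size = 300,
                              coloc_fraction = 0.4, seed = 8)
  expect_identical(p1$ref$pixels, p2$ref$pixels)
  expect_identical(p1$other$pixels, p2$other$pixels)

  a1 <- generate_aggregate_scene(n_aggregates = 30, n_golgi = 35,
                                 image_size = 300, seed = 8)
  a2 <- generate_aggregate_scene(n_aggregates = 30, n_golgi = 35,
                                 image_size = 300, seed = 8)
  expect_identical(a1$aggregate$pixels, a2$aggregate$pixels)

  f1 <- generate_membrane_profiles(seed = 8)
  f2 <- generate_membrane_profiles(seed = 8)
  expect_identical(f1$profiles[["t8_c3"]]$decad,
                   f2$profiles[["t8_c3"]]$decad)
})

test_that("epithelium truth: honeycomb degrees, symmetry, jittered degrees", {
  hc <- generate_epithelium(n_cells = 49, image_size = 240, jitter = 0,
                            seed = 2)
  tp <- hc$truth$planted
  interior <- setdiff(seq_len(tp$n_cells), tp$edge_labels)
  expect_gt(length(interior), 5)
  expect_true(all(vapply(tp$adjacency[interior], length, integer(1)) == 6L))

  vor <- generate_epithelium(n_cells = 200, image_size = 380, jitter = 0.5,
                             seed = 1)
  tpv <- vor$truth$planted
  for (lab in seq_len(tpv$n_cells)) {
    for (nb in tpv$adjacency[[lab]]) {
      expect_true(lab %in% tpv$adjacency[[nb]])
      expect_true(nb != lab)
    }
  }
  intv <- setdiff(seq_len(tpv$n_cells), tpv$edge_labels)
  mean_deg <- mean(vapply(tpv$adjacency[intv], length, integer(1)))
  expect_gte(mean_deg, 5.5); expect_lte(mean_deg, 6.5)
  # planted areas cover the frame
  expect_equal(sum(tpv$areas_px), 380L * 380L)

  expect_error(generate_epithelium(n_cells = 5000, image_size = 100),
               class = "eq_capacity_error")
})

test_that("puncta truth: partner bookkeeping and separation guarantees", {
  full <- generate_puncta_field(n_ref = 40, n_other = 40,
                                coloc_fraction = 1, image_size = 300,
                                seed = 6)
  expect_true(all(full$truth$planted$has_partner))
  expect_equal(full$truth$planted$n_coloc, 40L)

  none <- generate_puncta_field(n_ref = 40, n_other = 40,
                                coloc_fraction = 0, image_size = 300,
                                seed = 6)
  tp <- none$truth$planted
  ref_mask <- epiquant:::disc_mask(300, tp$ref_centers, tp$ref_radii)
  oth_mask <- epiquant:::disc_mask(300, tp$other_centers, tp$other_radii)
  expect_equal(sum(ref_mask & oth_mask), 0L)

  quarter <- generate_puncta_field(n_ref = 400, n_other = 400,
                                   coloc_fraction = 0.25, image_size = 900,
                                   seed = 12)
  expect_equal(quarter$truth$planted$n_coloc, 100L)

  expect_error(generate_puncta_field(n_ref = 500, n_other = 500,
                                     coloc_fraction = 0, image_size = 120),
               class = "eq_capacity_error")
})

test_that("aggregate truth: planted overlaps and ROI geometry", {
  all_ov <- generate_aggregate_scene(n_aggregates = 30, n_golgi = 30,
                                     overlap_frequency = 1,
                                     image_size = 360, seed = 9)
  tp <- all_ov$truth$planted
  expect_true(all(tp$overlapping))
  # planted partners really intersect: centre distance below radius sum
  d <- sqrt(rowSums((tp$aggregate_centers - tp$golgi_centers[1:30, ])^2))
  expect_true(all(d < tp$aggregate_radii + tp$golgi_radii[1:30]))

  full_roi <- generate_aggregate_scene(n_aggregates = 20, n_golgi = 25,
                                       roi_fraction = 1, image_size = 300,
                                       seed = 9)
  expect_true(all(full_roi$roi$pixels))

  forty <- generate_aggregate_scene(n_aggregates = 100, n_golgi = 120,
                                    overlap_frequency = 0.4, seed = 9)
  expect_equal(forty$truth$planted$n_overlap, 40L)
})

test_that("flow truth: full fronts, bookkeeping, input validation", {
  full <- generate_membrane_profiles(front_fractions = c("30" = 1),
                                     n_cells_per_timepoint = 2L,
                                     noise_sd = 0, front_jitter_sd = 0,
                                     seed = 3)
  p <- full$profiles[[1]]
  expect_true(all(signal_positive(p$decad, 0.2)))

  g <- generate_membrane_profiles(seed = 3)
  expect_length(g$profiles, 40L)
  ids <- vapply(g$profiles, function(p) p$cell_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(unique(vapply(g$profiles,
                                function(p) p$timepoint_min, numeric(1))),
                  c(1, 3, 5, 8, 12, 19, 25, 30))

  expect_error(generate_membrane_profiles(samples = 5L),
               class = "eq_invalid_params")
  expect_error(generate_membrane_profiles(front_fractions = c("1" = 1.4)),
               class = "eq_invalid_params")
})
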