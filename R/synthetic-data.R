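## Seeded synthetic-scene generators with planted ground truth. Each
## generator emulates one imaging experiment of the pipeline (junction-
## stained epithelium, two-channel puncta field, aggregate+Golgi scene with
## a clone ROI, dual-channel membrane profiles) so that every analysis
## stage can be validated by planted-parameter recovery. All generators are
## bit-identical under a fixed seed; independent scene components draw from
## deterministically derived sub-streams, so e.g. changing the number of
## non-reference puncta does not perturb the reference placement.

ground_truth <- function(scene_kind, planted, seed, noise_model) {
  structure(list(scene_kind = scene_kind, planted = planted,
                 seed = as.integer(seed), noise_model = noise_model),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("<GroundTruth '%s' (seed %d): %s>\n", x$scene_kind, x$seed,
              paste(names(x$planted), collapse = ", ")))
  invisible(x)
}

clamp_quantize <- function(px, maxval) {
  round(pmin(pmax(px, 0), maxval))
}

# Sequential placement with a minimum centre separation; error after
# bounded retries so impossible packings fail loudly.
place_points <- function(n, lo_r, hi_r, lo_c, hi_c, min_sep,
                         avoid = NULL, max_tries = 5000L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  all_pts <- avoid
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      if (is.null(all_pts) || !nrow(all_pts) ||
          min((all_pts[, 1] - cand[1])^2 + (all_pts[, 2] - cand[2])^2) >=
            min_sep^2) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      eq_stop("eq_capacity_error",
              "could not place %d objects at separation %g px (placed %d)",
              n, min_sep, placed)
    pts[i, ] <- cand
    all_pts <- rbind(all_pts, cand)
    placed <- placed + 1L
  }
  pts
}

# Render anti-aliased filled discs into an intensity image (max blending).
render_discs <- function(size, centers, radii, amplitudes) {
  img <- matrix(0, size, size)
  if (!nrow(centers)) return(img)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]; rad <- radii[k]
    rr <- max(1L, floor(r0 - rad - 2)):min(size, ceiling(r0 + rad + 2))
    cc <- max(1L, floor(c0 - rad - 2)):min(size, ceiling(c0 + rad + 2))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    v <- pmin(pmax(rad + 0.5 - d, 0), 1) * amplitudes[k]
    img[rr, cc] <- pmax(img[rr, cc], v)
  }
  img
}

# Ground-truth disc mask (pixel centre within radius of a disc centre).
disc_mask <- function(size, centers, radii) {
  m <- matrix(FALSE, size, size)
  if (!nrow(centers)) return(m)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]; rad <- radii[k]
    rr <- max(1L, floor(r0 - rad - 1)):min(size, ceiling(r0 + rad + 1))
    cc <- max(1L, floor(c0 - rad - 1)):min(size, ceiling(c0 + rad + 1))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    m[rr, cc] <- m[rr, cc] | (d2 <= rad^2)
  }
  m
}

#' Generate a junction-stained epithelial monolayer image
#'
#' Cell centres form a jittered triangular lattice; cells are the
#' nearest-centre tessellation of the frame. The junction channel renders
#' the tessellation boundaries as bright lines of the stated width (blurred
#' by 0.5 px) over a dark background with additive Gaussian noise. The
#' ground truth carries the planted label image, the cell adjacency graph
#' (4-adjacent territory contacts), per-cell pixel areas and the analytic
#' cell area of the unjittered lattice.
#'
#' @param n_cells approximate number of cells to host (>= 9); the realized
#'   count (including partial border cells) is reported in the truth.
#' @param image_size side length in pixels.
#' @param jitter centre jitter as a fraction of the lattice spacing, in
#'   `[0, 1]`; 0 gives a perfect honeycomb.
#' @param boundary_width_px junction line width in pixels (>= 1).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed integer seed; the scene is bit-identical given the seed.
#' @param pixel_size_um physical pixel size.
#' @param background,amplitude background level and boundary-line intensity.
#' @return list with elements `channel` (an [image_channel()] named
#'   `"Arm"`) and `truth` (a `GroundTruth`).
#' @export
generate_epithelium <- function(n_cells = 100L, image_size = 400L,
                                jitter = 0.3, boundary_width_px = 2L,
                                noise_sd = 8, seed = 1L,
                                pixel_size_um = 0.2, background = 10,
                                amplitude = 200) {
  stopifnot(n_cells >= 9L, jitter >= 0, jitter <= 1, boundary_width_px >= 1L,
            noise_sd >= 0)
  s <- sqrt(image_size^2 / (n_cells * sqrt(3) / 2))
  if (s < 10)
    eq_stop("eq_capacity_error",
            "%d cells in a %d px frame gives spacing %.1f px (< 10 px minimum)",
            n_cells, image_size, s)
  dy <- s * sqrt(3) / 2
  set.seed(sub_seed(seed, 1))
  rows <- seq(-dy, image_size + dy, by = dy)
  cols <- seq(-s, image_size + s, by = s)
  centers <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    cbind(rows[i], cols + off)
  }))
  centers <- centers + matrix(stats::runif(length(centers),
                                           -jitter * s / 2, jitter * s / 2),
                              nrow(centers), 2)
  # nearest-centre tessellation, windowed per centre
  best <- matrix(Inf, image_size, image_size)
  lab <- matrix(0L, image_size, image_size)
  win <- ceiling(2.5 * s)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    rr <- max(1L, floor(r0 - win)):min(image_size, ceiling(r0 + win))
    cc <- max(1L, floor(c0 - win)):min(image_size, ceiling(c0 + win))
    if (!length(rr) || !length(cc) || rr[1] > rr[length(rr)]) next
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    upd <- d2 < best[rr, cc]
    best[rr, cc][upd] <- d2[upd]
    lab[rr, cc][upd] <- k
  }
  lab <- renumber_labels(lab)
  n_real <- max(lab)
  # boundary rendering at the requested width
  right_diff <- cbind(lab[, -1] != lab[, -ncol(lab)], FALSE)
  down_diff <- rbind(lab[-1, ] != lab[-nrow(lab), ], FALSE)
  e1 <- right_diff | down_diff                       # one-sided, ~1 px
  left_diff <- cbind(FALSE, lab[, -1] != lab[, -ncol(lab)])
  up_diff <- rbind(FALSE, lab[-1, ] != lab[-nrow(lab), ])
  e2 <- e1 | left_diff | up_diff                     # both-sided, ~2 px
  w <- as.integer(boundary_width_px)
  boundary <- if (w %% 2 == 1L) e1 else e2
  extra <- (w - (if (w %% 2 == 1L) 1L else 2L)) %/% 2L
  if (extra > 0L) {
    brush <- EBImage::makeBrush(3L, "diamond")
    for (i in seq_len(extra)) boundary <- EBImage::dilate(boundary, brush) > 0
  }
  img <- background + amplitude * gaussian_smooth(boundary * 1, 0.5)
  set.seed(sub_seed(seed, 2))
  img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                      nrow(img), ncol(img))
  channel <- image_channel(clamp_quantize(img, 255), "Arm", pixel_size_um, 8L)
  adjacency <- contact_adjacency(lab, n_real, 3L)
  edge <- sort(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])))
  truth <- ground_truth(
    "epithelium",
    list(labels = lab, boundary = boundary, adjacency = adjacency,
         areas_px = tabulate(lab, nbins = n_real),
         edge_labels = as.integer(edge[edge > 0L]),
         centers = centers, spacing_px = s,
         cell_area_analytic_px = s^2 * sqrt(3) / 2,
         n_cells = n_real, jitter = jitter,
         boundary_width_px = w),
    seed, list(gaussian_sd = noise_sd))
  list(channel = channel, truth = truth)
}

#' Generate a two-channel puncta field with a planted overlap fraction
#'
#' Reference puncta are placed with a minimum mutual separation; a planted
#' subset of them (`round(coloc_fraction * n_ref)`) receives an
#' other-channel punctum at an overlapping position (centre offset at most
#' half the smaller radius, guaranteeing pixel overlap even after one
#' erosion). The remaining other-channel puncta are placed at least
#' `min_separation_px` from every reference punctum, so at
#' `coloc_fraction = 0` the two channels share no mask pixel.
#'
#' @param n_ref,n_other puncta counts per channel (`n_other` must be at
#'   least the planted partner count).
#' @param coloc_fraction planted fraction of reference puncta with an
#'   overlapping partner, in `[0, 1]`.
#' @param radius_range_px `c(min, max)` punctum radius in px.
#' @param image_size side length in pixels.
#' @param min_separation_px minimum centre separation (must exceed twice
#'   the maximum radius so that distinct puncta never share pixels).
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @param pixel_size_um physical pixel size.
#' @param background,amplitude background level and punctum peak intensity
#'   (the planted signal-to-noise ratio is `amplitude / noise_sd`).
#' @param channel_names names for the (reference, other) channels.
#' @return list with `ref`, `other` (both [image_channel()]) and `truth`;
#'   the truth records centres, radii, the planted partner flags and the
#'   planted co-localized count.
#' @export
generate_puncta_field <- function(n_ref = 500L, n_other = 500L,
                                  coloc_fraction = 0.5,
                                  radius_range_px = c(3, 6),
                                  image_size = 768L,
                                  min_separation_px = 15,
                                  noise_sd = 12, seed = 1L,
                                  pixel_size_um = 0.1,
                                  background = 15, amplitude = 180,
                                  channel_names = c("ref", "other")) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1,
            length(radius_range_px) == 2,
            radius_range_px[1] <= radius_range_px[2])
  rmax <- radius_range_px[2]
  if (min_separation_px <= 2 * rmax)
    eq_stop("eq_invalid_params",
            "min_separation_px must exceed twice the maximum radius")
  n_coloc <- round(coloc_fraction * n_ref)
  if (n_other < n_coloc)
    eq_stop("eq_invalid_params",
            "n_other (%d) below planted partner count (%d)", n_other, n_coloc)
  margin <- rmax + 3
  set.seed(sub_seed(seed, 1))
  ref_centers <- place_points(n_ref, margin, image_size - margin,
                              margin, image_size - margin, min_separation_px)
  ref_radii <- stats::runif(n_ref, radius_range_px[1], radius_range_px[2])
  set.seed(sub_seed(seed, 2))
  partner_of <- sort(sample.int(n_ref, n_coloc))
  partner_radii <- stats::runif(n_coloc, radius_range_px[1],
                                radius_range_px[2])
  ang <- stats::runif(n_coloc, 0, 2 * pi)
  mag <- stats::runif(n_coloc, 0,
                      pmin(ref_radii[partner_of], partner_radii) / 2)
  partner_centers <- ref_centers[partner_of, , drop = FALSE] +
    cbind(mag * sin(ang), mag * cos(ang))
  set.seed(sub_seed(seed, 3))
  n_free <- n_other - n_coloc
  free_centers <- place_points(n_free, margin, image_size - margin,
                               margin, image_size - margin,
                               min_separation_px,
                               avoid = rbind(ref_centers, partner_centers))
  free_radii <- stats::runif(max(n_free, 0L), radius_range_px[1],
                             radius_range_px[2])
  other_centers <- rbind(partner_centers, free_centers)
  other_radii <- c(partner_radii, free_radii)
  set.seed(sub_seed(seed, 4))
  mk_channel <- function(centers, radii, name) {
    img <- background +
      render_discs(image_size, centers, radii, rep(amplitude, nrow(centers))) +
      matrix(stats::rnorm(image_size^2, 0, noise_sd), image_size, image_size)
    image_channel(clamp_quantize(img, 255), name, pixel_size_um, 8L)
  }
  ref_ch <- mk_channel(ref_centers, ref_radii, channel_names[1])
  other_ch <- mk_channel(other_centers, other_radii, channel_names[2])
  truth <- ground_truth(
    "puncta",
    list(ref_centers = ref_centers, ref_radii = ref_radii,
         other_centers = other_centers, other_radii = other_radii,
         has_partner = seq_len(n_ref) %in% partner_of,
         n_coloc = n_coloc, coloc_fraction = coloc_fraction,
         snr = if (noise_sd > 0) amplitude / noise_sd else Inf),
    seed, list(gaussian_sd = noise_sd))
  list(ref = ref_ch, other = other_ch, truth = truth)
}

#' Generate an aggregate + Golgi scene with a clone ROI
#'
#' Protein aggregates are placed inside a centred rectangular clone ROI
#' covering `roi_fraction` of the frame; a planted subset of them
#' (`round(overlap_frequency * n_aggregates)`) receives a Golgi object at
#' an overlapping position, and the remaining Golgi objects are placed away
#' from every aggregate.
#'
#' @param n_aggregates,n_golgi object counts.
#' @param overlap_frequency planted fraction of aggregates intersecting a
#'   Golgi object, in `[0, 1]`.
#' @param roi_fraction fraction of the frame covered by the clone ROI, in
#'   `(0, 1]` (1 = full frame).
#' @param aggregate_radius_range,golgi_radius_range radius ranges in px.
#' @param image_size side length in pixels.
#' @param min_separation_px minimum centre separation between non-partner
#'   objects.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @param pixel_size_um physical pixel size.
#' @return list with `aggregate`, `golgi` (both [image_channel()]), `roi`
#'   (an [roi_mask()]) and `truth`.
#' @export
generate_aggregate_scene <- function(n_aggregates = 100L, n_golgi = 120L,
                                     overlap_frequency = 0.4,
                                     roi_fraction = 0.6,
                                     aggregate_radius_range = c(4, 9),
                                     golgi_radius_range = c(3, 6),
                                     image_size = 512L,
                                     min_separation_px = 24,
                                     noise_sd = 10, seed = 1L,
                                     pixel_size_um = 0.1) {
  stopifnot(overlap_frequency >= 0, overlap_frequency <= 1,
            roi_fraction > 0, roi_fraction <= 1)
  rmax_a <- aggregate_radius_range[2]
  rmax_g <- golgi_radius_range[2]
  if (min_separation_px <= rmax_a + rmax_g)
    eq_stop("eq_invalid_params",
            "min_separation_px must exceed the sum of the maximum radii")
  side <- round(image_size * sqrt(roi_fraction))
  lo <- floor((image_size - side) / 2) + 1L
  hi <- lo + side - 1L
  roi_px <- matrix(FALSE, image_size, image_size)
  roi_px[lo:hi, lo:hi] <- TRUE
  n_ov <- round(overlap_frequency * n_aggregates)
  if (n_golgi < n_ov)
    eq_stop("eq_invalid_params", "n_golgi below planted overlap count")
  set.seed(sub_seed(seed, 11))
  agg_centers <- place_points(n_aggregates,
                              lo + rmax_a + 1, hi - rmax_a - 1,
                              lo + rmax_a + 1, hi - rmax_a - 1,
                              min_separation_px)
  agg_radii <- stats::runif(n_aggregates, aggregate_radius_range[1],
                            aggregate_radius_range[2])
  set.seed(sub_seed(seed, 12))
  ov_idx <- sort(sample.int(n_aggregates, n_ov))
  g_ov_radii <- stats::runif(n_ov, golgi_radius_range[1],
                             golgi_radius_range[2])
  ang <- stats::runif(n_ov, 0, 2 * pi)
  mag <- stats::runif(n_ov, 0, pmin(agg_radii[ov_idx], g_ov_radii) / 2)
  g_ov_centers <- agg_centers[ov_idx, , drop = FALSE] +
    cbind(mag * sin(ang), mag * cos(ang))
  set.seed(sub_seed(seed, 13))
  margin <- rmax_g + 3
  g_free_centers <- place_points(n_golgi - n_ov, margin, image_size - margin,
                                 margin, image_size - margin,
                                 min_separation_px,
                                 avoid = rbind(agg_centers, g_ov_centers))
  g_free_radii <- stats::runif(max(n_golgi - n_ov, 0L),
                               golgi_radius_range[1], golgi_radius_range[2])
  golgi_centers <- rbind(g_ov_centers, g_free_centers)
  golgi_radii <- c(g_ov_radii, g_free_radii)
  set.seed(sub_seed(seed, 14))
  mk_channel <- function(centers, radii, name) {
    img <- 15 + render_discs(image_size, centers, radii,
                             rep(180, nrow(centers))) +
      matrix(stats::rnorm(image_size^2, 0, noise_sd), image_size, image_size)
    image_channel(clamp_quantize(img, 255), name, pixel_size_um, 8L)
  }
  agg_ch <- mk_channel(agg_centers, agg_radii, "Arm")
  golgi_ch <- mk_channel(golgi_centers, golgi_radii, "GM130")
  truth <- ground_truth(
    "aggregates",
    list(aggregate_centers = agg_centers, aggregate_radii = agg_radii,
         golgi_centers = golgi_centers, golgi_radii = golgi_radii,
         overlapping = seq_len(n_aggregates) %in% ov_idx,
         n_overlap = n_ov, overlap_frequency = overlap_frequency,
         roi = roi_px),
    seed, list(gaussian_sd = noise_sd))
  list(aggregate = agg_ch, golgi = golgi_ch,
       roi = roi_mask(roi_px, "in-memory"), truth = truth)
}

#' Generate dual-channel lateral-membrane profiles
#'
#' Emulates the cadherin-flow experiment: the junctional marker (Arm) shows
#' an apical peak with a lateral plateau, and the cadherin channel a
#' smoothed front positive basal of `(1 - front_fraction) * length_um`.
#' Per-cell front positions are perturbed by a small planted sd whose
#' realized values are recorded in the truth.
#'
#' @param front_fractions named numeric vector timepoint (min) ->
#'   planted front fraction in `[0, 1]`. The default follows the
#'   incubation design `{1, 3, 5, 8, 12, 19, 25, 30}` min with a front
#'   that reaches the mid-membrane by 8 min and the apical junction belt
#'   by 30 min.
#' @param n_cells_per_timepoint traced cells per timepoint.
#' @param length_um lateral membrane length.
#' @param samples samples per profile (>= 10).
#' @param noise_sd additive Gaussian intensity noise (channel max is ~1, so
#'   the planted signal-to-noise ratio is ~`1 / noise_sd`).
#' @param front_jitter_sd per-cell front perturbation, in fraction units.
#' @param seed integer seed.
#' @return list with `profiles` (list of [membrane_profile()]) and `truth`
#'   (records the design and the realized per-cell front fractions).
#' @export
generate_membrane_profiles <- function(
    front_fractions = c("1" = 0.18, "3" = 0.25, "5" = 0.34, "8" = 0.50,
                        "12" = 0.65, "19" = 0.80, "25" = 0.92, "30" = 1.00),
    n_cells_per_timepoint = 5L, length_um = 15, samples = 150L,
    noise_sd = 0.05, front_jitter_sd = 0.01, seed = 1L) {
  if (samples < 10L)
    eq_stop("eq_invalid_params", "need at least 10 samples per profile")
  if (any(front_fractions < 0 | front_fractions > 1))
    eq_stop("eq_invalid_params", "front fractions must lie in [0, 1]")
  if (is.null(names(front_fractions)))
    eq_stop("eq_invalid_params", "front_fractions must be named by timepoint")
  set.seed(sub_seed(seed, 21))
  x <- seq(0, length_um, length.out = samples)
  w <- 2 * length_um / samples
  profiles <- list()
  realized <- data.frame(cell_id = character(0), timepoint_min = numeric(0),
                         fraction = numeric(0))
  for (tp in names(front_fractions)) {
    f <- front_fractions[[tp]]
    for (ci in seq_len(n_cells_per_timepoint)) {
      f_cell <- min(max(f + stats::rnorm(1, 0, front_jitter_sd), 0), 1)
      x0 <- (1 - f_cell) * length_um
      arm <- 0.7 * exp(-(x / (0.1 * length_um))^2) + 0.35 +
        stats::rnorm(samples, 0, noise_sd)
      decad <- 1 / (1 + exp(-(x - x0) / w)) + stats::rnorm(samples, 0, noise_sd)
      id <- sprintf("t%s_c%d", tp, ci)
      profiles[[id]] <- membrane_profile(x, pmax(arm, 0), pmax(decad, 0),
                                         id, as.numeric(tp))
      realized <- rbind(realized,
                        data.frame(cell_id = id,
                                   timepoint_min = as.numeric(tp),
                                   fraction = f_cell))
    }
  }
  truth <- ground_truth(
    "flow",
    list(design = front_fractions, realized = realized,
         length_um = length_um, samples = samples,
         snr = if (noise_sd > 0) 1 / noise_sd else Inf),
    seed, list(gaussian_sd = noise_sd))
  list(profiles = profiles, truth = truth)
}
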