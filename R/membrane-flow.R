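## Lateral-membrane cadherin flow: from paired junctional-marker (Arm) and
## cadherin (DE-cad) intensity profiles traced along the lateral membrane,
## measure the total lateral membrane length (most apical Arm signal to most
## basal DE-cad signal), the extent of DE-cad signal along it, and the
## percentage; assemble the incubation time-course table.

#' Construct a lateral-membrane intensity profile
#'
#' @param positions_um strictly increasing arc-length samples (micrometres)
#'   from the apical end (0) towards basal.
#' @param arm,decad intensity vectors sampled at `positions_um` for the
#'   junctional marker and the cadherin channel.
#' @param cell_id text identifier of the traced cell.
#' @param timepoint_min incubation time in minutes (>= 0).
#' @return object of class `MembraneProfile`.
#' @export
membrane_profile <- function(positions_um, arm, decad, cell_id,
                             timepoint_min = 0) {
  n <- length(positions_um)
  if (length(arm) != n || length(decad) != n)
    eq_stop("eq_invalid_profile",
            "profile '%s': sample vectors differ in length", cell_id)
  if (n < 2L || any(diff(positions_um) <= 0))
    eq_stop("eq_invalid_profile",
            "profile '%s': positions must be strictly increasing", cell_id)
  if (timepoint_min < 0)
    eq_stop("eq_invalid_profile", "timepoint_min must be >= 0")
  structure(list(positions_um = as.numeric(positions_um),
                 arm = as.numeric(arm), decad = as.numeric(decad),
                 cell_id = as.character(cell_id),
                 timepoint_min = as.numeric(timepoint_min)),
            class = "MembraneProfile")
}

#' Threshold a profile into signal-positive positions
#'
#' A position is signal-positive when its intensity strictly exceeds
#' `threshold_fraction` times the profile's maximum. The per-profile maximum
#' makes the rule invariant to uniform intensity scaling.
#'
#' @param intensity numeric vector with a positive maximum.
#' @param threshold_fraction number in (0, 1); default 0.2.
#' @return logical vector.
#' @export
signal_positive <- function(intensity, threshold_fraction = 0.2) {
  if (!is_scalar_num(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    eq_stop("eq_invalid_params", "threshold_fraction must lie in (0, 1)")
  m <- max(intensity)
  if (!is.finite(m) || m <= 0)
    eq_stop("eq_zero_profile", "profile has no positive intensity")
  intensity > threshold_fraction * m
}

#' Measure membrane length and cadherin extent for one profile
#'
#' The total lateral membrane length is the distance from the most apical
#' Arm-positive position to the most basal DE-cad-positive position. The
#' DE-cad extent is, by default, the span from the most apical to the most
#' basal DE-cad-positive position (the front-span convention: the signal is
#' interpreted as a front advancing apically); `extent_mode = "summed"`
#' instead sums the lengths of all positive stretches.
#'
#' Intensities are smoothed with a centred running mean of
#' `smooth_window` samples before thresholding, so single noise spikes do
#' not masquerade as signal boundaries; set `smooth_window = 1` for the raw
#' threshold rule.
#'
#' @param profile a [membrane_profile()].
#' @param threshold_fraction positivity threshold (see [signal_positive()]).
#' @param extent_mode `"front"` (default) or `"summed"`.
#' @param smooth_window odd number of samples for the pre-threshold running
#'   mean (default 5).
#' @param min_run minimum number of consecutive positive samples for a
#'   stretch to count as signal (default 3); together with the smoothing
#'   this keeps isolated noise excursions from defining the signal
#'   boundaries. Set both to 1 for the raw threshold rule.
#' @return one-row data.frame: `cell_id`, `timepoint_min`,
#'   `total_length_um`, `decad_extent_um`, `percent` (clamped to
#'   `[0, 100]`), `threshold_fraction`, `extent_mode`.
#' @export
measure_extent <- function(profile, threshold_fraction = 0.2,
                           extent_mode = c("front", "summed"),
                           smooth_window = 5L, min_run = 3L) {
  stopifnot(inherits(profile, "MembraneProfile"))
  extent_mode <- match.arg(extent_mode)
  pos <- profile$positions_um
  arm_pos <- drop_short_runs(
    signal_positive(running_mean(profile$arm, smooth_window),
                    threshold_fraction), min_run)
  dec_pos <- drop_short_runs(
    signal_positive(running_mean(profile$decad, smooth_window),
                    threshold_fraction), min_run)
  if (!any(arm_pos) || !any(dec_pos))
    eq_stop("eq_no_signal", "profile '%s': no positive %s samples",
            profile$cell_id, if (!any(arm_pos)) "Arm" else "DE-cad")
  apical_arm <- pos[which(arm_pos)[1]]
  basal_dec <- pos[max(which(dec_pos))]
  total <- basal_dec - apical_arm
  if (total <= 0)
    eq_stop("eq_geometry_error",
            "profile '%s': most apical Arm signal (%.3g um) lies basal of the most basal DE-cad signal (%.3g um)",
            profile$cell_id, apical_arm, basal_dec)
  extent <- if (extent_mode == "front") {
    # The front is the contiguous positive region anchored at the basal
    # end, walking apical across gaps of at most max_gap samples; positive
    # islands disconnected from the front (apical noise) are ignored.
    max_gap <- 5L
    r <- rle(dec_pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- max(which(r$values))           # basal-most positive run
    while (k > 2L && r$lengths[k - 1L] <= max_gap && r$values[k - 2L])
      k <- k - 2L
    basal_dec - pos[starts[k]]
  } else {
    # summed length of positive stretches, measured midpoint-to-midpoint
    dx <- diff(pos)
    w <- c(dx / 2, 0) + c(0, dx / 2)  # length attributed to each sample
    sum(w[dec_pos])
  }
  percent <- min(max(100 * extent / total, 0), 100)
  data.frame(cell_id = profile$cell_id,
             timepoint_min = profile$timepoint_min,
             total_length_um = total,
             decad_extent_um = extent,
             percent = percent,
             threshold_fraction = threshold_fraction,
             extent_mode = extent_mode)
}

# Remove TRUE-runs shorter than min_run from a logical vector.
drop_short_runs <- function(x, min_run = 3L) {
  if (min_run <= 1L || !any(x)) return(x)
  r <- rle(x)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# Centred running mean with shrinking windows at the profile ends.
running_mean <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Measure a list of profiles
#'
#' @param profiles list of [membrane_profile()]s.
#' @inheritParams measure_extent
#' @return data.frame of per-cell measurements (one row per profile).
#' @export
measure_profiles <- function(profiles, threshold_fraction = 0.2,
                             extent_mode = "front", smooth_window = 5L) {
  out <- do.call(rbind, lapply(profiles, measure_extent,
                               threshold_fraction = threshold_fraction,
                               extent_mode = extent_mode,
                               smooth_window = smooth_window))
  rownames(out) <- NULL
  out
}

#' Time-course table of cadherin extent
#'
#' Groups per-cell measurements by incubation timepoint and reports the
#' mean, sample standard deviation and cell count of the extent percentage,
#' sorted by time. With a single cell at a timepoint the sd is reported as
#' 0 and flagged via `n_cells = 1`.
#'
#' @param measurements data.frame from [measure_extent()] /
#'   [measure_profiles()] (needs columns `timepoint_min`, `percent`,
#'   `cell_id`).
#' @return data.frame with columns `timepoint_min`, `mean_percent`,
#'   `sd_percent`, `n_cells`.
#' @export
kinetics_table <- function(measurements) {
  stopifnot(all(c("timepoint_min", "percent", "cell_id") %in%
                  names(measurements)))
  dup <- duplicated(measurements[, c("timepoint_min", "cell_id")])
  if (any(dup))
    eq_stop("eq_invalid_params",
            "duplicate measurement for cell '%s' at t=%g min",
            measurements$cell_id[dup][1], measurements$timepoint_min[dup][1])
  grp <- split(measurements$percent, measurements$timepoint_min)
  out <- data.frame(
    timepoint_min = as.numeric(names(grp)),
    mean_percent = vapply(grp, mean, numeric(1)),
    sd_percent = vapply(grp, sd0, numeric(1)),
    n_cells = vapply(grp, length, integer(1))
  )
  out <- out[order(out$timepoint_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read traced membrane profiles from CSV
#'
#' Expected columns: `cell_id`, `timepoint_min`, `position_um`, `arm`,
#' `decad`; one row per sample, samples of one cell contiguous or not.
#'
#' @param path CSV file path.
#' @param reverse set `TRUE` when traces were recorded basal-to-apical; the
#'   positions are then mirrored so 0 is apical.
#' @return list of [membrane_profile()]s.
#' @export
read_profiles <- function(path, reverse = FALSE) {
  if (!file.exists(path)) eq_stop("eq_io_error", "profile file not found: %s",
                                  path)
  df <- utils::read.csv(path)
  need <- c("cell_id", "timepoint_min", "position_um", "arm", "decad")
  if (!all(need %in% names(df)))
    eq_stop("eq_io_error", "profile CSV must have columns: %s",
            paste(need, collapse = ", "))
  lapply(split(df, paste(df$cell_id, df$timepoint_min)), function(d) {
    d <- d[order(d$position_um), ]
    p <- d$position_um
    arm <- d$arm; dec <- d$decad
    if (reverse) {
      p <- max(p) - rev(p); arm <- rev(arm); dec <- rev(dec)
    }
    membrane_profile(p, arm, dec, d$cell_id[1], d$timepoint_min[1])
  })
}

#' Sample a channel along a traced polyline
#'
#' Helper for extracting a 1D membrane profile from a 2D image: the polyline
#' is resampled at 1-pixel arc-length steps and intensities are read with
#' bilinear interpolation.
#'
#' @param channel an [image_channel()].
#' @param polyline matrix of `(row, col)` vertices (>= 2).
#' @return data.frame with `position_um` and `intensity`.
#' @export
sample_profile <- function(channel, polyline) {
  stopifnot(inherits(channel, "ImageChannel"),
            is.matrix(polyline), ncol(polyline) == 2, nrow(polyline) >= 2)
  seg <- sqrt(rowSums(diff(polyline)^2))
  total <- sum(seg)
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg))
  pts <- t(vapply(s, function(si) {
    i <- max(which(cum <= si + 1e-9)); i <- min(i, nrow(polyline) - 1L)
    t0 <- (si - cum[i]) / seg[i]
    polyline[i, ] + t0 * (polyline[i + 1L, ] - polyline[i, ])
  }, numeric(2)))
  px <- channel$pixels
  nr <- nrow(px); nc <- ncol(px)
  bilinear <- function(r, c) {
    r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
    c0 <- pmin(pmax(floor(c), 1L), nc - 1L)
    fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
    px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      px[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
      px[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
      px[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  }
  data.frame(position_um = s * channel$pixel_size_um,
             intensity = bilinear(pts[, 1], pts[, 2]))
}
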