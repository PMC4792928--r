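## Aggregate-Golgi overlap quantification: segment intracellular protein
## aggregates and Golgi objects per channel (with optional large-scale
## background reduction), restrict the analysis to a mutant-clone region of
## interest, and measure per-genotype aggregate statistics: count, size and
## the frequency with which aggregates overlap the Golgi.

#' Region-of-interest mask
#'
#' Marks the mutant-clone region to which the analysis is restricted. In
#' the original workflow objects in wild-type cells were removed by hand;
#' here the clone region is an explicit, reproducible input.
#'
#' @param pixels logical matrix (`TRUE` = inside the clone).
#' @param source `"mask-file"`, `"polygon-file"` or `"in-memory"`.
#' @return object of class `RoiMask`.
#' @export
roi_mask <- function(pixels, source = "in-memory") {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, source = source), class = "RoiMask")
}

# Even-odd scanline rasterization of a closed polygon given as a matrix of
# (row, col) vertices. Pixel centers at integer coordinates.
rasterize_polygon <- function(vertices, nrow_img, ncol_img) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  vr <- vertices[, 1]; vc <- vertices[, 2]
  k <- nrow(vertices)
  out <- matrix(FALSE, nrow_img, ncol_img)
  for (r in seq_len(nrow_img)) {
    xs <- numeric(0)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      r1 <- vr[i]; r2 <- vr[j]
      if ((r1 <= r && r2 > r) || (r2 <= r && r1 > r)) {
        t <- (r - r1) / (r2 - r1)
        xs <- c(xs, vc[i] + t * (vc[j] - vc[i]))
      }
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      for (p in seq(1, length(xs) - 1, by = 2)) {
        c1 <- max(1L, ceiling(xs[p])); c2 <- min(ncol_img, floor(xs[p + 1]))
        if (c1 <= c2) out[r, c1:c2] <- TRUE
      }
    }
  }
  out
}

#' Read a region-of-interest file
#'
#' Accepts either a label/mask TIFF (non-zero = inside the clone) or a
#' plain-text polygon file with one `row col` vertex pair per line (the
#' polygon is closed implicitly and rasterized with even-odd filling).
#'
#' @param path path to the ROI file.
#' @param dim target image dimensions `c(nrow, ncol)`; required for polygon
#'   files, and validated against mask files when given.
#' @return an [roi_mask()].
#' @export
read_roi <- function(path, dim = NULL) {
  if (!file.exists(path)) eq_stop("eq_io_error", "ROI file not found: %s", path)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(base::dim(px)) == 3L) px <- px[, , 1]
    m <- px > 0
    if (!is.null(dim) && !identical(base::dim(m), as.integer(dim)))
      eq_stop("eq_dim_mismatch", "ROI mask %s does not match image dimensions",
              path)
    roi_mask(m, "mask-file")
  } else {
    if (is.null(dim))
      eq_stop("eq_invalid_params", "image dimensions required for polygon ROI")
    coords <- utils::read.table(path, col.names = c("row", "col"))
    roi_mask(rasterize_polygon(as.matrix(coords), dim[1], dim[2]),
             "polygon-file")
  }
}

#' Segment aggregate or Golgi structures in one channel
#'
#' A channel-tuned Gaussian blur followed by thresholding, with optional
#' large-scale background reduction: when `background_sigma` is set, a
#' heavily blurred copy of the image is subtracted before thresholding
#' (difference-of-Gaussians), removing smooth background and illumination
#' offsets so only blob-scale structure crosses the threshold.
#'
#' @param channel an [image_channel()].
#' @param sigma blob-scale Gaussian standard deviation (px, >= 0).
#' @param background_sigma optional background-scale standard deviation;
#'   must exceed `sigma` when set (>= 5x is sensible).
#' @param threshold_method,absolute_threshold as in [binarize()]; Otsu is
#'   applied to the background-reduced image.
#' @return a [binary_mask()].
#' @export
segment_structures <- function(channel, sigma = 1, background_sigma = NULL,
                               threshold_method = c("otsu", "absolute"),
                               absolute_threshold = NULL) {
  stopifnot(inherits(channel, "ImageChannel"))
  threshold_method <- match.arg(threshold_method)
  if (!is.null(background_sigma) && background_sigma <= sigma)
    eq_stop("eq_invalid_params", "background_sigma must exceed sigma")
  maxval <- 2^channel$bit_depth - 1
  sm <- gaussian_smooth(channel$pixels, sigma)
  prov_bg <- ""
  if (!is.null(background_sigma)) {
    bg <- gaussian_smooth(channel$pixels, background_sigma)
    sm <- pmax(sm - bg, 0)
    prov_bg <- sprintf(" background_sigma=%g", background_sigma)
  }
  if (threshold_method == "absolute") {
    if (!is_scalar_num(absolute_threshold))
      eq_stop("eq_invalid_params", "absolute_threshold required")
    thr <- absolute_threshold
  } else {
    thr <- otsu_threshold(sm, maxval)
  }
  binary_mask(sm > thr,
              sprintf("channel='%s' sigma=%g%s method=%s threshold=%.6g",
                      channel$name, sigma, prov_bg, threshold_method, thr))
}

#' Restrict labeled objects to a region of interest
#'
#' @param labeled a `LabeledImage`.
#' @param roi an [roi_mask()] with matching dimensions.
#' @param rule `"centroid"` (keep objects whose centroid pixel lies inside
#'   the ROI, the default) or `"any-pixel"` (keep objects with any pixel
#'   inside).
#' @return a `LabeledImage` containing only the kept objects, relabeled
#'   1..N; the number of removed objects is attached as attribute
#'   `"n_removed"`.
#' @export
restrict_to_roi <- function(labeled, roi, rule = c("centroid", "any-pixel")) {
  stopifnot(inherits(labeled, "LabeledImage"), inherits(roi, "RoiMask"))
  rule <- match.arg(rule)
  if (!identical(dim(labeled$labels), dim(roi$pixels)))
    eq_stop("eq_dim_mismatch", "ROI dimensions do not match labeled image")
  L <- labeled$labels
  if (labeled$n == 0L) return(labeled)
  keep <- if (rule == "any-pixel") {
    sort(unique(L[roi$pixels & L > 0L]))
  } else {
    props <- region_properties(labeled, 1)
    ri <- pmin(pmax(round(props$centroid_r), 1L), nrow(L))
    ci <- pmin(pmax(round(props$centroid_c), 1L), ncol(L))
    props$label[roi$pixels[cbind(ri, ci)]]
  }
  removed <- labeled$n - length(keep)
  L[!(L %in% keep)] <- 0L
  out <- as_labeled_image(renumber_labels(L), labeled$connectivity)
  attr(out, "n_removed") <- as.integer(removed)
  out
}

#' Aggregate-Golgi overlap statistics within a clone ROI
#'
#' Labels the aggregate mask, keeps aggregates inside the ROI (centroid
#' rule), and measures how many of them intersect the Golgi mask, the
#' overlap frequency (fraction of aggregates with at least one shared
#' pixel), aggregate size statistics and the areas of the individual
#' overlap regions.
#'
#' @param aggregate_mask,golgi_mask [binary_mask()]s of equal size.
#' @param roi an [roi_mask()]; use a full-frame ROI for unrestricted
#'   analysis.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param genotype text label for the sample.
#' @param min_area_px,max_area_px aggregate size gate in pixels.
#' @return object of class `AggregateStats`: `genotype`, `n_aggregates`,
#'   `mean_area_um2`, `sd_area_um2`, `n_overlapping`, `overlap_frequency`
#'   (`NA` with `undefined_frequency = TRUE` when no aggregates are found),
#'   `overlap_areas_um2`.
#' @export
overlap_area_stats <- function(aggregate_mask, golgi_mask, roi,
                               pixel_size_um, genotype = "",
                               min_area_px = 1L, max_area_px = Inf) {
  stopifnot(inherits(aggregate_mask, "BinaryMask"),
            inherits(golgi_mask, "BinaryMask"), inherits(roi, "RoiMask"))
  if (!identical(dim(aggregate_mask$pixels), dim(golgi_mask$pixels)) ||
      !identical(dim(aggregate_mask$pixels), dim(roi$pixels)))
    eq_stop("eq_dim_mismatch", "masks and ROI must share dimensions")
  agg <- label_components(aggregate_mask, 8L)
  if (agg$n > 0L && (min_area_px > 1L || is.finite(max_area_px))) {
    sizes <- tabulate(agg$labels[agg$labels > 0L], nbins = agg$n)
    bad <- which(sizes < min_area_px | sizes > max_area_px)
    if (length(bad)) {
      L <- agg$labels; L[L %in% bad] <- 0L
      agg <- as_labeled_image(renumber_labels(L), 8L)
    }
  }
  agg <- restrict_to_roi(agg, roi, "centroid")
  n_agg <- agg$n
  if (n_agg == 0L) {
    return(structure(
      list(genotype = genotype, n_aggregates = 0L,
           mean_area_um2 = NA_real_, sd_area_um2 = NA_real_,
           n_overlapping = 0L, overlap_frequency = NA_real_,
           undefined_frequency = TRUE, overlap_areas_um2 = numeric(0)),
      class = "AggregateStats"))
  }
  props <- region_properties(agg, pixel_size_um)
  inter <- (agg$labels > 0L) & golgi_mask$pixels
  hit <- unique(agg$labels[inter])
  hit <- hit[hit > 0L]
  ov_comp <- label_components(binary_mask(inter, "aggregate & golgi"), 8L)
  ov_areas <- if (ov_comp$n)
    tabulate(ov_comp$labels[ov_comp$labels > 0L], nbins = ov_comp$n) *
      pixel_size_um^2
  else numeric(0)
  structure(
    list(genotype = genotype, n_aggregates = n_agg,
         mean_area_um2 = mean(props$area_um2),
         sd_area_um2 = sd0(props$area_um2),
         n_overlapping = length(hit),
         overlap_frequency = length(hit) / n_agg,
         undefined_frequency = FALSE,
         overlap_areas_um2 = ov_areas),
    class = "AggregateStats"
  )
}

#' @export
print.AggregateStats <- function(x, ...) {
  if (x$n_aggregates == 0L) {
    cat(sprintf("Aggregate stats [%s]: no aggregates (frequency undefined)\n",
                x$genotype))
  } else {
    cat(sprintf(
      "Aggregate stats [%s]: n=%d, mean area %.3g um^2 (sd %.3g), %d overlap Golgi (frequency %.2f)\n",
      x$genotype, x$n_aggregates, x$mean_area_um2, x$sd_area_um2,
      x$n_overlapping, x$overlap_frequency))
  }
  invisible(x)
}

#' Compare aggregate statistics between two genotypes
#'
#' Reports the ratios (a over b) of overlap frequency, mean aggregate size
#' and aggregate count, echoing both input records. A zero denominator
#' yields an infinite-ratio flag rather than an error.
#'
#' @param a,b `AggregateStats` with `n_aggregates > 0`.
#' @return list of class `GenotypeComparison` with fields
#'   `frequency_ratio`, `size_ratio`, `count_ratio`,
#'   `infinite_frequency_ratio` and the two input records.
#' @export
compare_genotypes <- function(a, b) {
  stopifnot(inherits(a, "AggregateStats"), inherits(b, "AggregateStats"))
  if (a$n_aggregates == 0L || b$n_aggregates == 0L)
    eq_stop("eq_invalid_params",
            "both genotypes need at least one aggregate to compare")
  inf_flag <- !is.na(b$overlap_frequency) && b$overlap_frequency == 0
  structure(
    list(frequency_ratio = if (inf_flag) Inf else
           a$overlap_frequency / b$overlap_frequency,
         size_ratio = a$mean_area_um2 / b$mean_area_um2,
         count_ratio = a$n_aggregates / b$n_aggregates,
         infinite_frequency_ratio = inf_flag,
         a = a, b = b),
    class = "GenotypeComparison"
  )
}

#' @export
print.GenotypeComparison <- function(x, ...) {
  cat(sprintf(
    "Genotype comparison (%s / %s): overlap frequency x%.2f, mean size x%.2f, count x%.2f\n",
    x$a$genotype, x$b$genotype, x$frequency_ratio, x$size_ratio,
    x$count_ratio))
  invisible(x)
}
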