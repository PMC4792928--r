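## Shared image data model: channels, binary masks, labeled images and
## region properties. All downstream analysis modules build on these.
##
## Conventions: pixel grids are base R matrices indexed (row, col), 1-based,
## origin top-left. Bounding boxes are inclusive on both ends.

#' Construct an image channel
#'
#' A single fluorescence channel: a rectangular non-negative intensity grid
#' plus the metadata needed for calibrated measurements.
#'
#' @param pixels numeric matrix of intensities, at least 16 x 16.
#' @param name text label for the stain (e.g. `"Arm"`, `"DEcad"`, `"GM130"`).
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return an object of class `ImageChannel`.
#' @export
image_channel <- function(pixels, name, pixel_size_um, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    eq_stop("eq_invalid_channel", "pixels must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    eq_stop("eq_invalid_channel", "channel must be at least 16x16 (got %dx%d)",
            nrow(pixels), ncol(pixels))
  if (!bit_depth %in% c(8L, 16L))
    eq_stop("eq_invalid_channel", "bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    eq_stop("eq_invalid_channel",
            "intensities of channel '%s' outside [0, %d]", name, maxval)
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    eq_stop("eq_calibration_error", "pixel_size_um must be a positive number")
  structure(
    list(pixels = pixels, name = as.character(name),
         pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth)),
    class = "ImageChannel"
  )
}

#' @export
print.ImageChannel <- function(x, ...) {
  cat(sprintf("<ImageChannel '%s': %d x %d px, %d-bit, %.4g um/px>\n",
              x$name, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_size_um))
  invisible(x)
}

#' Construct a binary mask
#'
#' @param pixels logical matrix.
#' @param provenance free-text description of the thresholding (or other
#'   operation) that produced the mask; carried along for reporting.
#' @return an object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, provenance = "") {
  if (!is.matrix(pixels) || !is.logical(pixels))
    eq_stop("eq_invalid_mask", "mask pixels must be a logical matrix")
  structure(list(pixels = pixels, provenance = as.character(provenance)),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("<BinaryMask %d x %d, %d foreground px; %s>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$provenance))
  invisible(x)
}

#' Read channels from a TIFF file
#'
#' Reads a single- or multi-page grayscale TIFF (8- or 16-bit) and returns
#' the requested pages as named [image_channel()] objects.
#'
#' @param path path to the TIFF file.
#' @param channel_map named integer vector mapping channel names to 1-based
#'   page indices, e.g. `c(Arm = 1, GM130 = 2)`.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list of `ImageChannel`, one per entry of `channel_map`, in map
#'   order. All channels are guaranteed to share dimensions.
#' @export
read_image <- function(path, channel_map, pixel_size_um) {
  if (!file.exists(path))
    eq_stop("eq_io_error", "image file not found: %s", path)
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    eq_stop("eq_io_error", "channel_map must be a named vector of page indices")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) eq_stop("eq_io_error", "unreadable TIFF '%s': %s",
                                path, conditionMessage(e))
  )
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (length(pages) > 1L && (length(unique(dims[1, ])) > 1L ||
                             length(unique(dims[2, ])) > 1L))
    eq_stop("eq_io_error", "pages of '%s' have non-uniform dimensions", path)
  out <- vector("list", length(channel_map))
  names(out) <- names(channel_map)
  for (i in seq_along(channel_map)) {
    idx <- as.integer(channel_map[[i]])
    if (idx < 1L || idx > length(pages))
      eq_stop("eq_channel_index", "channel index %d ('%s') out of range 1..%d in %s",
              idx, names(channel_map)[i], length(pages), path)
    px <- pages[[idx]]
    if (length(dim(px)) == 3L) px <- px[, , 1]  # flatten accidental RGB pages
    bit <- if (max(px) > 255) 16L else 8L
    out[[i]] <- image_channel(matrix(as.numeric(px), nrow(px), ncol(px)),
                              names(channel_map)[i], pixel_size_um, bit)
  }
  out
}

#' Write channels to a (multi-page) TIFF file
#'
#' Counterpart of [read_image()], used to emit synthetic fixtures. Pixel
#' values are stored at the channel's bit depth; integer intensities
#' round-trip exactly.
#'
#' @param channels a single `ImageChannel` or a list of them (equal sizes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(channels, path) {
  if (inherits(channels, "ImageChannel")) channels <- list(channels)
  pages <- lapply(channels, function(ch) {
    stopifnot(inherits(ch, "ImageChannel"))
    round(ch$pixels) / (2^ch$bit_depth - 1)
  })
  bits <- unique(vapply(channels, function(ch) ch$bit_depth, integer(1)))
  if (length(bits) != 1L)
    eq_stop("eq_io_error", "all channels in one file must share bit depth")
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

# Gaussian smoothing; sigma = 0 means identity. Works on a plain matrix.
# The kernel radius is capped so that large background-scale sigmas remain
# usable on small images.
gaussian_smooth <- function(pixels, sigma) {
  if (sigma <= 0) return(pixels)
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  limit <- min(dim(pixels))
  if (limit %% 2L == 0L) limit <- limit - 1L
  brush <- EBImage::makeBrush(min(radius, limit), shape = "Gaussian",
                              sigma = sigma)
  as.matrix(EBImage::filter2(pixels, brush, boundary = "replicate"))
}

# Otsu threshold of a numeric matrix over the channel's intensity range,
# using 256 histogram levels. Returns the threshold on the intensity scale.
otsu_threshold <- function(pixels, maxval) {
  if (diff(range(pixels)) == 0)
    eq_stop("eq_degenerate_threshold",
            "constant-intensity image: Otsu threshold undefined")
  px <- pmin(pmax(pixels / maxval, 0), 1)
  as.numeric(EBImage::otsu(EBImage::Image(px), range = c(0, 1), levels = 256)) *
    maxval
}

#' Binarize a channel
#'
#' Gaussian-smooths the channel and thresholds it. The mask is true where
#' the smoothed intensity *strictly* exceeds the threshold; pixels exactly
#' at the threshold are background.
#'
#' @param channel an [image_channel()].
#' @param sigma Gaussian standard deviation in pixels (>= 0; 0 = no
#'   smoothing). Default 1, a low-sigma blur that suppresses shot noise
#'   without merging structures.
#' @param method `"otsu"` (between-class-variance threshold over 256 levels
#'   of the bit-depth range) or `"absolute"`.
#' @param absolute_threshold intensity threshold, required when
#'   `method = "absolute"`; must lie within the bit-depth range.
#' @return a [binary_mask()] whose provenance records sigma, method and the
#'   threshold value actually applied.
#' @export
binarize <- function(channel, sigma = 1, method = c("otsu", "absolute"),
                     absolute_threshold = NULL) {
  stopifnot(inherits(channel, "ImageChannel"))
  method <- match.arg(method)
  if (!is_scalar_num(sigma) || sigma < 0)
    eq_stop("eq_invalid_params", "sigma must be >= 0")
  maxval <- 2^channel$bit_depth - 1
  sm <- gaussian_smooth(channel$pixels, sigma)
  if (method == "absolute") {
    if (!is_scalar_num(absolute_threshold) ||
        absolute_threshold < 0 || absolute_threshold > maxval)
      eq_stop("eq_invalid_params",
              "absolute_threshold must lie in [0, %d]", maxval)
    thr <- absolute_threshold
  } else {
    thr <- otsu_threshold(sm, maxval)
  }
  binary_mask(sm > thr,
              sprintf("channel='%s' sigma=%g method=%s threshold=%.6g",
                      channel$name, sigma, method, thr))
}

#' Label connected components
#'
#' @param mask a [binary_mask()] (or logical matrix).
#' @param connectivity 4 (edge-sharing) or 8 (edge- or corner-sharing).
#' @return an object of class `LabeledImage`: list with `labels` (integer
#'   matrix, 0 = background, objects numbered 1..N in order of first pixel
#'   in column-major scan), `connectivity` and `n` (component count).
#' @export
label_components <- function(mask, connectivity = 8L) {
  px <- if (inherits(mask, "BinaryMask")) mask$pixels else mask
  stopifnot(is.matrix(px), is.logical(px))
  if (!connectivity %in% c(4L, 8L))
    eq_stop("eq_invalid_params", "connectivity must be 4 or 8")
  labels <- if (connectivity == 4L) {
    matrix(as.integer(EBImage::bwlabel(px)), nrow(px), ncol(px))
  } else {
    label8_igraph(px)
  }
  labels <- renumber_labels(labels)
  structure(list(labels = labels, connectivity = as.integer(connectivity),
                 n = max(labels, 0L)),
            class = "LabeledImage")
}

# 8-connected labeling via the pixel adjacency graph.
label8_igraph <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  idx <- which(px)
  out <- matrix(0L, nr, nc)
  if (!length(idx)) return(out)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  shift_pairs <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    j <- idx[ok] + dr + dc * nr
    keep <- px[j]
    cbind(idx[ok][keep], j[keep])
  }
  e <- rbind(shift_pairs(1L, 0L), shift_pairs(0L, 1L),
             shift_pairs(1L, 1L), shift_pairs(-1L, 1L))
  v <- integer(nr * nc); v[idx] <- seq_along(idx)
  g <- igraph::make_graph(t(cbind(v[e[, 1]], v[e[, 2]])),
                          n = length(idx), directed = FALSE)
  out[idx] <- igraph::components(g)$membership
  out
}

# Renumber labels 1..N by first occurrence in column-major order.
renumber_labels <- function(labels) {
  pos <- which(labels > 0L)
  if (!length(pos)) return(labels)
  old <- labels[pos]
  first <- vapply(split(pos, old), min, numeric(1))
  map <- integer(max(old))
  map[as.integer(names(first))] <- order(order(first))
  labels[pos] <- map[old]
  labels
}

#' Labeled image from an integer matrix
#'
#' Wraps an existing label matrix (e.g. a planted ground-truth tessellation)
#' as a `LabeledImage` without re-labeling.
#'
#' @param labels integer matrix, 0 = background.
#' @param connectivity connectivity under which the labels were formed.
#' @return a `LabeledImage`.
#' @export
as_labeled_image <- function(labels, connectivity = 8L) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, connectivity = as.integer(connectivity),
                 n = max(labels, 0L)),
            class = "LabeledImage")
}

# Weighted boundary-chain perimeter estimate for one cropped logical mask
# (Vossepoel-Smeulders-style category weights; accurate for smooth shapes,
# can slightly exceed the true contour length for discs, hence the
# circularity clamp downstream).
perimeter_weighted <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  # interior = all 4-neighbors set; border pixels are mask minus interior
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  inner <- core &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  border <- core & !inner
  if (!any(border)) return(4)  # isolated pixel fallback
  bp <- matrix(0, nr + 2L, nc + 2L)
  bp[2:(nr + 1L), 2:(nc + 1L)] <- border
  # convolution with [[10,2,10],[2,1,2],[10,2,10]] evaluated at border pixels
  conv <- bp[2:(nr + 1L), 2:(nc + 1L)] +
    2 * (bp[1:nr, 2:(nc + 1L)] + bp[3:(nr + 2L), 2:(nc + 1L)] +
         bp[2:(nr + 1L), 1:nc] + bp[2:(nr + 1L), 3:(nc + 2L)]) +
    10 * (bp[1:nr, 1:nc] + bp[1:nr, 3:(nc + 2L)] +
          bp[3:(nr + 2L), 1:nc] + bp[3:(nr + 2L), 3:(nc + 2L)])
  cat_vals <- conv[border]
  w <- numeric(64)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(w[pmin(cat_vals, 63) + 1])
}

#' Measure region properties of labeled objects
#'
#' One row per label, ordered by label: pixel and calibrated areas, centroid,
#' an estimated boundary length, circularity (`4 * pi * area / perimeter^2`,
#' clamped at 1 because the discrete perimeter estimate can undershoot the
#' contour of near-circular objects), the inclusive bounding box and whether
#' the object touches the image border.
#'
#' @param labeled a `LabeledImage` (see [label_components()]).
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @return data.frame with columns `label`, `area_px`, `area_um2`,
#'   `centroid_r`, `centroid_c`, `perimeter_px`, `circularity`, `min_row`,
#'   `min_col`, `max_row`, `max_col`, `touches_border`.
#' @export
region_properties <- function(labeled, pixel_size_um) {
  stopifnot(inherits(labeled, "LabeledImage"))
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    eq_stop("eq_calibration_error", "pixel_size_um must be > 0")
  L <- labeled$labels
  nr <- nrow(L); nc <- ncol(L)
  n <- labeled$n
  empty <- data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), perimeter_px = numeric(0),
                      circularity = numeric(0), min_row = integer(0),
                      min_col = integer(0), max_row = integer(0),
                      max_col = integer(0), touches_border = logical(0))
  if (n == 0L) return(empty)
  pos <- which(L > 0L)
  lab <- L[pos]
  r <- ((pos - 1L) %% nr) + 1L
  co <- ((pos - 1L) %/% nr) + 1L
  area <- tabulate(lab, nbins = n)
  cr <- rowsum(r, lab)[, 1] / area
  cc <- rowsum(co, lab)[, 1] / area
  rmin <- vapply(split(r, lab), min, numeric(1))
  rmax <- vapply(split(r, lab), max, numeric(1))
  cmin <- vapply(split(co, lab), min, numeric(1))
  cmax <- vapply(split(co, lab), max, numeric(1))
  perim <- numeric(n)
  for (k in seq_len(n)) {
    sub <- L[rmin[k]:rmax[k], cmin[k]:cmax[k], drop = FALSE] == k
    perim[k] <- perimeter_weighted(sub)
  }
  circ <- pmin(4 * pi * area / perim^2, 1)
  data.frame(
    label = seq_len(n),
    area_px = area,
    area_um2 = area * pixel_size_um^2,
    centroid_r = cr, centroid_c = cc,
    perimeter_px = perim,
    circularity = circ,
    min_row = as.integer(rmin), min_col = as.integer(cmin),
    max_row = as.integer(rmax), max_col = as.integer(cmax),
    touches_border = rmin == 1L | cmin == 1L | rmax == nr | cmax == nc
  )
}
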