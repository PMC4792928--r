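## Epithelial cell-shape quantification: segment a junction-stained
## monolayer into cells, count each cell's vertices via connectivity with
## its neighbour cells, drop edge cells and cells with more than 8 vertices,
## and summarize polygon-class counts/percentages and cell areas.

#' Segmentation parameters for junction-stained epithelia
#'
#' @param sigma Gaussian smoothing (px) applied before thresholding the
#'   junction channel.
#' @param threshold_method `"otsu"` or `"absolute"`.
#' @param absolute_threshold intensity threshold when method is absolute.
#' @param gap_closing_radius radius (px) of a morphological closing applied
#'   to the boundary mask to seal small gaps in the junctional signal;
#'   0 disables it.
#' @param min_contact_px minimum number of 4-adjacent pixel contacts between
#'   two cells' territories for them to count as neighbours; small values
#'   admit spurious corner contacts, the default of 3 requires a short
#'   shared edge.
#' @return list of class `shape_params`.
#' @export
shape_params <- function(sigma = 1, threshold_method = "otsu",
                         absolute_threshold = NULL, gap_closing_radius = 0L,
                         min_contact_px = 3L) {
  stopifnot(sigma >= 0, gap_closing_radius >= 0, min_contact_px >= 1)
  structure(list(sigma = sigma, threshold_method = threshold_method,
                 absolute_threshold = absolute_threshold,
                 gap_closing_radius = as.integer(gap_closing_radius),
                 min_contact_px = as.integer(min_contact_px)),
            class = "shape_params")
}

# Expand cell-interior labels outward to cover unassigned pixels (the
# junction line and discarded speckles), so each cell's area includes its
# share of the boundary. Iterative 8-neighbour propagation; ties go to the
# larger label, which only moves the assignment boundary by <= 1 px.
expand_labels <- function(labels, max_iter = 100L) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (it in seq_len(max_iter)) {
    un <- labels == 0L
    if (!any(un)) break
    nb <- matrix(0L, nr, nc)
    mx <- function(a, b) {
      # elementwise max of label matrices
      ifelse(a > b, a, b)
    }
    sh <- matrix(0L, nr, nc)
    sh[-nr, ] <- labels[-1, ];        nb <- mx(nb, sh)  # from below
    sh[] <- 0L; sh[-1, ] <- labels[-nr, ];  nb <- mx(nb, sh)  # from above
    sh[] <- 0L; sh[, -nc] <- labels[, -1];  nb <- mx(nb, sh)  # from right
    sh[] <- 0L; sh[, -1] <- labels[, -nc];  nb <- mx(nb, sh)  # from left
    sh[] <- 0L; sh[-nr, -nc] <- labels[-1, -1];    nb <- mx(nb, sh)
    sh[] <- 0L; sh[-1, -1] <- labels[-nr, -nc];    nb <- mx(nb, sh)
    sh[] <- 0L; sh[-nr, -1] <- labels[-1, -nc];    nb <- mx(nb, sh)
    sh[] <- 0L; sh[-1, -nc] <- labels[-nr, -1];    nb <- mx(nb, sh)
    grow <- un & nb > 0L
    if (!any(grow)) break
    labels[grow] <- nb[grow]
  }
  labels
}

# Adjacency between labels of a fully assigned label image: pairs of labels
# meeting across >= min_contact 4-adjacent pixel contacts. Returns a named
# list label -> sorted integer vector of neighbours (symmetric).
contact_adjacency <- function(labels, n, min_contact = 3L) {
  pairs <- rbind(
    cbind(as.vector(labels[-nrow(labels), ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -ncol(labels)]), as.vector(labels[, -1]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0L & pairs[, 2] > 0L,
                 , drop = FALSE]
  adj <- rep(list(integer(0)), n)
  names(adj) <- as.character(seq_len(n))
  if (!nrow(pairs)) return(adj)
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  keep <- names(cnt)[cnt >= min_contact]
  if (!length(keep)) return(adj)
  kp <- do.call(rbind, strsplit(keep, " "))
  a <- as.integer(kp[, 1]); b <- as.integer(kp[, 2])
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Segment an epithelial junction image into cells
#'
#' Thresholds the junction channel into a boundary mask, takes 4-connected
#' components of its complement as cell interiors (discarding components
#' below `min_cell_area_px`), expands the interior labels through the
#' boundary so every pixel is assigned to its nearest cell, and derives the
#' cell adjacency graph from shared expanded-territory contacts. Cells whose
#' territory reaches the image border are flagged as edge cells.
#'
#' @param junction_channel [image_channel()] of the junctional stain.
#' @param params a [shape_params()] configuration.
#' @param min_cell_area_px minimum interior size in pixels; smaller
#'   complement components (boundary speckle) are discarded and absorbed by
#'   the label expansion.
#' @return an object of class `LabeledCells`: list with `labels` (interior
#'   `LabeledImage`), `filled` (expanded label matrix covering the frame),
#'   `boundary_mask`, `adjacency` (named list label -> neighbour labels),
#'   `edge_labels`, `areas_px` (expanded per-cell areas) and `params`.
#' @export
segment_cells <- function(junction_channel, params = shape_params(),
                          min_cell_area_px = 50L) {
  stopifnot(inherits(junction_channel, "ImageChannel"),
            inherits(params, "shape_params"))
  boundary <- binarize(junction_channel, sigma = params$sigma,
                       method = params$threshold_method,
                       absolute_threshold = params$absolute_threshold)
  bm <- boundary$pixels
  if (params$gap_closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$gap_closing_radius + 1L, "disc")
    bm <- EBImage::closing(bm, brush) > 0
  }
  interiors <- label_components(binary_mask(!bm, "complement of boundary"),
                                connectivity = 4L)
  sizes <- tabulate(interiors$labels[interiors$labels > 0L],
                    nbins = max(interiors$n, 1L))
  keep <- which(sizes >= min_cell_area_px)
  if (!length(keep) || interiors$n == 0L)
    eq_stop("eq_empty_segmentation",
            "no cell interiors of >= %d px found (boundary mask covers %.1f%% of the frame)",
            min_cell_area_px, 100 * mean(bm))
  lab <- interiors$labels
  lab[!(lab %in% keep)] <- 0L
  lab <- renumber_labels(lab)
  n <- length(keep)
  filled <- expand_labels(lab)
  areas <- tabulate(filled[filled > 0L], nbins = n)
  adjacency <- contact_adjacency(filled, n, params$min_contact_px)
  nr <- nrow(filled); nc <- ncol(filled)
  edge <- sort(unique(c(filled[1, ], filled[nr, ], filled[, 1], filled[, nc])))
  edge <- edge[edge > 0L]
  structure(
    list(labels = as_labeled_image(lab, 4L), filled = filled,
         boundary_mask = binary_mask(bm, boundary$provenance),
         adjacency = adjacency, edge_labels = as.integer(edge),
         areas_px = areas, params = params),
    class = "LabeledCells"
  )
}

#' @export
print.LabeledCells <- function(x, ...) {
  cat(sprintf("<LabeledCells: %d cells (%d at image edge), %d x %d px>\n",
              x$labels$n, length(x$edge_labels),
              nrow(x$filled), ncol(x$filled)))
  invisible(x)
}

#' Count vertices of each cell
#'
#' For cells of a tessellating monolayer the number of vertices (corners
#' where three or more cells meet) equals the number of neighbouring cells,
#' so the vertex count is the degree of the cell in the adjacency graph.
#'
#' @param cells a `LabeledCells` object from [segment_cells()].
#' @return named integer vector, label -> vertex count.
#' @export
count_vertices <- function(cells) {
  stopifnot(inherits(cells, "LabeledCells"))
  vapply(cells$adjacency, length, integer(1))
}

#' Build per-cell records with inclusion filters
#'
#' Applies the analysis filters: cells at the image edge are excluded, as
#' are cells with more than 8 vertices (and, symmetrically, fewer than 4,
#' since the polygon classes of interest run 4-8).
#'
#' @param cells a `LabeledCells` object.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return data.frame with one row per cell: `label`, `n_vertices`,
#'   `area_px`, `area_um2`, `is_edge`, `included`, `exclusion_reason`.
#'   Exclusion tallies are attached as attribute `"excluded"`.
#' @export
build_cell_records <- function(cells, pixel_size_um) {
  stopifnot(inherits(cells, "LabeledCells"))
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    eq_stop("eq_calibration_error", "pixel_size_um must be > 0")
  nv <- count_vertices(cells)
  n <- cells$labels$n
  is_edge <- seq_len(n) %in% cells$edge_labels
  reason <- rep("", n)
  reason[is_edge] <- "edge"
  reason[!is_edge & nv > 8L] <- "vertices>8"
  reason[!is_edge & nv < 4L] <- "vertices<4"
  rec <- data.frame(
    label = seq_len(n),
    n_vertices = as.integer(nv),
    area_px = as.integer(cells$areas_px),
    area_um2 = cells$areas_px * pixel_size_um^2,
    is_edge = is_edge,
    included = !nzchar(reason),
    exclusion_reason = reason
  )
  attr(rec, "excluded") <- table(reason[nzchar(reason)])
  rec
}

#' Summarize vertex classes and areas of included cells
#'
#' @param records data.frame from [build_cell_records()].
#' @param genotype label for the summarized sample.
#' @return a `ShapeSummary` (see [shape_summary_from_counts()]); area
#'   statistics are computed over the included cells.
#' @export
summarize_shapes <- function(records, genotype = "") {
  inc <- records[records$included, , drop = FALSE]
  if (!nrow(inc))
    eq_stop("eq_empty_summary", "no included cells to summarize")
  counts <- vapply(4:8, function(k) sum(inc$n_vertices == k), integer(1))
  names(counts) <- 4:8
  shape_summary_from_counts(counts, genotype,
                            mean_area_um2 = mean(inc$area_um2),
                            sd_area_um2 = sd0(inc$area_um2),
                            n_area = nrow(inc))
}

#' Shape summary from per-class cell counts
#'
#' Builds the polygon-class summary directly from counts of 4- to 8-vertex
#' cells, e.g. counts transcribed from a published quantification table.
#' Percentages are integer, rounded half up.
#'
#' @param counts named numeric vector with names among `"4".."8"`; missing
#'   classes count 0.
#' @param genotype sample label.
#' @param mean_area_um2,sd_area_um2,n_area optional area statistics to carry
#'   in the summary (the vertex classification and the area measurement may
#'   cover different numbers of cells).
#' @return an object of class `ShapeSummary` with fields `genotype`, `n`,
#'   `counts`, `percentages` (integer, per class 4-8), `mean_area_um2`,
#'   `sd_area_um2`, `n_area`.
#' @export
shape_summary_from_counts <- function(counts, genotype = "",
                                      mean_area_um2 = NA_real_,
                                      sd_area_um2 = NA_real_,
                                      n_area = NA_integer_) {
  full <- stats::setNames(integer(5), 4:8)
  if (is.null(names(counts)) && length(counts) == 5L) names(counts) <- 4:8
  if (!all(names(counts) %in% names(full)))
    eq_stop("eq_invalid_params", "counts must be named with classes 4..8")
  full[names(counts)] <- as.integer(counts)
  n <- sum(full)
  if (n < 1L) eq_stop("eq_empty_summary", "zero cells in counts")
  pct <- stats::setNames(round_half_up(100 * full / n), names(full))
  structure(
    list(genotype = genotype, n = n, counts = full, percentages = pct,
         mean_area_um2 = mean_area_um2, sd_area_um2 = sd_area_um2,
         n_area = if (is.na(n_area)) NA_integer_ else as.integer(n_area)),
    class = "ShapeSummary"
  )
}

#' @export
print.ShapeSummary <- function(x, ...) {
  cat(sprintf("Shape summary: %s (n = %d cells)\n", x$genotype, x$n))
  for (k in names(x$counts))
    cat(sprintf("  %s vertices: %4d cells (%d%%)\n",
                k, x$counts[[k]], x$percentages[[k]]))
  if (!is.na(x$mean_area_um2))
    cat(sprintf("  mean area: %.2f um^2 (sd %.2f, n = %s)\n",
                x$mean_area_um2, x$sd_area_um2, x$n_area))
  invisible(x)
}

#' @export
as.data.frame.ShapeSummary <- function(x, ...) {
  data.frame(genotype = x$genotype, n = x$n,
             class = as.integer(names(x$counts)),
             count = as.integer(x$counts),
             percent = as.integer(x$percentages),
             mean_area_um2 = x$mean_area_um2,
             sd_area_um2 = x$sd_area_um2,
             n_area = x$n_area)
}
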