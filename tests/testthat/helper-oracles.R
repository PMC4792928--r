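# Independent oracles and fixture builders used across the suite.

# Brute-force stack-based flood fill, independent of the package's
# graph-based labeling. Returns an integer label matrix.
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), each = 3), rep(c(-1L, 0L, 1L), 3))
  }
  nbr <- nbr[!(nbr[, 1] == 0L & nbr[, 2] == 0L), , drop = FALSE]
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff the label-pair mapping is
# one-to-one in both directions on foreground pixels.
same_partition <- function(a, b) {
  fg <- a > 0L | b > 0L
  if (!any(fg)) return(TRUE)
  if (any(xor(a > 0L, b > 0L))) return(FALSE)
  key <- paste(a[fg], b[fg])
  u <- unique(key)
  parts <- do.call(rbind, strsplit(u, " "))
  !anyDuplicated(parts[, 1]) && !anyDuplicated(parts[, 2])
}

# Exhaustive Otsu: try every integer threshold, maximize between-class
# variance of the strictly-above / at-or-below split.
exhaustive_otsu_mask <- function(px, maxval = 255) {
  best_t <- NA; best_v <- -Inf
  for (t in 0:(maxval - 1)) {
    hi <- px > t
    w1 <- mean(hi); w0 <- 1 - w1
    if (w1 == 0 || w0 == 0) next
    v <- w0 * w1 * (mean(px[hi]) - mean(px[!hi]))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  px > best_t
}

# Flat test channel from a matrix.
make_channel <- function(px, name = "test", pixel_size_um = 0.2,
                         bit_depth = 8L) {
  image_channel(px, name, pixel_size_um, bit_depth)
}

# Filled rasterized disc mask centred at (r0, c0).
disc_matrix <- function(size, r0, c0, radius) {
  d2 <- outer((seq_len(size) - r0)^2, (seq_len(size) - c0)^2, `+`)
  d2 <= radius^2
}

# Two 5x5 blocks joined by a single-pixel bridge; nine bridge geometries
# (three row offsets of the bridge on each side x three alignments).
bridge_fixture <- function(case) {
  stopifnot(case >= 1, case <= 9)
  px <- matrix(0, 20, 24)
  px[8:12, 4:8] <- 200    # left block
  px[8:12, 14:18] <- 200  # right block
  row <- 8L + ((case - 1L) %% 3L) * 2L       # bridge row: 8, 10 or 12
  shift <- ((case - 1L) %/% 3L) - 1L         # bridge bent up/flat/down
  px[row, 9:11] <- 200
  px[row + shift, 12:13] <- 200
  if (shift != 0) px[row + shift, 11] <- 200  # keep 8-connectivity
  px
}
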