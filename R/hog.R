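#' Histogram-of-oriented-gradients parameters
#'
#' The classic dense-descriptor configuration: 8-px cells, 2x2-cell blocks at
#' one-cell stride, 9 unsigned orientation bins over \[0, 180) degrees, and
#' L2-Hys block normalization (L2-normalize, clip at 0.2, renormalize). For a
#' 224-px working size this yields 27 x 27 blocks x 36 values = 26244
#' dimensions.
#'
#' @param cell_px cell side in pixels; must divide the working size.
#' @param block_cells cells per block side.
#' @param bins orientation bins (>= 2).
#' @param signed if `FALSE` (default) orientations are folded to \[0, 180).
#' @param block_norm_eps epsilon guarding the block L2 norms.
#' @return A `hog_params` list.
#' @export
hog_params <- function(cell_px = 8L, block_cells = 2L, bins = 9L,
                       signed = FALSE, block_norm_eps = 1e-6) {
  if (!is_count(cell_px) || !is_count(block_cells)) stopf("invalid HOG sizes")
  if (!is_count(bins) || bins < 2) stopf("bins must be >= 2")
  if (block_norm_eps <= 0) stopf("block_norm_eps must be > 0")
  structure(list(cell_px = as.integer(cell_px),
                 block_cells = as.integer(block_cells), bins = as.integer(bins),
                 signed = isTRUE(signed), block_norm_eps = block_norm_eps),
            class = "hog_params")
}

#' Expected HOG vector length for a given image side
#' @param side image side, px.
#' @param params a [hog_params()].
#' @return integer length.
#' @export
hog_length <- function(side, params = hog_params()) {
  ncell <- side %/% params$cell_px
  nb <- ncell - params$block_cells + 1L
  as.integer(nb * nb * params$block_cells^2 * params$bins)
}

# image gradients by central differences with edge-clamped borders
image_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- m[, c(2:w, w), drop = FALSE] - m[, c(1, 1:(w - 1)), drop = FALSE]
  gy <- m[c(2:h, h), , drop = FALSE] - m[c(1, 1:(h - 1)), , drop = FALSE]
  list(gx = gx, gy = gy)
}

# cached gather map translating the (bins x ncell x ncell) cell-histogram
# array into concatenated row-major block vectors
hog_block_map <- function(ncell, block_cells, bins) {
  key <- sprintf("hogmap_%d_%d_%d", ncell, block_cells, bins)
  map <- .acromir_cache[[key]]
  if (!is.null(map)) return(map)
  nb <- ncell - block_cells + 1L
  idx <- integer(nb * nb * block_cells^2 * bins)
  p <- 0L
  for (bi in seq_len(nb)) for (bj in seq_len(nb)) {        # blocks row-major
    for (ci in bi:(bi + block_cells - 1L))                 # cells row-major
      for (cj in bj:(bj + block_cells - 1L)) {
        base <- ((ci - 1L) * ncell + (cj - 1L)) * bins
        idx[p + seq_len(bins)] <- base + seq_len(bins)
        p <- p + bins
      }
  }
  .acromir_cache[[key]] <- idx
  idx
}

#' HOG descriptor of a canonical image
#'
#' Gradients by central differences (edge-clamped); magnitude-weighted votes
#' split bilinearly between the two nearest orientation-bin centers (centers
#' at multiples of the bin width, so a pure horizontal gradient falls wholly
#' in the first bin); per-cell histograms grouped into overlapping blocks at
#' one-cell stride; per-block L2-Hys normalization; blocks concatenated
#' row-major.
#'
#' @param image a [gray_image()] (or plain matrix) whose side is divisible by
#'   `params$cell_px`.
#' @param params a [hog_params()].
#' @return numeric feature vector with a `descriptor_id` attribute `"hog"`.
#' @export
hog_features <- function(image, params = hog_params()) {
  m <- unclass(image)
  h <- nrow(m); w <- ncol(m)
  if (h %% params$cell_px != 0L || w %% params$cell_px != 0L)
    stopf("cell_px (%d) must divide the image side (%dx%d)",
          params$cell_px, h, w)
  g <- image_gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  span <- if (params$signed) 360 else 180
  ang <- (atan2(g$gy, g$gx) * 180 / pi) %% span
  bins <- params$bins
  binw <- span / bins
  t <- ang / binw
  b0 <- floor(t)
  frac <- t - b0
  b0 <- as.integer(b0) %% bins
  b1 <- (b0 + 1L) %% bins

  ncell <- h %/% params$cell_px
  ci <- (row(m) - 1L) %/% params$cell_px
  cj <- (col(m) - 1L) %/% params$cell_px
  cell <- ci * ncell + cj                       # row-major cell index, 0-based
  nhist <- ncell * ncell * bins
  idx <- c(cell * bins + b0, cell * bins + b1) + 1L
  wts <- c(mag * (1 - frac), mag * frac)
  hist <- numeric(nhist)
  acc <- rowsum(wts, idx)
  hist[as.integer(rownames(acc))] <- acc

  bmap <- hog_block_map(ncell, params$block_cells, bins)
  blen <- params$block_cells^2 * bins
  B <- matrix(hist[bmap], nrow = blen)
  eps <- params$block_norm_eps
  nrm <- sqrt(colSums(B^2) + eps^2)
  B <- pmin(B / rep(nrm, each = blen), 0.2)     # L2 + clip
  nrm2 <- sqrt(colSums(B^2) + eps^2)
  B <- B / rep(nrm2, each = blen)               # renormalize (L2-Hys)
  structure(as.vector(B), descriptor_id = "hog")
}
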