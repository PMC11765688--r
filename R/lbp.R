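#' Grid-LBP parameters
#'
#' The 8-bit local binary pattern code image is pooled over a `grid` x `grid`
#' spatial partition of per-cell 256-bin histograms, each normalized to sum 1,
#' concatenated row-major (default 4 x 4 x 256 = 4096 dimensions).
#'
#' @param grid cells per side; must divide the working size.
#' @return An `lbp_params` list (`code_bins` is fixed at 256).
#' @export
lbp_params <- function(grid = 4L) {
  if (!is_count(grid)) stopf("grid must be a positive integer")
  structure(list(grid = as.integer(grid), code_bins = 256L),
            class = "lbp_params")
}

#' 8-bit LBP code image
#'
#' Each interior pixel is coded from its 3x3 neighborhood: a neighbor
#' contributes 1 when its value is greater than or equal to the center. Bit
#' order: the top-left neighbor is the most significant bit, proceeding
#' clockwise (top, top-right, right, bottom-right, bottom, bottom-left, left).
#' Border pixels are excluded, so the output is `(h-2) x (w-2)`.
#'
#' @param image a [gray_image()] or numeric matrix, at least 3x3.
#' @return integer matrix of codes in `0:255`.
#' @export
lbp_code_image <- function(image) {
  m <- unclass(image)
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) stopf("image must be at least 3x3 for LBP")
  ctr <- m[2:(h - 1), 2:(w - 1), drop = FALSE]
  nb <- list(m[1:(h - 2), 1:(w - 2), drop = FALSE],  # top-left (MSB)
             m[1:(h - 2), 2:(w - 1), drop = FALSE],  # top
             m[1:(h - 2), 3:w,       drop = FALSE],  # top-right
             m[2:(h - 1), 3:w,       drop = FALSE],  # right
             m[3:h,       3:w,       drop = FALSE],  # bottom-right
             m[3:h,       2:(w - 1), drop = FALSE],  # bottom
             m[3:h,       1:(w - 2), drop = FALSE],  # bottom-left
             m[2:(h - 1), 1:(w - 2), drop = FALSE])  # left (LSB)
  code <- matrix(0L, h - 2L, w - 2L)
  bit <- 128L
  for (n in nb) {
    code <- code + bit * (n >= ctr)
    bit <- bit %/% 2L
  }
  mode(code) <- "integer"
  code
}

#' Grid-pooled LBP histogram descriptor
#'
#' Computes the [lbp_code_image()], partitions it into `grid` x `grid`
#' near-equal contiguous cells (cell sides differ by at most one pixel since
#' the code image is two pixels narrower than the working size), builds a
#' 256-bin count histogram per cell normalized to sum 1, and concatenates the
#' cells row-major.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param params an [lbp_params()].
#' @return numeric vector of length `grid^2 * 256` with `descriptor_id`
#'   attribute `"lbp"`.
#' @export
lbp_features <- function(image, params = lbp_params()) {
  side <- nrow(unclass(image))
  if (side %% params$grid != 0L)
    stopf("grid (%d) must divide the working size (%d)", params$grid, side)
  code <- lbp_code_image(image)
  g <- params$grid
  hc <- nrow(code); wc <- ncol(code)
  ri <- ((seq_len(hc) - 1L) * g) %/% hc          # near-equal row partition
  cjv <- ((seq_len(wc) - 1L) * g) %/% wc
  cell <- outer(ri, cjv, function(a, b) a * g + b)  # row-major, 0-based
  idx <- cell * 256L + code + 1L
  hist <- numeric(g * g * 256L)
  cnt <- rowsum(rep(1, length(idx)), as.vector(idx))
  hist[as.integer(rownames(cnt))] <- cnt
  per_cell <- as.vector(table(factor(as.vector(cell), levels = 0:(g * g - 1))))
  hist <- hist / rep(per_cell, each = 256L)
  structure(hist, descriptor_id = "lbp")
}
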