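#' Canonical grayscale image
#'
#' The working representation every descriptor consumes: a numeric matrix of
#' intensities in `[0, 1]`, row-major with the origin at the top-left, square
#' at the configured working size after ingestion, carrying a string id.
#'
#' @param pixels numeric matrix of finite intensities in `[0, 1]`.
#' @param id single string identifying the image.
#' @return A `gray_image`: the pixel matrix with an `id` attribute.
#' @examples
#' img <- gray_image(matrix(runif(16), 4, 4), id = "demo")
#' dim(img)
#' @export
gray_image <- function(pixels, id = "img") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("zero-sized image")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stopf("image '%s' contains non-finite intensities", id)
  if (min(pixels) < 0 || max(pixels) > 1)
    stopf("image '%s' has intensities outside [0, 1]", id)
  if (!is.character(id) || length(id) != 1L)
    stopf("id must be a single string")
  structure(pixels, id = id, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s' %dx%d, range [%.3f, %.3f]>\n",
              attr(x, "id"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

image_id <- function(img) attr(img, "id")

#' Bilinear image resize
#'
#' Samples the source at target pixel centers (edge-clamped), the standard
#' convention that preserves the mean of smooth images under downsampling.
#'
#' @param m numeric matrix.
#' @param height,width target size in pixels.
#' @return numeric `height` x `width` matrix.
#' @export
resize_bilinear <- function(m, height, width = height) {
  sh <- nrow(m); sw <- ncol(m)
  if (sh == height && sw == width) return(m)
  # map target pixel center t (1-based) to source coordinate
  src_r <- pmin(pmax((seq_len(height) - 0.5) * sh / height + 0.5, 1), sh)
  src_c <- pmin(pmax((seq_len(width)  - 0.5) * sw / width  + 0.5, 1), sw)
  r0 <- pmin(floor(src_r), sh - 1L); fr <- src_r - r0
  c0 <- pmin(floor(src_c), sw - 1L); fc <- src_c - c0
  a <- m[r0, c0, drop = FALSE];      b <- m[r0, c0 + 1L, drop = FALSE]
  d <- m[r0 + 1L, c0, drop = FALSE]; e <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, height, width); wc <- matrix(fc, height, width, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + d * wr * (1 - wc) + e * wr * wc
}

# min-max rescale to [0,1]; a constant image maps to all zeros by convention
# so descriptors on degenerate inputs stay defined
rescale_minmax <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Load an image file into the canonical working representation
#'
#' Reads a PNG or TIFF, collapses color channels to their mean, min-max
#' rescales intensities to `[0, 1]` (a constant image maps to all zeros), and
#' resizes to the square working size with bilinear interpolation.
#'
#' @param path path to a PNG (`.png`) or TIFF (`.tif`/`.tiff`) file.
#' @param working_size side length in pixels of the canonical image.
#' @param id image id; defaults to the file name without extension.
#' @return A [gray_image()].
#' @export
load_image <- function(path, working_size = 224, id = NULL) {
  if (!is_count(working_size)) stopf("working_size must be a positive integer")
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stopf("unreadable PNG %s: %s", path,
                                             conditionMessage(e))),
    tif = ,
    tiff = tryCatch({
      x <- tiff::readTIFF(path, all = TRUE)
      if (length(x) != 1L) stopf("multi-frame TIFF not supported: %s", path)
      x[[1L]]
    }, error = function(e) stopf("unreadable TIFF %s: %s", path,
                                 conditionMessage(e))),
    dcm = ,
    dicom = stopf("DICOM input is not supported by this build: %s", path),
    stopf("unsupported image format '.%s' (expected PNG or TIFF): %s",
          ext, path)
  )
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  if (!is.matrix(px) || any(dim(px) == 0L)) stopf("zero-sized image: %s", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  m <- rescale_minmax(px)
  m <- resize_bilinear(m, working_size, working_size)
  # bilinear weights are convex so [0,1] is preserved; clamp rounding dust
  gray_image(pmin(pmax(m, 0), 1), id = id)
}

#' Save a grayscale image
#'
#' TIFF output (`.tif`/`.tiff`) is written at 16 bits per sample, which
#' round-trips intensities to within 1/65535; PNG output is 8-bit.
#'
#' @param img a [gray_image()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  m <- unclass(img); attr(m, "id") <- NULL
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    stopf("unsupported output format '.%s' (expected PNG or TIFF)", ext)
  )
  invisible(path)
}
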