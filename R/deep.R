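#' Deep-feature extractor contract
#'
#' CNN backbones (DarkNet53, DenseNet201, ...) are plugins, never
#' dependencies: an extractor is any deterministic function of the canonical
#' image that declares a fixed output length. The pipeline treats its output
#' opaquely as one more descriptor block, tagged `"deep:<name>"`.
#'
#' @param name short plugin name (letters, digits, `_`).
#' @param length declared output length.
#' @param fn `function(image) -> numeric(length)`.
#' @return A `deep_extractor`.
#' @export
deep_extractor <- function(name, length, fn) {
  if (!grepl("^[A-Za-z0-9_]+$", name)) stopf("invalid extractor name '%s'",
                                             name)
  if (!is_count(length)) stopf("declared length must be a positive integer")
  if (!is.function(fn)) stopf("fn must be a function(image)")
  structure(list(name = name, length = as.integer(length), fn = fn),
            class = "deep_extractor")
}

#' Apply a deep-feature extractor to an image
#'
#' @param image a [gray_image()].
#' @param extractor a [deep_extractor()].
#' @return numeric vector of the declared length, with `descriptor_id`
#'   attribute `"deep:<name>"`.
#' @export
deep_features <- function(image, extractor) {
  if (!inherits(extractor, "deep_extractor"))
    stopf("extractor must be a deep_extractor")
  v <- as.numeric(extractor$fn(image))
  if (length(v) != extractor$length)
    stopf("contract violation: extractor '%s' declared length %d but returned %d",
          extractor$name, extractor$length, length(v))
  if (anyNA(v) || any(!is.finite(v)))
    stopf("contract violation: extractor '%s' returned non-finite values",
          extractor$name)
  structure(v, descriptor_id = paste0("deep:", extractor$name))
}

#' Built-in stand-in extractors
#'
#' Lightweight deterministic extractors used to exercise the deep-feature
#' slots of the pipeline without pretrained networks: `pool32` mean-pools the
#' image to 32 x 32 intensities (1024 dims); `gradpool32` does the same on the
#' gradient-magnitude map. Both are honest low-level image summaries, not
#' approximations of any CNN.
#'
#' @param name one of `"pool32"`, `"gradpool32"`.
#' @return A [deep_extractor()].
#' @export
builtin_extractor <- function(name = c("pool32", "gradpool32")) {
  name <- match.arg(name)
  pool <- 32L
  fn <- switch(name,
    pool32 = function(image)
      as.vector(t(resize_bilinear(unclass(image), pool, pool))),
    gradpool32 = function(image) {
      g <- image_gradients(unclass(image))
      as.vector(t(resize_bilinear(sqrt(g$gx^2 + g$gy^2), pool, pool)))
    })
  deep_extractor(name, pool * pool, fn)
}
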