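#' Configuration for the synthetic acromion phantom generator
#'
#' Defaults mirror the class balance of the clinical cohort the pipeline is
#' designed for: 178 flat, 337 curved, 104 hooked, 129 convex (748 images in
#' total), one image per simulated patient.
#'
#' @param class_counts integer vector of length 4: images per class.
#' @param image_size side length in pixels.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensity units on the `[0, 1]` scale).
#' @param jitter_px maximum absolute translation, pixels (uniform).
#' @param jitter_deg maximum absolute rotation, degrees (uniform).
#' @param seed RNG seed; identical config + seed gives a bit-identical dataset.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(class_counts = c(178L, 337L, 104L, 129L),
                           image_size = 224, noise_sd = 0.05,
                           jitter_px = 3, jitter_deg = 3, seed = 1L) {
  if (length(class_counts) != 4L || !all(vapply(class_counts, is_count, TRUE)))
    stopf("class_counts must be 4 integers >= 1")
  if (!is_count(image_size) || image_size < 8)
    stopf("image_size must be an integer >= 8")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (jitter_px < 0 || jitter_deg < 0) stopf("jitter must be >= 0")
  structure(list(class_counts = as.integer(class_counts),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, jitter_px = jitter_px,
                 jitter_deg = jitter_deg, seed = as.integer(seed)),
            class = "phantom_config")
}

# Lower-contour depth profile of the bright ridge, per class, in units of the
# image side. u runs 0 (anterior/left) to 1 (posterior/right).
#   1 flat:   straight undersurface
#   2 curved: smooth shallow arc
#   3 hooked: shallow arc ending in an anterior downward hook
#   4 convex: broad, deeper downward bulge
phantom_lower_contour <- function(u, class) {
  base <- 0.54
  switch(class,
         `1` = rep(base, length(u)),
         `2` = 0.50 + 0.06 * sin(pi * u),
         `3` = 0.50 + 0.03 * sin(pi * u) +
               0.14 * exp(-((u - 0.06) / 0.07)^2),
         `4` = 0.44 + 0.16 * (4 * u * (1 - u)),
         stopf("class must be 1-4"))
}

# Render one phantom: a bright ridge on a dark background, analytically
# rotated/translated (so no resampling is needed), with soft ~1.5 px edges.
render_phantom <- function(size, class, tx = 0, ty = 0, theta_deg = 0) {
  s <- size
  fg <- 0.85; bg <- 0.12; edge <- 1.5
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  col <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  row <- matrix(seq_len(s), s, s) - cy
  th <- theta_deg * pi / 180
  # object-frame coordinates of each pixel center
  x <- cos(th) * (col - tx) + sin(th) * (row - ty) + cx
  y <- -sin(th) * (col - tx) + cos(th) * (row - ty) + cy
  x0 <- 0.10 * s; x1 <- 0.90 * s
  ytop <- 0.34 * s
  u <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  ybot <- phantom_lower_contour(u, as.character(class)) * s
  soft <- function(t) pmin(pmax(t / edge + 0.5, 0), 1)
  inside <- soft(x - x0) * soft(x1 - x) * soft(y - ytop) * soft(ybot - y)
  bg + (fg - bg) * inside
}

#' Generate the synthetic acromion phantom dataset
#'
#' Each image shows a bright horizontal ridge (the acromion) on a dark
#' background; the four classes differ only in the shape of the ridge's lower
#' contour, mimicking the flat / curved / hooked / convex typing of the
#' acromial undersurface. Gaussian intensity noise and uniform
#' translation/rotation jitter emulate acquisition variability. The generator
#' is a pure function of its configuration: the session RNG is left untouched.
#'
#' @param config a [phantom_config()].
#' @return A [labeled_dataset()] with ids `"t<class>_<index>"`.
#' @examples
#' ds <- generate_phantoms(phantom_config(class_counts = c(2, 2, 2, 2),
#'                                        image_size = 64, seed = 7))
#' ds
#' @export
generate_phantoms <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config,
                                                             config)
  s <- config$image_size
  with_seed(config$seed, {
    images <- vector("list", sum(config$class_counts))
    labels <- integer(sum(config$class_counts))
    pos <- 0L
    for (cls in 1:4) {
      for (i in seq_len(config$class_counts[cls])) {
        tx <- runif(1, -config$jitter_px, config$jitter_px)
        ty <- runif(1, -config$jitter_px, config$jitter_px)
        th <- runif(1, -config$jitter_deg, config$jitter_deg)
        m <- render_phantom(s, cls, tx, ty, th)
        if (config$noise_sd > 0)
          m <- m + rnorm(s * s, sd = config$noise_sd)
        m <- pmin(pmax(m, 0), 1)
        pos <- pos + 1L
        images[[pos]] <- gray_image(m, id = sprintf("t%d_%03d", cls, i))
        labels[pos] <- cls
      }
    }
    labeled_dataset(images, labels)
  })
}
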