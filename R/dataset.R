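ACROMION_CLASSES <- c(`1` = "flat", `2` = "curved", `3` = "hooked",
                      `4` = "convex")

#' Labeled image dataset
#'
#' A list of canonical [gray_image()]s with a morphological class label per
#' image: 1 = flat, 2 = curved, 3 = hooked, 4 = convex.
#'
#' @param images list of [gray_image()] with unique ids.
#' @param labels integer vector of classes in `1:4`, one per image.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(images, labels) {
  if (!is.list(images) || !all(vapply(images, inherits, TRUE, "gray_image")))
    stopf("images must be a list of gray_image")
  labels <- as.integer(labels)
  if (length(labels) != length(images))
    stopf("labels and images must have equal length")
  if (anyNA(labels) || !all(labels %in% 1:4))
    stopf("every label must be in 1:4")
  ids <- vapply(images, image_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate image ids: %s",
                                paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  structure(list(images = images, labels = labels, ids = ids,
                 class_names = ACROMION_CLASSES),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 1:4))
  cat(sprintf("<labeled_dataset: %d images; classes %s>\n", length(x$images),
              paste(sprintf("%s=%d", ACROMION_CLASSES, tab), collapse = " ")))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

#' Load a labeled dataset from a CSV manifest
#'
#' The manifest must have a header row with columns `id`, `path`, `label`
#' (class in 1-4). Relative paths are resolved against the manifest's
#' directory. Images are canonicalized with [load_image()]; manifest order is
#' preserved.
#'
#' @param manifest path to the CSV manifest.
#' @param working_size side length of the canonical image in pixels.
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(manifest, working_size = 224) {
  if (!file.exists(manifest)) stopf("manifest not found: %s", manifest)
  df <- read.csv(manifest, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "path", "label")
  if (!all(need %in% names(df)))
    stopf("manifest must have columns id, path, label; found: %s",
          paste(names(df), collapse = ", "))
  if (nrow(df) == 0L) stopf("manifest is empty: %s", manifest)
  if (anyDuplicated(df$id)) {
    row <- which(duplicated(df$id))[1L]
    stopf("manifest row %d: duplicate id '%s'", row, df$id[row])
  }
  lab <- suppressWarnings(as.integer(df$label))
  bad <- which(is.na(lab) | !(lab %in% 1:4))
  if (length(bad))
    stopf("manifest row %d: label '%s' outside 1-4", bad[1L],
          df$label[bad[1L]])
  base <- dirname(normalizePath(manifest))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                  file.path(base, df$path))
  missing <- which(!file.exists(paths))
  if (length(missing))
    stopf("manifest row %d: file not found '%s'", missing[1L],
          df$path[missing[1L]])
  imgs <- lapply(seq_len(nrow(df)), function(i)
    load_image(paths[i], working_size = working_size, id = df$id[i]))
  labeled_dataset(imgs, lab)
}

#' Write a dataset to disk as images plus a CSV manifest
#'
#' @param dataset a [labeled_dataset()].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` (16-bit, lossless at this scale) or `"png"` (8-bit).
#' @return Path to the written `manifest.csv`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stopf("directory not writable: %s", dir)
  files <- paste0(dataset$ids, ".", ext)
  for (i in seq_along(dataset$images))
    save_image(dataset$images[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(id = dataset$ids, path = files,
                       label = dataset$labels),
            manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
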