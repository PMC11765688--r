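#' Fuse reduced feature blocks into the searchable index
#'
#' Horizontally concatenates the blocks in the given order and min-max
#' normalizes every column to `[0, 1]` on the database (a constant column maps
#' to 0). The per-column minima/ranges are stored so queries can be projected
#' into exactly the same space; normalization to `[0, 1]` is also what makes
#' the PSNR similarity's peak value well-defined.
#'
#' @param blocks ordered list of [feature_block()]s sharing image ids and
#'   labels (conventionally HOG, LBP, then deep blocks).
#' @return A `fused_index`: normalized `matrix`, `block_layout`
#'   (descriptor_id, offset, length), `image_ids`, `labels`, `col_min`,
#'   `col_range`, and any per-block `selections`.
#' @export
fuse <- function(blocks) {
  if (!length(blocks)) stopf("at least one block required")
  ids <- blocks[[1L]]$image_ids; labels <- blocks[[1L]]$labels
  for (b in blocks) {
    if (!identical(b$image_ids, ids) || !identical(b$labels, labels))
      stopf("block '%s' does not share image ids/labels with the first block",
            b$descriptor_id)
  }
  widths <- vapply(blocks, function(b) ncol(b$matrix), integer(1))
  layout <- data.frame(
    descriptor_id = vapply(blocks, function(b) b$descriptor_id, character(1)),
    offset = cumsum(c(0L, widths[-length(widths)])),
    length = widths, stringsAsFactors = FALSE)
  X <- do.call(cbind, lapply(blocks, function(b) b$matrix))
  cmin <- apply(X, 2L, min)
  cmax <- apply(X, 2L, max)
  crange <- cmax - cmin
  csafe <- ifelse(crange > 0, crange, 1)
  Xn <- sweep(sweep(X, 2L, cmin, "-"), 2L, csafe, "/")
  Xn[, crange <= 0] <- 0
  Xn <- pmin(pmax(Xn, 0), 1)
  sels <- lapply(blocks, function(b) attr(b, "selection"))
  names(sels) <- layout$descriptor_id
  structure(list(matrix = Xn, block_layout = layout,
                 image_ids = ids, labels = labels,
                 col_min = cmin, col_range = crange,
                 selections = sels, class_names = ACROMION_CLASSES),
            class = "fused_index")
}

#' @export
print.fused_index <- function(x, ...) {
  cat(sprintf("<fused_index: %d images x %d features (%s)>\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", x$block_layout$descriptor_id,
                            x$block_layout$length), collapse = " + ")))
  invisible(x)
}

#' @export
dim.fused_index <- function(x) dim(x$matrix)

#' Project a query image's raw descriptors into the fused index space
#'
#' Applies each block's stored feature selection, concatenates the blocks in
#' the index's layout order, applies the stored min-max normalization, and
#' clips to `[0, 1]`. A database image projected this way reproduces its own
#' index row exactly.
#'
#' @param index a [fuse()]d index.
#' @param raw_blocks named list mapping descriptor_id to the full-length raw
#'   feature vector of the query (as returned by [hog_features()] etc.).
#' @return numeric vector of length `ncol(index$matrix)`.
#' @export
project_query <- function(index, raw_blocks) {
  if (is.null(names(raw_blocks)))
    names(raw_blocks) <- vapply(raw_blocks, function(v)
      attr(v, "descriptor_id") %||% "", character(1))
  parts <- vector("list", nrow(index$block_layout))
  for (i in seq_len(nrow(index$block_layout))) {
    id <- index$block_layout$descriptor_id[i]
    v <- raw_blocks[[id]]
    if (is.null(v)) stopf("query is missing descriptor block '%s'", id)
    sel <- index$selections[[id]]
    if (!is.null(sel)) {
      if (max(sel$chosen) > length(v))
        stopf("descriptor config mismatch for block '%s': raw length %d < selected index %d",
              id, length(v), max(sel$chosen))
      v <- as.numeric(v)[sel$chosen]
    }
    if (length(v) != index$block_layout$length[i])
      stopf("descriptor config mismatch for block '%s': got %d values, index stores %d",
            id, length(v), index$block_layout$length[i])
    parts[[i]] <- as.numeric(v)
  }
  q <- unlist(parts, use.names = FALSE)
  csafe <- ifelse(index$col_range > 0, index$col_range, 1)
  qn <- (q - index$col_min) / csafe
  qn[index$col_range <= 0] <- 0
  pmin(pmax(qn, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a fused index
#'
#' Writes the normalized matrix as little-endian float32 (column-major) to
#' `<path>.bin` and a JSON sidecar `<path>.json` holding the layout,
#' selections, normalization state, ids, labels, and an MD5 checksum of the
#' matrix file. Note float32 storage rounds values by up to ~6e-8.
#'
#' @param index a `fused_index`.
#' @param path basename (without extension) for the two files.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  writeBin(as.vector(index$matrix), con, size = 4L, endian = "little")
  close(con)
  sidecar <- list(
    format = "acromir-index-v1",
    storage = "float32 little-endian column-major",
    n_images = nrow(index$matrix), n_features = ncol(index$matrix),
    block_layout = index$block_layout,
    selections = lapply(index$selections, function(s) if (is.null(s)) NULL
                        else list(chosen = s$chosen, scores = s$scores,
                                  k = s$k, criterion = s$criterion,
                                  bins = s$bins)),
    col_min = index$col_min, col_range = index$col_range,
    image_ids = index$image_ids, labels = index$labels,
    config = if (!is.null(index$config)) config_to_list(index$config),
    checksum_md5 = unname(tools::md5sum(bin)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a persisted fused index
#'
#' Verifies the stored MD5 checksum of the matrix file before reconstructing.
#'
#' @param path basename used in [save_index()].
#' @return A `fused_index`.
#' @export
load_index <- function(path) {
  bin <- paste0(path, ".bin"); side <- paste0(path, ".json")
  if (!file.exists(bin) || !file.exists(side))
    stopf("index files not found at '%s.{bin,json}'", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "acromir-index-v1"))
    stopf("unrecognized index format in %s", side)
  if (!identical(unname(tools::md5sum(bin)), meta$checksum_md5))
    stopf("checksum mismatch: %s is corrupt or was modified", bin)
  n <- meta$n_images; d <- meta$n_features
  con <- file(bin, "rb")
  vals <- readBin(con, "numeric", n = n * d, size = 4L, endian = "little")
  close(con)
  sels <- lapply(meta$selections, function(s) {
    if (is.null(s)) return(NULL)
    structure(list(chosen = as.integer(s$chosen), scores = as.numeric(s$scores),
                   k = as.integer(s$k), criterion = s$criterion,
                   bins = as.integer(s$bins)), class = "selection_result")
  })
  out <- structure(list(matrix = matrix(vals, n, d),
                        block_layout = as.data.frame(meta$block_layout),
                        image_ids = as.character(meta$image_ids),
                        labels = as.integer(meta$labels),
                        col_min = as.numeric(meta$col_min),
                        col_range = as.numeric(meta$col_range),
                        selections = sels, class_names = ACROMION_CLASSES),
                   class = "fused_index")
  if (!is.null(meta$config)) out$config <- list_to_config(meta$config)
  out
}
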