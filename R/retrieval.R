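#' Similarity metric specification
#'
#' Euclidean distance (lower is closer) or PSNR in decibels (higher is
#' closer). PSNR's peak value is fixed at 1.0 because the fused index is
#' min-max normalized per column to `[0, 1]`.
#'
#' @param name `"euclidean"` or `"psnr"`.
#' @return A `metric_spec` with `name`, `direction`, `psnr_peak`.
#' @export
metric_spec <- function(name) {
  supported <- c("euclidean", "psnr")
  if (!is.character(name) || length(name) != 1L || !(name %in% supported))
    stopf("unsupported metric '%s'; supported metrics: %s",
          as.character(name)[1L], paste(supported, collapse = ", "))
  structure(list(name = name,
                 direction = if (name == "euclidean") "lower_is_closer"
                             else "higher_is_closer",
                 psnr_peak = 1.0),
            class = "metric_spec")
}

#' Euclidean distance between feature vectors
#' @param a,b equal-length numeric vectors.
#' @return non-negative distance.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch: %d vs %d",
                                    length(a), length(b))
  sqrt(sum((a - b)^2))
}

#' PSNR similarity between feature vectors (dB)
#'
#' `10 * log10(peak^2 / MSE)` with `MSE` the mean squared difference.
#' Identical vectors give `+Inf` (and rank first). Values must lie in
#' `[0, peak]`, the normalized fused-index space.
#'
#' @param a,b equal-length numeric vectors in `[0, 1]`.
#' @param peak peak signal value (1.0 in the normalized index space).
#' @return similarity in decibels.
#' @export
psnr_similarity <- function(a, b, peak = 1.0) {
  if (length(a) != length(b)) stopf("length mismatch: %d vs %d",
                                    length(a), length(b))
  tol <- 1e-9
  if (min(a, b) < -tol || max(a, b) > peak + tol)
    stopf("PSNR inputs must lie in [0, %g]", peak)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Rank database images against a query
#'
#' Scores every candidate row of the index (optionally excluding the query's
#' own id), sorts by the metric's direction with ties broken by ascending
#' image id, and truncates to the top `k`.
#'
#' @param index a [fuse()]d index.
#' @param query numeric vector of length `ncol(index$matrix)` (see
#'   [project_query()]).
#' @param metric a [metric_spec()] or metric name.
#' @param k number of neighbors to return (default 20, the query protocol the
#'   pipeline is evaluated under).
#' @param exclude_id optional image id removed from the candidates
#'   (leave-one-out querying).
#' @param query_id,query_label bookkeeping fields carried into the result.
#' @return A `ranked_retrieval` with an `entries` data frame
#'   (`rank, image_id, label, score`).
#' @export
rank_index <- function(index, query, metric = "euclidean", k = 20L,
                       exclude_id = NULL, query_id = "query",
                       query_label = NA_integer_) {
  if (!inherits(metric, "metric_spec")) metric <- metric_spec(metric)
  D <- ncol(index$matrix)
  if (length(query) != D)
    stopf("query length %d does not match index dimension %d",
          length(query), D)
  if (!is_count(k)) stopf("k must be a positive integer")
  keep <- if (is.null(exclude_id)) rep(TRUE, nrow(index$matrix))
          else index$image_ids != exclude_id
  M <- index$matrix[keep, , drop = FALSE]
  ids <- index$image_ids[keep]
  labels <- index$labels[keep]
  d2 <- rowSums(sweep(M, 2L, as.numeric(query), "-")^2)
  score <- if (metric$name == "euclidean") sqrt(d2) else {
    mse <- d2 / D
    ifelse(mse == 0, Inf, 10 * log10(metric$psnr_peak^2 / mse))
  }
  key <- if (metric$direction == "lower_is_closer") score else -score
  ord <- order(key, ids)
  ord <- ord[seq_len(min(k, length(ord)))]
  structure(list(query_id = query_id, query_label = query_label,
                 entries = data.frame(rank = seq_along(ord),
                                      image_id = ids[ord],
                                      label = labels[ord],
                                      score = score[ord],
                                      stringsAsFactors = FALSE),
                 k = as.integer(k), metric = metric,
                 excluded_self = !is.null(exclude_id)),
            class = "ranked_retrieval")
}

#' @export
print.ranked_retrieval <- function(x, ...) {
  cat(sprintf("<ranked_retrieval: query '%s', %d of k=%d by %s>\n",
              x$query_id, nrow(x$entries), x$k, x$metric$name))
  print(utils::head(x$entries, 5L))
  if (nrow(x$entries) > 5L) cat("...\n")
  invisible(x)
}
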