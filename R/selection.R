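#' Feature block: one descriptor's matrix over a dataset
#'
#' @param matrix numeric `n_images x d` matrix, finite.
#' @param descriptor_id descriptor tag (`"hog"`, `"lbp"`, `"deep:<name>"`).
#' @param image_ids,labels per-row ids and class labels.
#' @return A `feature_block`.
#' @export
feature_block <- function(matrix, descriptor_id, image_ids, labels) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stopf("matrix required")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stopf("block '%s' contains non-finite entries", descriptor_id)
  if (nrow(matrix) != length(image_ids) || nrow(matrix) != length(labels))
    stopf("row count must match image_ids and labels")
  structure(list(matrix = matrix, descriptor_id = descriptor_id,
                 image_ids = as.character(image_ids),
                 labels = as.integer(labels)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block '%s': %d images x %d features>\n",
              x$descriptor_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Equal-width discretization of a numeric column
#'
#' Bins span `[min, max]` of the column; lower bins are half-open and the top
#' bin is closed, so the maximum maps to `bins - 1`. A constant column maps to
#' all zeros.
#'
#' @param column numeric vector.
#' @param bins number of bins (>= 2).
#' @return integer vector of bin codes in `0:(bins-1)`.
#' @export
discretize <- function(column, bins) {
  if (!is_count(bins) || bins < 2) stopf("bins must be an integer >= 2")
  lo <- min(column); hi <- max(column)
  if (hi <= lo) return(integer(length(column)))
  b <- floor((column - lo) / (hi - lo) * bins)
  as.integer(pmin(pmax(b, 0), bins - 1))
}

#' Plug-in mutual information between two discrete vectors (nats)
#'
#' Empirical estimator from the joint contingency table:
#' `sum p(x,y) * log(p(x,y) / (p(x) p(y)))`. Symmetric and non-negative.
#'
#' @param x,y equal-length vectors of discrete codes (integers or factors).
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) == 0L) stopf("empty input")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log(pxy / outer(px, py))
  max(sum(terms[pxy > 0]), 0)
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' Columns are discretized with equal-width bins; relevance is the mutual
#' information of a feature with the class labels and redundancy the mean
#' mutual information with the already-chosen features. The first pick
#' maximizes relevance alone; each subsequent pick maximizes
#' `relevance - mean_redundancy` (MID, the original difference form) or
#' `relevance / mean_redundancy` (MIQ, mean redundancy floored at a small
#' epsilon). Ties break to the lowest column index, so selection is fully
#' deterministic.
#'
#' @param block a [feature_block()].
#' @param k number of features to select, `1 <= k <= ncol`.
#' @param criterion `"MID"` or `"MIQ"`.
#' @param bins discretization bin count.
#' @return A `selection_result`: `chosen` (1-based column indices in selection
#'   order), `scores` (criterion value at each step), `k`, `criterion`,
#'   `bins`.
#' @export
mrmr_select <- function(block, k, criterion = c("MID", "MIQ"), bins = 10L) {
  criterion <- match.arg(criterion)
  d <- ncol(block$matrix)
  if (!is_count(k) || k < 1 || k > d) stopf("k must be in 1..%d", d)
  if (!is_count(bins) || bins < 2) stopf("bins must be >= 2")
  D <- .discretize_matrix(block$matrix, as.integer(bins))
  yf <- factor(block$labels)
  y <- as.integer(yf) - 1L
  rel <- .mi_columns_ref(D, y, as.integer(bins), nlevels(yf))

  chosen <- integer(k); scores <- numeric(k)
  chosen[1L] <- which.max(rel)        # which.max takes the lowest index on ties
  scores[1L] <- rel[chosen[1L]]
  if (k > 1L) {
    active <- rep(TRUE, d); active[chosen[1L]] <- FALSE
    redsum <- numeric(d)
    eps <- 1e-10
    for (step in 2:k) {
      redsum <- redsum + .mi_columns_ref(D, D[, chosen[step - 1L]],
                                         as.integer(bins), as.integer(bins))
      mred <- redsum / (step - 1L)
      sc <- if (criterion == "MID") rel - mred else rel / pmax(mred, eps)
      sc[!active] <- -Inf
      j <- which.max(sc)
      chosen[step] <- j; scores[step] <- sc[j]; active[j] <- FALSE
    }
  }
  structure(list(chosen = chosen, scores = scores, k = as.integer(k),
                 criterion = criterion, bins = as.integer(bins)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d features, %s, %d bins>\n",
              x$k, x$criterion, x$bins))
  invisible(x)
}

#' Reduce a feature block to its selected columns
#'
#' @param block a [feature_block()].
#' @param sel a `selection_result` (or list with `chosen`).
#' @return A [feature_block()] whose columns are `sel$chosen`, in selection
#'   order, carrying the selection as attribute `selection`.
#' @export
reduce_block <- function(block, sel) {
  idx <- sel$chosen
  if (any(idx < 1L | idx > ncol(block$matrix)))
    stopf("selection index out of range for block '%s'", block$descriptor_id)
  out <- feature_block(block$matrix[, idx, drop = FALSE], block$descriptor_id,
                       block$image_ids, block$labels)
  attr(out, "selection") <- sel
  out
}
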