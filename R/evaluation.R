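#' Precision-recall points of one ranked retrieval
#'
#' One point per rank at which a relevant (same-class) image appears:
#' precision is relevant-so-far over rank, recall is relevant-so-far over the
#' recall denominator R. By default R is the number of relevant images within
#' the retrieved list ("retrieved"), so recall reaches 1.0 at the retrieval
#' depth; with `denominator = "database"` R is the number of same-class images
#' in the database (minus the query), which must be supplied.
#'
#' @param retrieval a [rank_index()] result.
#' @param query_label class of the query; retrieved images of this class are
#'   relevant.
#' @param denominator `"retrieved"` (default) or `"database"`.
#' @param relevant_in_db required when `denominator = "database"`.
#' @return data frame with columns `rank`, `recall`, `precision` (possibly
#'   zero rows when nothing relevant was retrieved).
#' @export
pr_points <- function(retrieval, query_label,
                      denominator = c("retrieved", "database"),
                      relevant_in_db = NULL) {
  denominator <- match.arg(denominator)
  entries <- retrieval$entries
  if (nrow(entries) == 0L) stopf("retrieval is empty")
  rel <- entries$label == query_label
  cum <- cumsum(rel)
  R <- if (denominator == "retrieved") sum(rel) else {
    if (is.null(relevant_in_db))
      stopf("relevant_in_db is required when denominator = \"database\"")
    relevant_in_db
  }
  at <- which(rel)
  if (R == 0L || length(at) == 0L)
    return(data.frame(rank = integer(0), recall = numeric(0),
                      precision = numeric(0)))
  data.frame(rank = at, recall = cum[at] / R, precision = cum[at] / at)
}

PR_GRID <- (0:10) / 10

#' Interpolated 11-point precision-recall curve and average precision
#'
#' At each grid recall g in 0.0, 0.1, ..., 1.0 the interpolated precision is
#' the maximum precision over all observed points with recall >= g (zero when
#' no such point exists, hence an all-zero curve and AP 0 for a query that
#' retrieved nothing relevant). AP is the arithmetic mean of the 11 values.
#'
#' @param points data frame from [pr_points()].
#' @return A `pr_curve`: `recall_grid`, `precision` (11 non-increasing
#'   values), `ap`.
#' @export
interpolate_11pt <- function(points) {
  prec <- vapply(PR_GRID, function(g) {
    ok <- points$recall >= g - 1e-9
    if (any(ok)) max(points$precision[ok]) else 0
  }, numeric(1))
  structure(list(recall_grid = PR_GRID, precision = prec, ap = mean(prec)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: AP = %.4f>\n", x$ap))
  print(round(stats::setNames(x$precision, format(x$recall_grid)), 3))
  invisible(x)
}

#' Plot an interpolated precision-recall curve
#' @param x a `pr_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$recall_grid, x$precision, type = "b", pch = 16,
                 xlab = "Recall", ylab = "Interpolated precision",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Pointwise average of interpolated precision-recall curves
#'
#' The AP of the averaged curve equals the mean of the individual APs
#' (averaging is linear).
#'
#' @param curves nonempty list of `pr_curve`s.
#' @return A `pr_curve`.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stopf("empty curve list")
  P <- vapply(curves, function(cv) cv$precision, numeric(length(PR_GRID)))
  prec <- rowMeans(P)
  structure(list(recall_grid = PR_GRID, precision = prec, ap = mean(prec)),
            class = "pr_curve")
}

#' Leave-one-out retrieval evaluation of a fused index
#'
#' Every database image is queried against the rest (self excluded), the top
#' `k` are retrieved per metric, and interpolated 11-point curves are averaged
#' per class and over all queries. Class-level AP is the mean over that
#' class's queries; dataset AP the unweighted mean over all queries. Queries
#' retrieving nothing relevant contribute AP = 0 rather than being dropped.
#'
#' @param index a labeled [fuse()]d index.
#' @param metrics character vector of metric names.
#' @param k retrieval depth per query.
#' @param denominator recall denominator convention, see [pr_points()].
#' @return An `evaluation_report`: `per_class_ap` (metric x class matrix),
#'   `dataset_ap`, per-class and dataset `pr_curve`s, `k`, `n_queries`,
#'   `total_listed`, `per_class_listed`.
#' @export
evaluate_index <- function(index, metrics = c("euclidean", "psnr"), k = 20L,
                           denominator = c("retrieved", "database")) {
  denominator <- match.arg(denominator)
  if (is.null(index$labels) || !length(index$labels))
    stopf("index is unlabeled; evaluation needs class labels")
  n <- nrow(index$matrix)
  classes <- sort(unique(index$labels))
  per_class_ap <- matrix(NA_real_, length(metrics), 4,
                         dimnames = list(metrics, names(ACROMION_CLASSES)))
  dataset_ap <- stats::setNames(numeric(length(metrics)), metrics)
  per_class_curves <- stats::setNames(vector("list", length(metrics)), metrics)
  dataset_curves <- stats::setNames(vector("list", length(metrics)), metrics)
  total_listed <- 0L
  class_tab <- table(factor(index$labels, levels = 1:4))
  for (m in metrics) {
    spec <- metric_spec(m)
    curves <- vector("list", n)
    for (i in seq_len(n)) {
      rr <- rank_index(index, index$matrix[i, ], spec, k = k,
                       exclude_id = index$image_ids[i],
                       query_id = index$image_ids[i],
                       query_label = index$labels[i])
      if (m == metrics[[1L]]) total_listed <- total_listed + nrow(rr$entries)
      pts <- pr_points(rr, index$labels[i], denominator = denominator,
                       relevant_in_db = as.integer(class_tab[index$labels[i]]) - 1L)
      curves[[i]] <- interpolate_11pt(pts)
    }
    for (cls in classes) {
      cc <- curves[index$labels == cls]
      per_class_curves[[m]][[as.character(cls)]] <- average_curves(cc)
      per_class_ap[m, as.character(cls)] <- per_class_curves[[m]][[
        as.character(cls)]]$ap
    }
    dataset_curves[[m]] <- average_curves(curves)
    dataset_ap[m] <- dataset_curves[[m]]$ap
  }
  structure(list(per_class_ap = per_class_ap, dataset_ap = dataset_ap,
                 per_class_curves = per_class_curves,
                 dataset_curves = dataset_curves,
                 k = as.integer(k), n_queries = n,
                 total_listed = as.integer(total_listed),
                 per_class_listed = stats::setNames(
                   as.integer(class_tab) * as.integer(k),
                   names(ACROMION_CLASSES)),
                 denominator = denominator,
                 class_names = ACROMION_CLASSES),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d queries, k = %d, %d listed (%s recall)>\n",
              x$n_queries, x$k, x$total_listed, x$denominator))
  ap <- cbind(x$per_class_ap, dataset = x$dataset_ap)
  colnames(ap)[1:4] <- paste0(colnames(x$per_class_ap), " (",
                              x$class_names, ")")
  print(round(ap, 4))
  invisible(x)
}
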