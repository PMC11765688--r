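# Shared fixtures, all generated in code. Heavy objects are memoised in a
# session-local environment so independent test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small working configuration: 64-px images, modest reductions
tiny_config <- function(counts = c(6L, 6L, 6L, 6L), seed = 11L, k = 5L,
                        noise_sd = 0.05) {
  pipeline_config(
    working_size = 64,
    # translation jitter scales with resolution (about 3 px at 224 ~ 1 px
    # at 64); rotation is resolution-independent
    phantom = phantom_config(class_counts = counts, image_size = 64,
                             noise_sd = noise_sd, jitter_px = 1,
                             seed = seed),
    reduce = list(hog = 30L, lbp = 40L, `deep:pool32` = 20L,
                  `deep:gradpool32` = 20L),
    k = k)
}

tiny_dataset <- function() memo("tiny_ds", function()
  generate_phantoms(tiny_config()$phantom))

tiny_index <- function() memo("tiny_idx", function()
  suppressMessages(build_index(tiny_dataset(), tiny_config())))

# full-scale study conditions: 748 phantoms at 224 px, HOG+LBP+two deep
# stand-ins reduced to 400/500/400/400. Built once per test run.
full_config <- function() pipeline_config(seed = 20260920L,
                                          phantom = phantom_config(seed = 101L))

full_dataset <- function() memo("full_ds", function()
  generate_phantoms(full_config()$phantom))

full_blocks <- function() memo("full_blocks", function()
  suppressMessages(acromir:::extract_blocks(full_dataset(), full_config())))

full_reduced_blocks <- function() memo("full_reduced", function() {
  cfg <- full_config()
  lapply(full_blocks(), function(b) {
    sel <- mrmr_select(b, cfg$reduce[[b$descriptor_id]], cfg$criterion,
                       cfg$bins)
    reduce_block(b, sel)
  })
})

full_index <- function() memo("full_idx", function() {
  idx <- fuse(unname(full_reduced_blocks()))
  idx$config <- full_config()
  idx
})

# HOG+LBP-only fusion of the same fitted blocks
texture_index <- function() memo("texture_idx", function()
  fuse(unname(full_reduced_blocks()[c("hog", "lbp")])))

full_evaluation <- function() memo("full_eval", function()
  evaluate_index(full_index(), metrics = c("euclidean", "psnr"), k = 20L))

# independent stepwise mRMR oracle: re-evaluates the greedy criterion from
# scratch at every step with the plain-R estimator, over all remaining
# candidates
oracle_mrmr <- function(X, labels, k, criterion = "MID", bins = 4L) {
  d <- ncol(X)
  D <- vapply(seq_len(d), function(j) discretize(X[, j], bins),
              integer(nrow(X)))
  rel <- vapply(seq_len(d), function(j) mutual_information(D[, j], labels),
                numeric(1))
  chosen <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf; pick <- NA_integer_
    for (j in seq_len(d)) {
      if (j %in% chosen) next
      sc <- if (step == 1) rel[j] else {
        red <- mean(vapply(chosen, function(c)
          mutual_information(D[, j], D[, c]), numeric(1)))
        if (criterion == "MID") rel[j] - red else rel[j] / max(red, 1e-10)
      }
      if (sc > best + 1e-12) { best <- sc; pick <- j }
    }
    chosen <- c(chosen, pick)
  }
  chosen
}

# plain-R criterion scores of every remaining candidate given an
# already-chosen set (NA for chosen columns); used to verify per-step
# optimality of the greedy selection against exhaustive evaluation
oracle_step_scores <- function(X, labels, chosen, criterion = "MID",
                               bins = 4L) {
  d <- ncol(X)
  D <- vapply(seq_len(d), function(j) discretize(X[, j], bins),
              integer(nrow(X)))
  sc <- rep(NA_real_, d)
  for (j in setdiff(seq_len(d), chosen)) {
    rel <- mutual_information(D[, j], labels)
    sc[j] <- if (!length(chosen)) rel else {
      red <- mean(vapply(chosen, function(c)
        mutual_information(D[, j], D[, c]), numeric(1)))
      if (criterion == "MID") rel - red else rel / max(red, 1e-10)
    }
  }
  sc
}

# independent brute-force 11-point interpolation oracle: max precision over
# all points at recall >= g, by direct scanning
oracle_11pt <- function(points) {
  prec <- numeric(11)
  for (i in 0:10) {
    g <- i / 10
    best <- 0
    if (nrow(points)) for (r in seq_len(nrow(points)))
      if (points$recall[r] >= g - 1e-9 && points$precision[r] > best)
        best <- points$precision[r]
    prec[i + 1] <- best
  }
  list(precision = prec, ap = mean(prec))
}

# PR points straight from a 0/1 relevance pattern (denominator "retrieved")
pattern_points <- function(pattern) {
  cum <- cumsum(pattern)
  at <- which(pattern == 1)
  R <- sum(pattern)
  if (R == 0) return(data.frame(rank = integer(0), recall = numeric(0),
                                precision = numeric(0)))
  data.frame(rank = at, recall = cum[at] / R, precision = cum[at] / at)
}

# build a ranked_retrieval-shaped object from a relevance pattern
pattern_retrieval <- function(pattern, query_label = 1L) {
  labels <- ifelse(pattern == 1, query_label, query_label + 1L)
  structure(list(query_id = "q", query_label = query_label,
                 entries = data.frame(
                   rank = seq_along(pattern),
                   image_id = sprintf("im%02d", seq_along(pattern)),
                   label = as.integer(labels),
                   score = seq_along(pattern)),
                 k = length(pattern),
                 metric = metric_spec("euclidean"), excluded_self = TRUE),
            class = "ranked_retrieval")
}
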