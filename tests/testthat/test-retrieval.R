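test_that("euclidean distance matches closed forms and metric axioms", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(3, 4), c(0, 0)), 5)
  expect_error(euclidean_distance(1:3, 1:2), "length mismatch")
  set.seed(17)
  for (i in 1:1000) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    dab <- euclidean_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, euclidean_distance(b, a), tolerance = 1e-12)
    expect_lte(dab, euclidean_distance(a, c) + euclidean_distance(c, b) +
                 1e-12)
  }
})

test_that("PSNR matches closed forms, with +Inf for exact duplicates", {
  expect_identical(psnr_similarity(c(0.2, 0.8), c(0.2, 0.8)), Inf)
  expect_equal(psnr_similarity(c(1, 0), c(0, 1)), 0)            # MSE = 1
  expect_equal(psnr_similarity(c(0.5, 0.5), c(0, 0)), 10 * log10(4),
               tolerance = 1e-12)                               # ~6.0206 dB
  expect_equal(psnr_similarity(c(0.5, 0.5), c(0, 0)), 6.0206, tolerance = 1e-4)
  expect_equal(psnr_similarity(c(0.3, 0.4), c(0.5, 0.1)),
               psnr_similarity(c(0.5, 0.1), c(0.3, 0.4)))       # symmetric
  expect_error(psnr_similarity(c(1.2, 0), c(0, 1)), "\\[0, 1\\]")
  expect_error(psnr_similarity(c(0.1, 0.2, 0.3), c(0.1, 0.2)),
               "length mismatch")
})

test_that("metric specs pair each name with its direction", {
  expect_identical(metric_spec("euclidean")$direction, "lower_is_closer")
  eu <- metric_spec("psnr")
  expect_identical(eu$direction, "higher_is_closer")
  expect_identical(eu$psnr_peak, 1.0)
  expect_error(metric_spec("cosine"), "supported metrics: euclidean, psnr")
})

# a 5-point index with hand-checkable geometry
toy_index <- function() {
  M <- rbind(c(0.0, 0.0), c(0.1, 0.0), c(0.5, 0.5), c(1.0, 1.0), c(0.0, 0.1))
  b <- feature_block(M, "toy", paste0("p", 1:5), c(1L, 1L, 2L, 2L, 1L))
  idx <- fuse(list(b))
  idx$matrix <- M   # keep raw coordinates for hand-checked distances
  idx$col_min <- c(0, 0); idx$col_range <- c(1, 1)
  idx
}

test_that("ranking matches an exhaustive sort oracle on a 5-point index", {
  idx <- toy_index()
  q <- c(0.05, 0.0)
  rr <- rank_index(idx, q, "euclidean", k = 5L)
  d <- apply(idx$matrix, 1, function(r) euclidean_distance(r, q))
  oracle <- idx$image_ids[order(d, idx$image_ids)]
  expect_identical(rr$entries$image_id, oracle)
  expect_equal(rr$entries$score, sort(d), tolerance = 1e-12)
  # and PSNR produces the same ordering on equal-length vectors
  rp <- rank_index(idx, q, "psnr", k = 5L)
  expect_identical(rp$entries$image_id, rr$entries$image_id)
})

test_that("a database image ranks itself first without self-exclusion", {
  idx <- toy_index()
  for (m in c("euclidean", "psnr")) {
    rr <- rank_index(idx, idx$matrix[3, ], m, k = 5L)
    expect_identical(rr$entries$image_id[1], "p3")
  }
  rp <- rank_index(idx, idx$matrix[3, ], "psnr", k = 5L)
  expect_identical(rp$entries$score[1], Inf)
  # with self-exclusion the id disappears entirely
  rx <- rank_index(idx, idx$matrix[3, ], "euclidean", k = 5L,
                   exclude_id = "p3")
  expect_false("p3" %in% rx$entries$image_id)
  expect_identical(nrow(rx$entries), 4L)
})

test_that("k beyond the candidate count returns everything sorted", {
  idx <- toy_index()
  rr <- rank_index(idx, c(0.2, 0.2), "euclidean", k = 50L)
  expect_identical(nrow(rr$entries), 5L)
  expect_true(!is.unsorted(rr$entries$score))
})

test_that("ranking is invariant to permuting the index rows", {
  set.seed(30)
  n <- 20
  M <- matrix(runif(n * 6), n)
  b <- feature_block(M, "toy", sprintf("x%02d", 1:n),
                     rep(1:4, each = 5))
  idx <- fuse(list(b))
  q <- runif(6)
  rr1 <- rank_index(idx, q, "euclidean", k = 10L)
  perm <- sample(n)
  idx2 <- idx
  idx2$matrix <- idx$matrix[perm, ]
  idx2$image_ids <- idx$image_ids[perm]
  idx2$labels <- idx$labels[perm]
  rr2 <- rank_index(idx2, q, "euclidean", k = 10L)
  expect_identical(rr1$entries, rr2$entries)
})

test_that("ties break deterministically by ascending image id", {
  M <- rbind(c(0, 0), c(0, 0), c(1, 1))
  b <- feature_block(M, "toy", c("b_id", "a_id", "c_id"), c(1L, 1L, 2L))
  idx <- fuse(list(b))
  idx$matrix <- M; idx$col_min <- c(0, 0); idx$col_range <- c(1, 1)
  rr <- rank_index(idx, c(0, 0), "euclidean", k = 3L)
  expect_identical(rr$entries$image_id, c("a_id", "b_id", "c_id"))
})

test_that("dimension mismatches are rejected", {
  idx <- toy_index()
  expect_error(rank_index(idx, c(0.1, 0.2, 0.3), "euclidean"),
               "does not match index dimension")
})
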