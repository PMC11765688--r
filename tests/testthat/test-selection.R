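test_that("equal-width discretization follows the stated conventions", {
  expect_identical(discretize(c(0, 0.5, 1), 2L), c(0L, 1L, 1L))
  expect_identical(discretize(rep(3.7, 5), 8L), integer(5))
  set.seed(10)
  x <- runif(200)
  b <- discretize(x, 10L)
  expect_true(all(b %in% 0:9))
  expect_identical(length(b), 200L)            # every value in exactly one bin
  expect_identical(sum(tabulate(b + 1L, 10L)), 200L)
})

test_that("plug-in mutual information matches hand calculations", {
  x <- rep(c(0L, 1L), 10)
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(rep(1L, 20), x), 0)
  # joint counts ((2,1),(1,2)) over 6 samples, evaluated by hand:
  # (2/3) ln(4/3) - (1/3) ln(3/2) = 0.0566330...
  x2 <- c(0L, 0L, 0L, 1L, 1L, 1L)
  y2 <- c(0L, 0L, 1L, 0L, 1L, 1L)
  expect_equal(mutual_information(x2, y2),
               2 * (2 / 6) * log((2 / 6) / 0.25) +
               2 * (1 / 6) * log((1 / 6) / 0.25), tolerance = 1e-12)
  expect_equal(mutual_information(x2, y2), 0.05663301, tolerance = 1e-7)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information is symmetric and non-negative", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- sample(0:3, 40, replace = TRUE)
    y <- sample(0:2, 40, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
  }
})

test_that("compiled MI and discretization kernels match the R reference", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 7), 60, 7)
    X[, 7] <- 1.5                                # constant column
    bins <- 5L
    D <- acromir:::.discretize_matrix(X, bins)
    Dref <- vapply(1:7, function(j) discretize(X[, j], bins), integer(60))
    expect_identical(D, Dref)
    y <- sample(0:3, 60, replace = TRUE)
    mi <- acromir:::.mi_columns_ref(D, y, bins, 4L)
    miref <- vapply(1:7, function(j) mutual_information(D[, j], y),
                    numeric(1))
    expect_equal(mi, miref, tolerance = 1e-12)
  }
})

test_that("greedy selection matches the exhaustive stepwise oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- 30L
    d <- sample(3:8, 1)
    k <- sample(1:min(3, d), 1)
    labels <- sample(1:4, n, replace = TRUE)
    X <- matrix(rnorm(n * d), n, d)
    X[, 1] <- labels + rnorm(n, sd = 0.3)        # make something informative
    crit <- if (seed %% 3 == 0) "MIQ" else "MID"
    blk <- feature_block(X, "toy", sprintf("i%02d", 1:n), labels)
    sel <- mrmr_select(blk, k, criterion = crit, bins = 4L)
    expect_identical(sel$chosen, oracle_mrmr(X, labels, k, crit, 4L),
                     info = sprintf("seed %d", seed))
    expect_identical(length(unique(sel$chosen)), as.integer(k))
  }
})

test_that("an exact duplicate feature is never selected twice under MID", {
  labels <- rep(1:4, each = 10)
  f <- as.numeric(labels %in% c(1, 2))
  g <- as.numeric(labels %in% c(1, 3))
  blk <- feature_block(cbind(f, dup = f, g), "toy",
                       sprintf("i%02d", seq_along(labels)), labels)
  sel <- mrmr_select(blk, 2L, "MID", bins = 4L)
  expect_identical(sel$chosen, c(1L, 3L))        # f then g, never the dup
})

test_that("degenerate selection sizes behave as stated", {
  set.seed(44)
  labels <- sample(1:4, 30, replace = TRUE)
  X <- matrix(rnorm(30 * 5), 30, 5)
  blk <- feature_block(X, "toy", sprintf("i%02d", 1:30), labels)
  s1 <- mrmr_select(blk, 1L, bins = 4L)
  rel <- vapply(1:5, function(j)
    mutual_information(discretize(X[, j], 4L), labels), numeric(1))
  expect_identical(s1$chosen, which.max(rel))
  sd_ <- mrmr_select(blk, 5L, bins = 4L)
  expect_identical(sort(sd_$chosen), 1:5)
  expect_error(mrmr_select(blk, 6L), "k must be")
  expect_error(mrmr_select(blk, 0L), "k must be")
})

test_that("reduce_block subsets columns in selection order, idempotently", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  blk <- feature_block(X, "toy", sprintf("i%02d", 1:20),
                       rep(1:4, each = 5))
  one <- reduce_block(blk, list(chosen = 1L))
  expect_equal(one$matrix, X[, 1, drop = FALSE], ignore_attr = TRUE)
  sel <- list(chosen = c(5L, 2L))
  red <- reduce_block(blk, sel)
  expect_equal(red$matrix, X[, c(5, 2)], ignore_attr = TRUE)
  expect_identical(red$descriptor_id, "toy")
  ident <- list(chosen = seq_len(ncol(red$matrix)))
  expect_equal(reduce_block(red, ident)$matrix, red$matrix)
  expect_error(reduce_block(blk, list(chosen = 9L)), "out of range")
})
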