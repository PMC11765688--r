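test_that("precision-recall points follow direct counting", {
  # 20 retrieved, 15 relevant: precision at depth 20 is 0.75
  set.seed(1)
  pat <- sample(c(rep(1, 15), rep(0, 5)))
  pts <- pr_points(pattern_retrieval(pat), 1L)
  expect_equal(pts$precision[nrow(pts)], 15 / 20)
  expect_equal(pts$recall[nrow(pts)], 1)

  # all K relevant: points (r/K, 1)
  pts <- pr_points(pattern_retrieval(rep(1, 5)), 1L)
  expect_equal(pts$recall, (1:5) / 5)
  expect_equal(pts$precision, rep(1, 5))

  # the worked (1,0,1,0,1) pattern
  pts <- pr_points(pattern_retrieval(c(1, 0, 1, 0, 1)), 1L)
  expect_equal(pts$recall, c(1 / 3, 2 / 3, 1))
  expect_equal(pts$precision, c(1, 2 / 3, 3 / 5))
})

test_that("the database recall denominator divides by relevant-in-database", {
  pts <- pr_points(pattern_retrieval(c(1, 0, 1, 0, 1)), 1L,
                   denominator = "database", relevant_in_db = 10L)
  expect_equal(pts$recall, c(1, 2, 3) / 10)
  expect_error(pr_points(pattern_retrieval(c(1, 0)), 1L,
                         denominator = "database"), "relevant_in_db")
})

test_that("11-point interpolation reproduces hand-derived curves", {
  # single point (recall 1, precision 1)
  cv <- interpolate_11pt(data.frame(rank = 1, recall = 1, precision = 1))
  expect_equal(cv$precision, rep(1, 11))
  expect_equal(cv$ap, 1)

  # nothing relevant retrieved: all-zero curve, AP 0
  cv <- interpolate_11pt(pr_points(pattern_retrieval(rep(0, 5)), 1L))
  expect_equal(cv$precision, rep(0, 11))
  expect_equal(cv$ap, 0)

  # the worked (1,0,1,0,1) pattern: (1 x4, 2/3 x3, 3/5 x4), AP = 8.4/11
  cv <- interpolate_11pt(pr_points(pattern_retrieval(c(1, 0, 1, 0, 1)), 1L))
  expect_equal(cv$precision,
               c(rep(1, 4), rep(2 / 3, 3), rep(3 / 5, 4)), tolerance = 1e-12)
  expect_equal(cv$ap, 8.4 / 11, tolerance = 1e-12)
  expect_equal(cv$ap, 0.7636, tolerance = 1e-4)
})

test_that("interpolation agrees with the brute-force oracle on 1000 random patterns", {
  set.seed(77)
  for (i in 1:1000) {
    K <- sample(1:25, 1)
    pat <- rbinom(K, 1, runif(1))
    pts <- pattern_points(pat)
    got <- interpolate_11pt(pts)
    ora <- oracle_11pt(pts)
    expect_equal(got$precision, ora$precision, tolerance = 1e-12)
    expect_equal(got$ap, ora$ap, tolerance = 1e-12)
    # monotone non-increasing along the recall grid
    expect_true(all(diff(got$precision) <= 1e-12))
  }
})

test_that("curve averaging is linear in AP", {
  mk <- function(pat) interpolate_11pt(pattern_points(pat))
  same <- average_curves(list(mk(c(1, 0, 1)), mk(c(1, 0, 1))))
  expect_equal(same$precision, mk(c(1, 0, 1))$precision)
  half <- average_curves(list(mk(rep(1, 4)), mk(rep(0, 4))))
  expect_equal(half$ap, 0.5)
  set.seed(3)
  curves <- lapply(1:10, function(i) mk(rbinom(10, 1, 0.5)))
  avg <- average_curves(curves)
  expect_equal(avg$ap, mean(vapply(curves, `[[`, numeric(1), "ap")),
               tolerance = 1e-12)
  expect_error(average_curves(list()), "empty")
})

test_that("leave-one-out evaluation books exactly n x k retrievals", {
  idx <- tiny_index()                 # 24 images
  rep <- evaluate_index(idx, metrics = "euclidean", k = 5L)
  expect_identical(rep$total_listed, 24L * 5L)
  expect_identical(rep$n_queries, 24L)
  expect_identical(unname(rep$per_class_listed), rep(6L * 5L, 4))
  expect_true(all(rep$per_class_ap >= 0 & rep$per_class_ap <= 1))
})

test_that("exact duplicate clusters larger than k give AP 1 everywhere", {
  n_per <- 6; k <- 4
  M <- do.call(rbind, lapply(1:4, function(cls)
    matrix(rep(c(cls / 4, 1 - cls / 4), each = n_per), n_per)))
  b <- feature_block(M, "toy", sprintf("d%02d", 1:(4 * n_per)),
                     rep(1:4, each = n_per))
  idx <- fuse(list(b))
  for (m in c("euclidean", "psnr")) {
    rep <- evaluate_index(idx, metrics = m, k = k)
    expect_equal(unname(rep$per_class_ap[m, ]), rep(1, 4))
    expect_equal(unname(rep$dataset_ap[m]), 1)
  }
})

test_that("euclidean and PSNR rankings coincide, hence equal APs", {
  idx <- tiny_index()
  rep <- evaluate_index(idx, metrics = c("euclidean", "psnr"), k = 5L)
  expect_equal(rep$per_class_ap["euclidean", ], rep$per_class_ap["psnr", ],
               tolerance = 1e-12)
  expect_equal(unname(rep$dataset_ap["euclidean"]),
               unname(rep$dataset_ap["psnr"]), tolerance = 1e-12)
})

test_that("an unlabeled index cannot be evaluated", {
  idx <- tiny_index()
  idx$labels <- integer(0)
  expect_error(evaluate_index(idx), "unlabeled")
})
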