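test_that("mutual information reproduces closed forms", {
  a <- rep(0:1, 500)
  expect_equal(mutual_information(a, a), log(2), tolerance = 1e-12)
  # MI(a, a) = H(a) for a skewed discrete variable
  b <- rep(c(0, 0, 0, 1), 250)
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(mutual_information(b, b), H, tolerance = 1e-12)
  # closed form for a printed 2x2 joint table: counts (40, 10; 10, 40)
  x <- rep(c(0, 0, 1, 1), times = c(40, 10, 10, 40))
  y <- rep(c(0, 1, 0, 1), times = c(40, 10, 10, 40))
  p <- c(0.4, 0.1, 0.1, 0.4)
  mi_closed <- sum(p * log(p / c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(mutual_information(x, y), mi_closed, tolerance = 1e-12)
})

test_that("mutual information is symmetric, non-negative, near zero under independence", {
  set.seed(12)
  worst <- 0
  for (i in 1:20) {
    a <- sample(0:3, 10000, replace = TRUE)
    b <- sample(0:3, 10000, replace = TRUE)
    expect_equal(mutual_information(a, b), mutual_information(b, a),
                 tolerance = 1e-12)
    worst <- max(worst, mutual_information(a, b))
  }
  expect_gte(worst, 0)
  expect_lte(worst, 0.01)
  expect_error(mutual_information(1:5, 1:6), "mismatch")
})

test_that("continuous inputs are binned by equal frequency", {
  set.seed(13)
  x <- rcauchy(400)   # heavy tails must not collapse the binning
  d <- discretize_ef(x, 16)
  expect_equal(sort(unique(d)), 1:16)
  expect_true(max(table(d)) - min(table(d)) <= 1)
})

test_that("a single candidate is ranked first with its relevance", {
  set.seed(14)
  y <- rep(0:1, 50)
  X <- cbind(v1 = y + rnorm(100, 0, 0.1))
  res <- mrmr_rank(X, y)
  expect_equal(res$ranked_names, "v1")
  expect_equal(res$importance_raw[1],
               mutual_information(X[, 1], y), tolerance = 1e-12)
})

test_that("an exact duplicate of the top feature is demoted below a weak independent predictor", {
  set.seed(15)
  n <- 400
  y <- rep(0:1, n / 2)
  f1 <- y; flip <- sample(n, n * 0.02); f1[flip] <- 1 - f1[flip]
  f2 <- f1
  f3 <- y + rnorm(n, 0, 2)   # weak but independent information
  X <- cbind(f1 = f1, f2 = f2, f3 = f3)
  res <- mrmr_rank(X, y)
  expect_equal(res$ranked_names, c("f1", "f3", "f2"))
  # when the duplicate competes against f3 (one variable selected), its
  # redundancy I(f1; f2) = H(f1) makes its incremental score negative
  score_f2_step2 <- mutual_information(f2, y) - mutual_information(f1, f2)
  expect_lt(score_f2_step2, 0)
  # adding the duplicate never changes the next pick after f1
  expect_equal(mrmr_rank(X[, c("f1", "f3")], y)$ranked_names[2], "f3")
})

test_that("incremental ranking equals exhaustive recomputation", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 200
    y <- rep(0:1, n / 2)
    X <- cbind(a = y + rnorm(n, 0, 0.5),
               b = y + rnorm(n, 0, 1.5),
               c = rnorm(n),
               d = y * rnorm(n))
    expect_equal(mrmr_rank(X, y)$ranked_names, oracle_mrmr(X, y))
  }
})

test_that("first pick is always the maximum-relevance variable", {
  set.seed(17)
  n <- 300
  y <- rep(0:1, n / 2)
  X <- sapply(1:4, function(j) y + rnorm(n, 0, j))
  colnames(X) <- paste0("v", 1:4)
  res <- mrmr_rank(X, y)
  rel <- sapply(1:4, function(j) mutual_information(X[, j], y))
  expect_equal(res$ranked_names[1], colnames(X)[which.max(rel)])
})

test_that("a constant variable is still rankable with zero relevance", {
  set.seed(18)
  y <- rep(0:1, 50)
  X <- cbind(good = y + rnorm(100, 0, 0.2), flat = rep(1, 100))
  res <- mrmr_rank(X, y)
  expect_equal(res$ranked_names[1], "good")
  expect_equal(unname(res$relevance["flat"]), 0, tolerance = 1e-12)
})

test_that("the sweep keeps the smallest count achieving peak accuracy", {
  expect_equal(p3dseize:::chosen_k_from_accuracies(c(0.90, 0.94, 0.97, 0.95)), 3)
  expect_equal(p3dseize:::chosen_k_from_accuracies(rep(0.9, 4)), 1)
  expect_equal(p3dseize:::chosen_k_from_accuracies(c(0.7, 0.8, 0.9, 0.95)), 4)
})

test_that("feature_count_sweep evaluates top-j sets under a fixed plan", {
  set.seed(19)
  n <- 200
  y <- rep(0:1, n / 2)
  X <- cbind(s1 = y + rnorm(n, 0, 0.3), s2 = rnorm(n), s3 = rnorm(n))
  fm <- p3dseize:::build_feature_matrix_raw(X, y)
  res <- mrmr_rank(fm)
  swept <- feature_count_sweep(fm, res, seed = 7)
  expect_length(swept$sweep_accuracy, 3)
  expect_true(swept$chosen_k %in% 1:3)
  # pure-noise additions cannot raise accuracy much; the informative
  # variable is ranked first and retained
  expect_equal(swept$ranked_names[1], "s1")
  # deterministic under the same seed
  swept2 <- feature_count_sweep(fm, mrmr_rank(fm), seed = 7)
  expect_identical(swept$sweep_accuracy, swept2$sweep_accuracy)
  expect_error(feature_count_sweep(fm, res, k_max = 0), ">= 1")
})

test_that("selection results serialize to JSON and back", {
  set.seed(20)
  y <- rep(0:1, 50)
  X <- cbind(a = y + rnorm(100, 0, 0.4), b = rnorm(100))
  res <- mrmr_rank(X, y)
  path <- tempfile(fileext = ".json")
  write_selection_json(res, path, seed = 1L)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$ranked_names, res$ranked_names)
  expect_equal(back$importance, res$importance, tolerance = 1e-9)
})
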