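test_that("all four estimators match brute-force enumeration", {
  set.seed(101)
  worst <- c(hfd = 0, apen = 0, sampen = 0, fuzzyen = 0)
  for (i in 1:50) {
    n <- sample(60:200, 1)
    x <- oracle_series(n)
    worst["hfd"] <- max(worst["hfd"],
                        abs(higuchi_fd(x, 10) - oracle_higuchi(x, 10)))
    worst["apen"] <- max(worst["apen"],
                         abs(approximate_entropy(x, 2, 0.3) -
                               oracle_apen(x, 2, 0.3)))
    worst["sampen"] <- max(worst["sampen"],
                           abs(sample_entropy(x, 2, 0.3) -
                                 oracle_sampen(x, 2, 0.3)))
    worst["fuzzyen"] <- max(worst["fuzzyen"],
                            abs(fuzzy_entropy(x, 2, 0.3, 2) -
                                  oracle_fuzzyen(x, 2, 0.3, 2)))
  }
  expect_lt(max(worst), 1e-10)
})

test_that("fixed oracle examples reproduce exactly", {
  x1 <- rep(c(1, 2, 3), 20)
  expect_lt(abs(approximate_entropy(x1, 2, 0.5) - oracle_apen(x1, 2, 0.5)),
            1e-10)
  # logistic-map orbit
  x2 <- numeric(100); x2[1] <- 0.3
  for (i in 2:100) x2[i] <- 4 * x2[i - 1] * (1 - x2[i - 1])
  expect_lt(abs(sample_entropy(x2, 2, 0.2) - oracle_sampen(x2, 2, 0.2)),
            1e-10)
  set.seed(5)
  x3 <- rep(c(-1, 1), 40) + rnorm(80, 0, 0.1)
  expect_lt(abs(fuzzy_entropy(x3, 2, 0.2, 2) - oracle_fuzzyen(x3, 2, 0.2, 2)),
            1e-10)
})

test_that("a straight line has fractal dimension exactly 1", {
  expect_equal(higuchi_fd(seq_len(1000), 10), 1, tolerance = 1e-12)
})

test_that("white noise has fractal dimension near 2", {
  set.seed(33)
  vals <- replicate(50, higuchi_fd(rnorm(2000), 10))
  expect_gte(mean(vals), 1.9)
  expect_lte(mean(vals), 2.05)
})

test_that("fractal dimension rises with the noise fraction of a mixture", {
  set.seed(17)
  t <- seq_len(1024) / 256
  base <- sin(2 * pi * 8 * t)
  fd <- vapply(c(0.1, 0.4, 0.8), function(a) {
    mean(replicate(10, higuchi_fd(base + a * rnorm(1024), 10)))
  }, 0)
  expect_true(all(diff(fd) > 0))
})

test_that("degenerate inputs behave as specified", {
  expect_error(higuchi_fd(rep(1, 100), 10), "degenerate")
  expect_error(higuchi_fd(1:5, 10), "exceed")
  expect_equal(approximate_entropy(rep(5, 100), 2, 0.2), 0)
  expect_equal(sample_entropy(rep(5, 100), 2, 0.2), 0)
  expect_equal(fuzzy_entropy(rep(5, 100), 2, 0.2), 0)
  expect_error(approximate_entropy(c(1, 2), 2, 0.2), "too short")
})

test_that("noise is less regular than a pure tone by ApEn", {
  set.seed(44)
  t <- seq_len(512) / 256
  wins <- vapply(1:50, function(i) {
    approximate_entropy(rnorm(512), 2, 0.2) >
      approximate_entropy(sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)), 2, 0.2)
  }, logical(1))
  expect_gte(sum(wins), 48)
})

test_that("SampEn is scale invariant and FuzzyEn offset invariant", {
  set.seed(55)
  x <- oracle_series(150)
  expect_equal(sample_entropy(3.7 * x - 2, 2, 0.2), sample_entropy(x, 2, 0.2),
               tolerance = 1e-12)
  expect_equal(fuzzy_entropy(x + 17.3, 2, 0.2), fuzzy_entropy(x, 2, 0.2),
               tolerance = 1e-12)
})

test_that("entropy traces expose valid aggregates", {
  set.seed(66)
  tr <- entropy_trace(oracle_series(150))
  expect_true(tr$B_m > 0 && tr$B_m <= 1)
  expect_true(tr$B_m1 > 0 && tr$B_m1 <= 1)
  expect_true(tr$Phi_m > 0 && tr$Phi_m <= 1)
  expect_true(tr$Phi_m1 > 0 && tr$Phi_m1 <= 1)
  expect_length(tr$curve_L, 10)
  expect_true(all(is.finite(log(tr$curve_L))))
})

test_that("feature blocks have the contracted shape and are deterministic", {
  set.seed(77)
  steps <- array(rnorm(5 * 2 * 4 * 96), c(5, 2, 4, 96))
  steps[5, , , ] <- steps[1, , , ]   # duplicated window
  fb <- extract_feature_block(steps, feature_params(),
                              c("HFD", "ApEn", "FuzzyEn"),
                              channel_names = fixture_channels4)
  expect_equal(dim(fb$values), c(5, 2, 3, 4))
  expect_true(all(is.finite(fb$values)))
  expect_equal(fb$values[5, , , ], fb$values[1, , , ])
  expect_error(extract_feature_block(steps, feature_names = character(0)),
               "non-empty")
  expect_error(extract_feature_block(steps, feature_names = "Hurst"),
               "unknown")
})

test_that("constant channels are recorded as 0 with a warning", {
  steps <- array(rnorm(2 * 2 * 2 * 96), c(2, 2, 2, 96))
  steps[1, 1, 1, ] <- 7
  expect_warning(fb <- extract_feature_block(steps, feature_names = "HFD"),
                 "failure")
  expect_equal(fb$values[1, 1, 1, 1], 0)
})

test_that("feature tables are tidy and complete", {
  set.seed(88)
  steps <- array(rnorm(3 * 2 * 2 * 96), c(3, 2, 2, 96))
  fb <- extract_feature_block(steps, feature_names = c("HFD", "ApEn"))
  tab <- feature_table(fb)
  expect_named(tab, c("window_id", "step", "channel", "feature", "value"))
  expect_equal(nrow(tab), 3 * 2 * 2 * 2)
  expect_equal(tab$value[tab$window_id == 2 & tab$step == 1 &
                           tab$feature == "ApEn" & tab$channel == "ch02"],
               fb$values[2, 1, 2, 2])
})

test_that("selected-feature subsetting reorders by name", {
  set.seed(99)
  steps <- array(rnorm(2 * 2 * 2 * 96), c(2, 2, 2, 96))
  fb <- extract_feature_block(steps)
  sub <- select_features(fb, c("FuzzyEn", "HFD"))
  expect_equal(sub$feature_names, c("FuzzyEn", "HFD"))
  expect_equal(sub$values[, , 2, ], fb$values[, , 1, ])
  expect_error(select_features(fb, "nope"), "not present")
})
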