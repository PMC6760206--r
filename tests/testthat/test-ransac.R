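# RANSAC regression and the per-range model assembly.

test_that("noiseless linear data is recovered to numerical precision", {
  set.seed(1)
  X <- cbind(bsr = runif(300, 0, 100), sef = runif(300, 8, 26),
             rbr = runif(300, -2, 1), emg = runif(300, 25, 45))
  y <- 10 - 0.4 * X[, "bsr"] + 2 * X[, "sef"] + 3 * X[, "rbr"]
  fit <- ransac_fit(X, y, ransac_config(sample_size = 50, seed = 2))
  expect_equal(unname(fit$coefficients),
               c(10, -0.4, 2, 3, 0), tolerance = 1e-8)
  expect_true(all(fit$inliers))
})

test_that("gross outliers are rejected where least squares is dragged away", {
  set.seed(3)
  n <- 3000
  X <- cbind(bsr = runif(n, 0, 100), rbr = runif(n, -2, 1))
  y <- 20 - 0.5 * X[, "bsr"] + 1.5 * X[, "rbr"] + rnorm(n, 0, 0.5)
  bad <- sample.int(n, n * 0.2)
  y[bad] <- y[bad] + 30
  fit <- ransac_fit(X, y, ransac_config(sample_size = 500, seed = 4))
  expect_equal(unname(fit$coefficients[1]), 20, tolerance = 0.05 * 20)
  expect_equal(unname(fit$coefficients["bsr"]), -0.5, tolerance = 0.05)
  expect_lt(mean(fit$inliers[bad]), 0.05)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_gt(abs(ols[1] - 20), 1)   # the negative control fails
})

test_that("robustness to growing outlier fractions, unlike least squares", {
  set.seed(8)
  n <- 3000
  X <- cbind(bsr = runif(n, 0, 100), rbr = runif(n, -2, 1))
  clean <- 20 - 0.5 * X[, "bsr"] + 1.5 * X[, "rbr"] + rnorm(n, 0, 0.5)
  fits <- lapply(c(0, 0.3), function(fr) {
    y <- clean
    if (fr > 0) {
      bad <- sample.int(n, n * fr)
      y[bad] <- y[bad] + 30
    }
    list(ransac = ransac_fit(X, y,
                             ransac_config(sample_size = 500,
                                           seed = 9))$coefficients,
         ols = stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients)
  })
  pred <- function(cf) cf[1] + X %*% cf[-1]
  ransac_drift <- mean(abs(pred(fits[[2]]$ransac) - pred(fits[[1]]$ransac)))
  ols_drift <- mean(abs(pred(fits[[2]]$ols) - pred(fits[[1]]$ols)))
  # the BSR slope stays within 5x the noiseless tolerance of 0.05
  expect_lt(abs(fits[[2]]$ransac["bsr"] - fits[[1]]$ransac["bsr"]), 0.25)
  # fitted values degrade materially less than under least squares; at this
  # contamination the consensus truncation does bias the fit, so the gain is
  # a bounded factor rather than immunity
  expect_lt(ransac_drift, 0.6 * ols_drift)
})

test_that("the final refit is idempotent on its own inlier set", {
  set.seed(5)
  X <- cbind(bsr = runif(2000, 0, 100), rbr = runif(2000, -2, 1))
  y <- 30 - 0.4 * X[, "bsr"] + rnorm(2000)
  fit <- ransac_fit(X, y, ransac_config(sample_size = 500, seed = 6))
  refit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[fit$inliers, ]),
                         y[fit$inliers])
  expect_equal(fit$coefficients, refit$coefficients)
})

test_that("small samples fall back to least squares with a notice", {
  set.seed(6)
  X <- cbind(bsr = runif(100, 0, 100), rbr = runif(100, -2, 1))
  y <- 5 + 0.1 * X[, "bsr"]
  expect_message(fit <- ransac_fit(X, y, ransac_config(sample_size = 1000)),
                 "least squares")
  expect_equal(unname(fit$coefficients[1]), 5, tolerance = 1e-8)
})

test_that("rank-deficient designs raise a fitting error", {
  X <- cbind(bsr = rep(1, 2000), rbr = rep(2, 2000))
  expect_error(ransac_fit(X, rnorm(2000), ransac_config(sample_size = 100)),
               class = "bisre_fitting_error")
})

test_that("per-range fits on model-generated data recover the generator", {
  pool <- quick_pool(30000, seed = 11, bis_noise = 1)
  fitted <- fit_range_models(pool, bis_tree_spec(),
                             ransac_config(seed = 12))
  # noiseless held-out set scored against the fitted model
  holdout <- quick_pool(5000, seed = 13, bis_noise = 0)
  pred <- predict_bis(holdout, fitted$model)
  expect_lt(stats::median(abs(pred$bis - holdout$bis)), 1)
  # determinism
  again <- fit_range_models(pool, bis_tree_spec(), ransac_config(seed = 12))
  expect_identical(fitted$coefficients, again$coefficients)
})

test_that("a range with no samples fails with its name", {
  pool <- quick_pool(2000, seed = 14)
  shallow <- pool[pool$bsr < 40, ]   # removes the isoelectric range
  expect_error(fit_range_models(shallow, bis_tree_spec(),
                                ransac_config(sample_size = 100)),
               "0-21", class = "bisre_fitting_error")
})
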