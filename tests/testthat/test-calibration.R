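# Calibration fitting, prediction, metrics, cross-validation, baseline.

rec <- function(x, y) data.frame(log_g_over_r = x, elogp = y)

test_that("exact lines are recovered exactly", {
  x <- c(-1, 0, 1, 2, 3.5)
  m <- fit_calibration(rec(x, 2 * x + 1))
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$metrics$r_squared, 1)
  expect_equal(m$metrics$mae, 0, tolerance = 1e-12)
  expect_equal(m$metrics$rmse, 0, tolerance = 1e-12)
})

test_that("a hand-solved 3-point fit matches the normal equations", {
  m <- fit_calibration(rec(c(0, 1, 2), c(0, 1, 3)))
  expect_equal(m$slope, 1.5, tolerance = 1e-12)
  expect_equal(m$intercept, -1 / 6, tolerance = 1e-12)
})

test_that("fitting degenerate inputs fails cleanly", {
  expect_error(fit_calibration(rec(1, 1)), class = "vgnp_fit_error")
  expect_error(fit_calibration(rec(c(1, 1, 1), c(0, 1, 2))),
               class = "vgnp_fit_error")
  expect_error(fit_calibration(rec(c(1, NA), c(0, 1))),
               class = "vgnp_fit_error")
})

test_that("the shipped default model carries the published coefficients", {
  m <- default_calibration()
  expect_equal(predict_nanologp(0, m), -2.4306)
  expect_equal(predict_nanologp(1, m), -1.6972)
  ident <- vgnp:::new_calibration(1, 0, 2)
  expect_equal(predict_nanologp(c(-3, 0.4), ident), c(-3, 0.4))
})

test_that("prediction after fitting reproduces the fitted values bit-exactly", {
  x <- c(0.1, 0.5, 0.9, 1.7, 2.2)
  y <- c(-2, -1.5, -1.2, -0.4, 0.1)
  m <- fit_calibration(rec(x, y))
  pred <- predict_nanologp(x, m)
  expect_identical(m$metrics$rmse,
                   sqrt(mean((y - pred)^2)))
  expect_identical(m$metrics$mae, mean(abs(y - pred)))
})

test_that("regression metrics match their definitions", {
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unlist(m), c(r_squared = 1, mae = 0, rmse = 0))
  m2 <- regression_metrics(c(1, 2, 3), c(0, 1, 2))
  expect_equal(m2$mae, 1)
  expect_equal(m2$rmse, 1)
  expect_equal(m2$r_squared, -0.5)  # SSres = 3, SStot = 2
  expect_error(regression_metrics(1:3, 1:4), class = "vgnp_domain_error")
  expect_error(regression_metrics(1:3, c(2, 2, 2)),
               class = "vgnp_domain_error")
})

test_that("RMSE dominates MAE on arbitrary data", {
  for (seed in 1:20) {
    m <- vgnp:::with_seed(seed, {
      regression_metrics(rnorm(30), rnorm(30))
    })
    expect_gte(m$rmse, m$mae)
  }
})

test_that("noisy linear data recovers the generating coefficients within 3 SE", {
  for (seed in c(101, 202, 303)) {
    d <- vgnp:::with_seed(seed, {
      x <- runif(200, -1, 3)
      rec(x, 0.7334 * x - 2.4306 + rnorm(200, 0, 0.5))
    })
    m <- fit_calibration(d)
    fit <- stats::lm(elogp ~ log_g_over_r, data = d)
    se <- sqrt(diag(stats::vcov(fit)))
    expect_lt(abs(m$intercept - (-2.4306)), 3 * se[1])
    expect_lt(abs(m$slope - 0.7334), 3 * se[2])
  }
})

test_that("k-fold CV is deterministic, honest, and noise-calibrated", {
  # noiseless linear data: perfect CV
  x <- seq(-1, 3, length.out = 20)
  cv0 <- kfold_cv(rec(x, 1.2 * x - 0.5), k = 5, seed = 1)
  expect_equal(cv0$metrics$r_squared, 1)
  expect_equal(cv0$metrics$rmse, 0, tolerance = 1e-10)

  # determinism in the seed
  d <- vgnp:::with_seed(7, {
    x <- runif(100, -1, 3)
    rec(x, 0.73 * x - 2.43 + rnorm(100, 0, 0.8))
  })
  a <- kfold_cv(d, k = 5, seed = 42)
  b <- kfold_cv(d, k = 5, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$predictions$fold,
                         kfold_cv(d, k = 5, seed = 43)$predictions$fold))

  # pooled CV RMSE tracks the generator noise
  expect_lt(abs(a$metrics$rmse - 0.8) / 0.8, 0.2)

  # no peeking: CV R^2 does not beat fit R^2 on average over seeds
  diffs <- vapply(1:5, function(s) {
    ds <- vgnp:::with_seed(400 + s, {
      x <- runif(40, -1, 3)
      rec(x, 0.73 * x - 2.43 + rnorm(40, 0, 0.8))
    })
    fit_calibration(ds)$metrics$r_squared -
      kfold_cv(ds, k = 5, seed = s)$metrics$r_squared
  }, numeric(1))
  expect_gte(mean(diffs), 0)

  expect_error(kfold_cv(rec(1:3, 1:3), k = 4), class = "vgnp_domain_error")
  expect_error(kfold_cv(rec(1:3, 1:3), k = 1), class = "vgnp_domain_error")
})

test_that("the ligand baseline is the count-weighted mean logP", {
  expect_equal(ligand_baseline_logp(1.7, 5), 1.7)
  expect_equal(ligand_baseline_logp(c(2, -2), c(1, 1)), 0)
  expect_equal(ligand_baseline_logp(c(3, -1), c(30, 10)), 2)
  expect_error(ligand_baseline_logp(c(1, 2), c(0, 0)),
               class = "vgnp_domain_error")
})

test_that("calibration models round-trip through JSON", {
  m <- fit_calibration(rec(c(0, 1, 2), c(0, 1, 3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$metrics$rmse, m$metrics$rmse)
})
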