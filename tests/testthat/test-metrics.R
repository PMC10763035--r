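test_that("paired scores are validated", {
  expect_error(paired_scores(1:3, 1:4), "lengths differ")
  expect_error(paired_scores(1, 1), "at least 2")
  expect_error(paired_scores(c(1, NA), c(1, 2)), "missing")
})

test_that("R-squared follows the residual/total variance ratio and can be negative", {
  expect_equal(r_squared(paired_scores(c(0, 50, 100), c(10, 50, 90))), 0.96)
  expect_equal(r_squared(paired_scores(c(0, 50, 100), c(100, 50, 0))), -3)
  y <- c(3, 7, 9); expect_equal(r_squared(paired_scores(y, y)), 1)
  expect_error(r_squared(paired_scores(c(5, 5), c(1, 2))),
               class = "promval_undefined_metric")
})

test_that("MAE and RMSE use the divisor-n population forms", {
  p <- paired_scores(c(0, 50, 100), c(10, 50, 90))
  expect_equal(mae(p), 20 / 3)
  expect_equal(rmse(p), sqrt(200 / 3))
  same <- paired_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mae(same), 0); expect_equal(rmse(same), 0)
  const_err <- paired_scores(c(1, 2, 3), c(1, 2, 3) + 4.5)
  expect_equal(mae(const_err), 4.5)
  expect_equal(rmse(const_err), 4.5)
})

test_that("RMSE dominates MAE with equality only for constant |residuals|", {
  set.seed(11)
  for (rep in 1:30) {
    p <- make_paired(sample(5:80, 1), seed = rep)
    expect_gte(rmse(p) + 1e-12, mae(p))
  }
})

test_that("the concordance index counts strict pairs as printed", {
  expect_equal(c_index(paired_scores(c(1, 3, 2, 2), c(1, 2, 2, 3))), 0.6)
  ## perfectly ordered / reversed
  expect_equal(c_index(paired_scores(1:5, 2 * (1:5))), 1)
  expect_equal(c_index(paired_scores(5:1, 1:5)), 0)
  ## half-credit policy gives observed ties 0.5
  expect_equal(c_index(paired_scores(c(1, 3, 2, 2), c(1, 2, 2, 3)), "half_credit"),
               3.5 / 5)
  expect_error(c_index(paired_scores(1:4, rep(2, 4))),
               class = "promval_undefined_metric")
})

test_that("the concordance index matches the O(n^2) oracle and is rank-invariant", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    yhat <- sample(1:8, n, replace = TRUE)        # forces both tie kinds
    y <- sample(1:8, n, replace = TRUE)
    p <- paired_scores(y, yhat)
    for (pol in c("as_printed", "half_credit")) {
      expect_equal(c_index(p, pol), c_index_oracle(y, yhat, pol), tolerance = 1e-12)
    }
    ## strictly increasing transforms of predictions do not move the c-index
    p2 <- paired_scores(y, exp(yhat / 3) + 5)
    expect_equal(c_index(p2), c_index(p))
    ## but R2/MAE/RMSE/CL/CS do move
    expect_false(isTRUE(all.equal(r_squared(p2), r_squared(p))))
    expect_false(isTRUE(all.equal(mae(p2), mae(p))))
  }
})

test_that("calibration-in-the-large is the (lower) median or mean residual", {
  y <- c(0, 10, 40); yhat <- y - c(-10, 5, 30)    # residuals -10, 5, 30
  p <- paired_scores(y, yhat)
  expect_equal(calibration_in_large(p, "median"), 5)
  expect_equal(calibration_in_large(p, "mean"), 25 / 3)
  same <- make_paired(30, seed = 2)
  expect_equal(calibration_in_large(paired_scores(same$yhat, same$yhat)), 0)
  ## shift equivariance at c = 7
  p7 <- paired_scores(p$y + 7, p$yhat)
  expect_equal(calibration_in_large(p7, "median"),
               calibration_in_large(p, "median") + 7)
  expect_equal(calibration_in_large(p7, "mean"),
               calibration_in_large(p, "mean") + 7)
  ## median CL attains the LAD optimum of the offset regression (grid oracle)
  pr <- make_paired(41, seed = 6)
  res <- pr$y - pr$yhat
  expect_equal(sum(abs(res - calibration_in_large(pr, "median"))),
               cl_grid_oracle(res)$objective, tolerance = 1e-10)
})

test_that("symmetric residuals give identical mean and median CL", {
  yhat <- c(10, 20, 30, 40, 50)
  y <- yhat + c(-4, -2, 0, 2, 4)
  p <- paired_scores(y, yhat)
  expect_equal(calibration_in_large(p, "median"), calibration_in_large(p, "mean"))
})

test_that("calibration slope recovers exact linear relations", {
  yhat <- c(0, 1, 2, 3)
  expect_equal(calibration_slope(paired_scores(2 * yhat, yhat), "median"), 2,
               tolerance = 1e-9)
  expect_equal(calibration_slope(paired_scores(2 * yhat, yhat), "mean"), 2)
  expect_equal(calibration_slope(paired_scores(yhat + 5, yhat), "median"), 1,
               tolerance = 1e-9)
  ## outlier case: the median fit attains the LP optimum (slope non-unique)
  p <- paired_scores(c(0, 1, 2, 10), yhat)
  s <- calibration_slope(p, "median")
  expect_equal(sum(abs(p$y - lad_fit(cbind(1, p$yhat), p$y)$coefficients[1] -
                         s * p$yhat)),
               lad_lp_oracle(cbind(1, yhat), p$y)$objective, tolerance = 1e-8)
  expect_error(calibration_slope(paired_scores(1:4, rep(3, 4))),
               class = "promval_undefined_metric")
})

test_that("mean-method CL and CS reproduce closed-form OLS exactly", {
  set.seed(8)
  for (rep in 1:10) {
    p <- make_paired(sample(10:100, 1), seed = rep + 100)
    b <- cov(p$y, p$yhat) / var(p$yhat)
    a <- mean(p$y) - b * mean(p$yhat)
    expect_equal(calibration_slope(p, "mean"), b, tolerance = 1e-10)
    expect_equal(calibration_in_large(p, "mean"), mean(p$y - p$yhat), tolerance = 1e-12)
    ## the OLS intercept with yhat as offset is the mean residual
    expect_equal(mean(p$y - p$yhat), a + (b - 1) * mean(p$yhat), tolerance = 1e-10)
  }
})

test_that("the metric set bundles all six statistics consistently", {
  p <- make_paired(50, seed = 3)
  ms <- compute_metric_set(p, "median", domain = "sexual", timepoint = "12m",
                           imputation = 1L)
  expect_equal(ms$R2, r_squared(p))
  expect_equal(ms$CL, calibration_in_large(p, "median"))
  expect_equal(ms$CS, calibration_slope(p, "median"))
  expect_equal(ms$MAE, mae(p))
  expect_equal(ms$RMSE, rmse(p))
  expect_equal(ms$c_index, c_index(p))

  perfect <- paired_scores(p$yhat, p$yhat)
  msp <- compute_metric_set(perfect, "median")
  expect_equal(msp$R2, 1); expect_equal(msp$CL, 0)
  expect_equal(msp$CS, 1, tolerance = 1e-9)
  expect_equal(msp$MAE, 0); expect_equal(msp$RMSE, 0)
  expect_equal(msp$c_index, 1)

  ## undefined metrics propagate the metric name, or NA on request
  const <- paired_scores(c(4, 4, 4), c(1, 2, 3))
  expect_error(compute_metric_set(const), class = "promval_undefined_metric")
  ms_na <- compute_metric_set(const, undefined = "na")
  expect_true(is.na(ms_na$R2))
  expect_false(is.na(ms_na$MAE))
})
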