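test_that("product-limit estimator matches direct arithmetic", {
  km <- km_estimate(1:5, rep(TRUE, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median_survival, 3)

  # with no censoring KM reproduces the empirical survival function
  set.seed(10)
  t <- rexp(200, 0.2)
  km2 <- km_estimate(t, rep(TRUE, 200))
  ecdf_surv <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$surv, ecdf_surv, tolerance = 1e-12)

  # all censored: curve defined, median undefined
  km3 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  expect_true(is.na(km3$median_survival))
})

test_that("product-limit estimator agrees with survival::survfit", {
  set.seed(11)
  t <- round(rexp(150, 0.1), 1)        # rounding creates ties
  ev <- runif(150) < 0.7
  km <- km_estimate(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  at <- sf$n.event > 0
  expect_equal(km$time, sf$time[at])
  expect_equal(km$surv, sf$surv[at], tolerance = 1e-12)
})

test_that("KM median recovers the distribution median", {
  set.seed(12)
  km <- km_estimate(rexp(500, 0.1), rep(TRUE, 500))
  expect_lt(abs(km$median_survival - log(2) / 0.1), 0.1 * log(2) / 0.1)
})

test_that("log-rank: identical arms, relabeling invariance, null calibration", {
  t <- c(2, 4, 6, 8, 10); ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  lr0 <- logrank_test(c(t, t), c(ev, ev), rep(c(0, 1), each = 5))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)

  set.seed(13)
  tt <- rexp(120, 0.1); evv <- runif(120) < 0.8
  g <- rep(c(0, 1), 60)
  expect_equal(logrank_test(tt, evv, g)$chi_square,
               logrank_test(tt, evv, 1 - g)$chi_square, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(0, 1)),
               "zero events")
})

test_that("log-rank detects a hazard ratio of 2 at n=150/arm", {
  set.seed(14)
  hits <- replicate(50, {
    t0 <- rexp(150, 0.1); t1 <- rexp(150, 0.2)
    logrank_test(c(t0, t1), rep(TRUE, 300), rep(0:1, each = 150))$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Cox fit recovers parameters and rejects degenerate covariates", {
  set.seed(15)
  n <- 400
  x <- rep(0:1, each = n / 2)
  loghr <- replicate(7, {
    t0 <- rweibull(n, 1.5, 12)
    t <- t0 * 2^(-x / 1.5)                     # true HR 2 for x = 1
    cox_fit(data.frame(os_months = t, os_event = TRUE, x = x),
            covariates = "x")$coefficients[["x"]]
  })
  expect_lt(abs(median(loghr) - log(2)), 0.15)
  t <- rweibull(n, 1.5, 12) * 2^(-x / 1.5)
  df <- data.frame(os_months = t, os_event = TRUE, x = x)
  fit <- cox_fit(df, covariates = "x")
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))
  expect_equal(fit$df, 1)

  expect_error(cox_fit(data.frame(os_months = t, os_event = TRUE, z = 1),
                       covariates = "z"), "zero variance")

  # reparameterization: centering leaves the coefficient, scaling rescales it
  df$xc <- df$x - mean(df$x)
  df$x2 <- df$x / 2
  expect_equal(cox_fit(df, covariates = "xc")$coefficients[["xc"]],
               fit$coefficients[["x"]], tolerance = 1e-8)
  expect_equal(cox_fit(df, covariates = "x2")$coefficients[["x2"]],
               2 * fit$coefficients[["x"]], tolerance = 1e-8)
})

test_that("rows with missing covariates are excluded and counted", {
  set.seed(16)
  df <- data.frame(os_months = rexp(50, 0.1), os_event = TRUE,
                   x = rnorm(50))
  df$x[c(3, 7)] <- NA
  fit <- cox_fit(df, covariates = "x")
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n, 48)
})

test_that("the cutoff scan is gatekept by the continuous Cox screen", {
  set.seed(17)
  df <- data.frame(os_months = rexp(120, 0.1), os_event = TRUE,
                   marker = rlnorm(120, log(10), 1))
  res <- max_median_diff_cutoff(df, "marker")
  expect_s3_class(res, "survival_screen")
  expect_false(res$scanned)
  expect_match(res$reason, "screen")
  forced <- max_median_diff_cutoff(df, "marker", force = TRUE)
  expect_s3_class(forced, "survival_cutoff")
  # anti-conservative selection must carry a warning field
  expect_true(nzchar(forced$multiple_testing_warning))
})

test_that("the scan equals a brute-force scan on random instances", {
  set.seed(18)
  for (i in 1:500) {
    n <- sample(40:70, 1)
    marker <- round(rlnorm(n, log(10), 1), 1)
    hi <- marker > 15
    t <- rweibull(n, 2, ifelse(hi, 8, 14))
    ev <- runif(n) < 0.85
    if (sum(ev) < 5) next
    df <- data.frame(os_months = t, os_event = ev, marker = marker)
    grid <- sort(unique(marker))
    res <- tryCatch(
      max_median_diff_cutoff(df, "marker", grid = grid,
                             min_arm_fraction = 0.15, force = TRUE),
      error = function(e) e)
    oracle <- brute_force_survival_cutoff(t, ev, marker, grid,
                                          ceiling(0.15 * n))
    if (is.null(oracle)) {
      expect_s3_class(res, "error")
      expect_match(conditionMessage(res), "no admissible cutoff")
    } else {
      expect_equal(res$cutoff, oracle$cutoff)
      expect_equal(res$median_low, oracle$median_low)
      expect_equal(res$median_high, oracle$median_high)
    }
  }
})

test_that("inadmissible scans explain every skipped cutoff", {
  # every event censored in the would-be high arm -> undefined medians
  df <- data.frame(os_months = c(rexp(30, 0.05), rexp(30, 0.05)),
                   os_event = rep(c(TRUE, FALSE), each = 30),
                   marker = rep(c(1, 10), each = 30))
  suppressWarnings(expect_error(
    max_median_diff_cutoff(df, "marker", grid = c(5), force = TRUE),
    "undefined median"))
})
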