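test_that("identical spec and seed give bit-identical samples", {
  spec <- sample_spec(n_events = 5000, seed = 99)
  a <- simulate_sample(spec)
  b <- simulate_sample(spec)
  expect_identical(a$values, b$values)
  expect_identical(a$truth_labels, b$truth_labels)
  c <- simulate_sample(sample_spec(n_events = 5000, seed = 100))
  expect_false(identical(a$values, c$values))
})

test_that("population counts are multinomial in the spec weights", {
  pops <- default_populations(weights = c(lymphocyte = 0.3,
                                          classical_mono = 0.7))
  tbl <- simulate_sample(sample_spec(n_events = 1e5, populations = pops,
                                     seed = 11))
  n_lymph <- sum(tbl$truth_labels == "lymphocyte")
  expect_lt(abs(n_lymph - 30000), 4 * sqrt(1e5 * 0.3 * 0.7))
})

test_that("weights must sum to one", {
  pops <- default_populations(weights = c(lymphocyte = 0.3,
                                          classical_mono = 0.6))
  expect_error(sample_spec(populations = pops), "sum to")
})

test_that("per-population channel moments match the spec", {
  spec <- sample_spec(n_events = 2e5, seed = 21)
  tbl <- simulate_sample(spec)
  # 64 simultaneous mean checks: use a 4 SE margin for the family
  for (p in spec$populations) {
    idx <- tbl$truth_labels == p$name
    n <- sum(idx)
    for (ch in names(p$mean)) {
      # empirical SE: FSC-H rides on FSC-A, so its spread exceeds the
      # marginal sd parameter; every other channel matches it
      se <- stats::sd(tbl$values[idx, ch]) / sqrt(n)
      expect_lt(abs(mean(tbl$values[idx, ch]) - p$mean[[ch]]), 4 * se,
                label = sprintf("|mean err| %s/%s", p$name, ch))
      if (ch != "FSC-H")
        expect_lt(abs(stats::sd(tbl$values[idx, ch]) / p$sd[[ch]] - 1), 0.1,
                  label = sprintf("sd ratio %s/%s", p$name, ch))
    }
  }
})

test_that("zero-fraction samples measure the background false-positive rate", {
  # with no true positives the measured positive fraction estimates 1 - q
  q <- 0.995
  tbl <- small_sample(n_events = 4e5, gfap_fracs = NULL, seed = 31)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  thr <- lymphocyte_background_threshold(tbl, g, "GFAP", quantile = q)
  flags <- label_marker_positive(tbl, g, "GFAP", thr)
  cd16 <- g$assignment %in% c("intermediate_mono", "nonclassical_mono")
  measured <- mean(flags[cd16])
  expect_lt(abs(measured - (1 - q)), 0.002)
})

test_that("cohort bookkeeping, censoring and survival-arm structure", {
  spec <- default_cohort_spec(groups = list(
    healthy = timascan:::group_spec(38, log(0.25), 0.7, dexa_p = 0),
    GBM = timascan:::group_spec(145, log(1.2), 0.9, size_mean_cm = 3.5)))
  sim <- simulate_cohort(spec, seed = 2, events = FALSE)
  expect_equal(nrow(sim$cohort), 183)
  expect_equal(sum(sim$cohort$diagnosis_group == "GBM"), 145)
  expect_equal(sum(sim$cohort$diagnosis_group == "healthy"), 38)
  expect_identical(sim$cohort$sample_id, sim$truth$sample_id)

  # no censoring -> every survival record is an event
  spec0 <- default_cohort_spec(censoring_rate = 0, censoring_horizon = 1e6,
                               groups = list(
    GBM = timascan:::group_spec(60, log(1.2), 0.9, size_mean_cm = 3.5)))
  sim0 <- simulate_cohort(spec0, seed = 3, events = FALSE)
  expect_true(all(sim0$cohort$os_event))

  expect_error(simulate_cohort(default_cohort_spec(groups = list())),
               "at least one group")
})

test_that("cohort generation is a pure function of (spec, seed)", {
  spec <- default_cohort_spec(n_events = 2000, groups = list(
    GBM = timascan:::group_spec(3, log(1.2), 0.9, size_mean_cm = 3.5)))
  a <- simulate_cohort(spec, seed = 7)
  b <- simulate_cohort(spec, seed = 7)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$events, `[[`, "values"),
                   lapply(b$events, `[[`, "values"))
})

test_that("null survival coupling is recovered by Cox (log HR near 0)", {
  # hazard ratio 1 between arms: make both arm medians equal; a balanced
  # median dichotomy keeps the estimator SE well inside the band, and the
  # check is judged at the replicate median
  spec <- default_cohort_spec(os_median_low = 10, os_median_high = 10,
                              groups = list(
    GBM = timascan:::group_spec(400, log(1.2), 0.9, size_mean_cm = 3.5)))
  coefs <- vapply(1:7, function(s) {
    sim <- simulate_cohort(spec, seed = 12 + s, events = FALSE)
    m <- merge(as.data.frame(sim$cohort), sim$truth[, -2], by = "sample_id")
    m$arm <- as.numeric(m$true_pct_gfap_nonclassical >
                          median(m$true_pct_gfap_nonclassical))
    cox_fit(m, covariates = "arm")$coefficients[["arm"]]
  }, numeric(1))
  expect_lt(abs(median(coefs)), 0.15)
})

test_that("stroke time courses follow the configured profiles", {
  ts <- simulate_ais_timecourse(noise_sdlog = 0, seed = 1)
  big <- ts[ts$patient_id == "AIS005", ]
  early <- big$hours_since_onset <= 8
  expect_gte(sum(big$true_pct[early] > 0.6), 2)
  expect_true(all(big$true_pct[big$hours_since_onset >= 48] < 0.6))
  small <- ts[ts$patient_id == "AIS010", ]
  expect_true(all(small$true_pct < 0.6))
  # single marginal excursion profile stays below 1%
  marginal <- ts[ts$patient_id == "AIS001", ]
  expect_equal(sum(marginal$true_pct > 0.6), 1)
  expect_true(all(marginal$true_pct < 1))

  expect_identical(simulate_ais_timecourse(seed = 5),
                   simulate_ais_timecourse(seed = 5))
  expect_error(simulate_ais_timecourse(sampling_times = c(2, 2, 4)),
               "strictly increasing")
})

test_that("analytic decay curve crosses the cutoff where expected", {
  # peak 2.0% at 4 h, half-life 12 h, baseline 0.1%: closed-form check
  f <- function(t) 0.1 + 1.9 * ifelse(t <= 4, t / 4, 2^(-(t - 4) / 12))
  times <- c(2, 4, 6, 8, 12, 24, 48, 72, 96)
  expect_equal(timascan:::ais_curve(times, 2.0, 4, 12, 0.1), f(times))
  expect_true(all(f(c(2, 4, 6, 8)) > 0.6))
  expect_true(all(f(c(48, 72, 96)) < 0.6))
})
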