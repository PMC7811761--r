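test_that("AUC equals the concordance pair count", {
  r <- roc_curve(c(3, 5, 7, 1, 2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 7 / 9)
  perfect <- roc_curve(c(10, 11, 12, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal area equals the rank-statistic AUC, ties included", {
  trapezoid_auc <- function(r) {
    fpr <- 1 - r$specificity
    tpr <- r$sensitivity
    o <- order(fpr, tpr)
    fpr <- fpr[o]; tpr <- tpr[o]
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(2:30, 1); n0 <- sample(2:30, 1)
    # heavy rounding forces many ties
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), sample(0:1, 1))
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_curve(scores, labels)
    expect_equal(trapezoid_auc(r), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(5)
  scores <- rlnorm(80); labels <- rep(c(TRUE, FALSE), 40)
  a <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(log(scores), labels)$auc, a)
  expect_equal(roc_curve(scores^3, labels)$auc, a)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- round(c(rnorm(60, 1), rnorm(60)), 1)
  labels <- rep(c(1, 0), each = 60)
  a <- roc_curve(scores, labels)$auc
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(7)
  ok <- replicate(100, {
    scores <- rnorm(400)
    labels <- sample(rep(c(TRUE, FALSE), 200))
    abs(roc_curve(scores, labels)$auc - 0.5) < 0.06
  })
  expect_gte(mean(ok), 0.95)
})

test_that("closest-sens-spec cutoff matches the worked example", {
  r <- roc_curve(c(2, 3, 4, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cm <- closest_sens_spec_cutoff(r)
  expect_equal(cm$cutoff, 2.5)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 1)
  expect_equal(abs(cm$sensitivity - cm$specificity), 1 / 3, tolerance = 1e-12)

  sep <- closest_sens_spec_cutoff(roc_curve(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
})

test_that("cutoff selection equals a brute-force scan on random instances", {
  set.seed(8)
  for (i in 1:1000) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    scores <- round(c(rnorm(n1, runif(1, 0, 2)), rnorm(n0)), 1)
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    mine <- closest_sens_spec_cutoff(roc_curve(scores, labels))
    oracle <- brute_force_cutoff(scores, labels)
    expect_equal(mine$cutoff, oracle$cutoff)
    expect_equal(mine$sensitivity, oracle$sensitivity)
    expect_equal(mine$specificity, oracle$specificity)
  }
})

test_that("cutoff evaluation reproduces the closed-form 2x2 statistics", {
  # cross-tab [[50,10],[8,40]]: chi2 = N(ad-bc)^2 / (row x col products)
  scores <- c(rep(1, 50), rep(0, 8), rep(1, 10), rep(0, 40))
  labels <- c(rep(TRUE, 58), rep(FALSE, 50))
  rep_ <- evaluate_cutoff(scores, labels, cutoff = 1)
  expect_equal(unname(rep_$table), matrix(c(50, 10, 8, 40), 2, byrow = TRUE))
  expect_equal(rep_$sensitivity, 50 / 58)
  expect_equal(rep_$specificity, 40 / 50)
  chi_expected <- 108 * (50 * 40 - 10 * 8)^2 / (60 * 48 * 58 * 50)
  expect_equal(rep_$chi_square, chi_expected, tolerance = 1e-10)
  expect_true(rep_$sensitivity_ci[1] <= rep_$sensitivity &&
                rep_$sensitivity <= rep_$sensitivity_ci[2])

  # everything called positive: sens 1, spec 0, chi-square undefined
  all_pos <- evaluate_cutoff(c(2, 3, 4, 5), c(TRUE, TRUE, FALSE, FALSE), 1)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_true(is.na(all_pos$chi_square))
})

test_that("train/validation split respects patients and healthy controls", {
  groups <- c(rep("GBM", 145), rep("diffuse-astrocytoma", 28),
              rep("oligodendroglioma", 32), rep("metastasis", 21),
              rep("WHO-I", 2), rep("other-tumour", 11))
  stopifnot(length(groups) == 239)
  ct <- cohort_table(data.frame(
    sample_id = c(sprintf("L%03d", 1:239), sprintf("H%03d", 1:38)),
    patient_id = c(sprintf("PL%03d", 1:239), sprintf("PH%03d", 1:38)),
    diagnosis_group = c(groups, rep("healthy", 38)),
    stringsAsFactors = FALSE))
  sp <- split_train_validation(ct, 0.33, seed = 2)
  expect_gte(length(sp$train), 76)
  expect_lte(length(sp$train), 84)
  expect_false(any(grepl("^H", sp$train)))          # healthy never trained on
  expect_true(all(sprintf("H%03d", 1:38) %in% sp$validation))
  expect_identical(sp, split_train_validation(ct, 0.33, seed = 2))

  # two samples of one patient stay on one side
  ct2 <- cohort_table(data.frame(
    sample_id = sprintf("S%02d", 1:40),
    patient_id = c("P01", "P01", sprintf("P%02d", 2:39)),
    diagnosis_group = "GBM", stringsAsFactors = FALSE))
  for (seed in 1:10) {
    sp2 <- split_train_validation(ct2, 0.4, seed = seed)
    expect_equal(sum(c("S01", "S02") %in% sp2$train) %% 2, 0)
  }
})
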