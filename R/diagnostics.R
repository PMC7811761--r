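#' Patient-level train/validation split
#'
#' Patients (not samples) are the sampling unit: all samples of one
#' patient land on one side. Healthy controls never enter training — they
#' are all assigned to validation; the training fraction is drawn from
#' lesion patients, stratified by diagnosis group to avoid degenerate
#' splits.
#'
#' @param cohort a [cohort_table()].
#' @param train_fraction fraction of lesion patients trained on
#'   (default 0.33).
#' @param seed integer seed; the split is reproducible under it.
#' @return List with `train` and `validation` sample_id vectors, plus the
#'   seed and per-group training counts.
#' @export
split_train_validation <- function(cohort, train_fraction = 0.33, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  lesion <- cohort[cohort$diagnosis_group %in% lesion_groups(), ]
  if (nrow(lesion) == 0L)
    stop("no lesion-group patients available for training")
  train_patients <- character()
  for (g in unique(lesion$diagnosis_group)) {
    pats <- unique(lesion$patient_id[lesion$diagnosis_group == g])
    n_tr <- round(train_fraction * length(pats))
    if (n_tr > 0L)
      train_patients <- c(train_patients, sample(pats, n_tr))
  }
  train_ids <- cohort$sample_id[cohort$patient_id %in% train_patients]
  val_ids <- setdiff(cohort$sample_id, train_ids)
  list(train = train_ids, validation = val_ids, seed = seed,
       n_train_patients = length(train_patients))
}

#' Empirical ROC curve
#'
#' Candidate thresholds are midpoints between adjacent distinct scores
#' with -Inf/+Inf sentinels; a positive call is score >= threshold. The
#' AUC is computed in the rank-statistic form
#' (concordant + ties/2) / (n_pos * n_neg), which equals the trapezoidal
#' area under the empirical curve.
#'
#' @param scores numeric per-sample scores (% GFAP+CD16+ monocytes).
#' @param labels logical (or 0/1) lesion status.
#' @return A `roc_curve`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes non-empty (", n_pos, " positive, ",
         n_neg, " negative)")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg,
                 numeric(1))
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Cutoff where sensitivity and specificity are closest
#'
#' Selects the candidate threshold minimizing |sensitivity -
#' specificity|; ties broken by maximal (sensitivity + specificity), then
#' by the smaller threshold. The tie-break rule is recorded in the result.
#'
#' @param roc a [roc_curve()].
#' @return A `cutoff_model` with the cutoff and its training operating
#'   point.
#' @export
closest_sens_spec_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  # keys rounded to 9 decimals: sens/spec are small-denominator rationals,
  # so true gaps are far larger while float noise (~1e-16) must not break
  # genuine ties
  d <- round(abs(roc$sensitivity - roc$specificity), 9)
  s <- round(roc$sensitivity + roc$specificity, 9)
  ord <- order(d, -s, roc$thresholds)
  i <- ord[1L]
  structure(list(cutoff = roc$thresholds[i],
                 sensitivity = roc$sensitivity[i],
                 specificity = roc$specificity[i],
                 auc = roc$auc,
                 criterion = "closest-sens-spec",
                 tie_break = "max(sens+spec), then smaller threshold"),
            class = "cutoff_model")
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf("Cutoff %.4g (%s): training sens %.3f, spec %.3f, AUC %.3f\n",
              x$cutoff, x$criterion, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  # prop.test warns about the asymptotic p-value in small cells; only the
  # Wilson interval is used here
  ci <- suppressWarnings(
    stats::prop.test(k, n, correct = FALSE, conf.level = conf))$conf.int
  as.numeric(ci)
}

#' Evaluate a diagnostic cutoff on labelled scores
#'
#' Test-positive means score >= cutoff. Reports the 2x2 cross-tabulation,
#' sensitivity and specificity with Wilson 95% CIs, and Pearson's
#' chi-square for independence (df 1, no continuity correction).
#'
#' @param scores numeric scores.
#' @param labels logical lesion status.
#' @param cutoff decision threshold.
#' @param conf confidence level for the Wilson intervals.
#' @return A `validation_report`.
#' @export
evaluate_cutoff <- function(scores, labels, cutoff, conf = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("evaluation needs both classes non-empty")
  test_pos <- scores >= cutoff
  tab <- matrix(c(sum(test_pos & labels), sum(test_pos & !labels),
                  sum(!test_pos & labels), sum(!test_pos & !labels)),
                nrow = 2, byrow = TRUE,
                dimnames = list(test = c("positive", "negative"),
                                lesion = c("present", "absent")))
  sens <- tab[1, 1] / sum(tab[, 1])
  spec <- tab[2, 2] / sum(tab[, 2])
  chi <- NA_real_; p <- NA_real_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    # the Pearson statistic is exact arithmetic; its asymptotic p-value is
    # approximate in small cells, which the report leaves to the reader
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(table = tab, cutoff = cutoff,
                 sensitivity = sens,
                 sensitivity_ci = wilson_ci(tab[1, 1], sum(tab[, 1]), conf),
                 specificity = spec,
                 specificity_ci = wilson_ci(tab[2, 2], sum(tab[, 2]), conf),
                 ci_method = "Wilson", conf = conf,
                 chi_square = chi, df = 1L, p = p, n = sum(tab),
                 positive_call = "score >= cutoff"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation at cutoff %.4g (n = %d)\n", x$cutoff, x$n))
  print(x$table)
  cat(sprintf("  sensitivity %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2]))
  cat(sprintf("  specificity %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$specificity, 100 * x$specificity_ci[1],
              100 * x$specificity_ci[2]))
  if (!is.na(x$chi_square))
    cat(sprintf("  Pearson chi-square(%d) = %.2f, P = %.3g\n", x$df,
                x$chi_square, x$p))
  invisible(x)
}
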