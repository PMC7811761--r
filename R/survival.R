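#' Kaplan-Meier product-limit estimate
#'
#' Hand-rolled product-limit estimator so the tie and median conventions
#' are explicit: at tied times events precede censorings, and the median
#' is the first time at which S(t) <= 0.5 (undefined while S stays above
#' 0.5). Cross-checked against survival::survfit in the test suite.
#'
#' @param times follow-up in months, >= 0.
#' @param events logical (TRUE = death observed).
#' @return A `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median_survival` (NA if undefined).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  events <- as.logical(events)
  ut <- sort(unique(times[events]))
  n <- length(times)
  surv <- numeric(length(ut))
  n_risk <- integer(length(ut))
  n_event <- integer(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk[i] <- sum(times >= t)   # censorings at t still at risk for events at t
    n_event[i] <- sum(times == t & events)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  # 1e-9 slack: S can equal 0.5 exactly (even n, no prior censoring) and
  # the cumulative product must not miss it through float rounding
  med <- if (any(surv <= 0.5 + 1e-9)) ut[which(surv <= 0.5 + 1e-9)[1L]]
         else NA_real_
  structure(list(time = ut, surv = surv, n_risk = n_risk,
                 n_event = n_event, median_survival = med,
                 n = n, n_events = sum(events)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d subjects, %d events; median %s months\n",
              x$n, x$n_events,
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival)))
  invisible(x)
}

#' Mantel-Cox (log-rank) test between two arms
#'
#' @param times,events follow-up and event indicators.
#' @param group binary arm indicator.
#' @return List `chi_square`, `df` (1), `p`.
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  if (length(unique(group)) != 2L) stop("log-rank needs exactly two arms")
  if (!any(events)) stop("log-rank undefined: zero events overall")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi, df = 1L,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via survival::coxph; rows with missing
#' covariates are excluded and counted. Ties handled by the Breslow
#' approximation by default (Efron available).
#'
#' @param cohort data.frame.
#' @param time_col,event_col column names.
#' @param covariates character vector of covariate columns.
#' @param ties `"breslow"` or `"efron"`.
#' @return A `cox_fit`: coefficients, hazard ratios, SEs, p-values, model
#'   chi-square with df, ties method, `n_excluded`.
#' @export
cox_fit <- function(cohort, time_col = "os_months", event_col = "os_event",
                    covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cols <- c(time_col, event_col, covariates)
  stopifnot(all(cols %in% names(cohort)))
  df <- cohort[, cols]
  keep <- stats::complete.cases(df)
  df <- df[keep, ]
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v) && stats::sd(v) == 0)
      stop("covariate with zero variance: ", cv)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  sm <- summary(fit)
  structure(list(covariates = covariates,
                 coefficients = stats::coef(fit),
                 hazard_ratios = exp(stats::coef(fit)),
                 se = sm$coefficients[, "se(coef)"],
                 p_values = sm$coefficients[, "Pr(>|z|)"],
                 model_chi_square = unname(sm$logtest["test"]),
                 df = unname(sm$logtest["df"]),
                 model_p = unname(sm$logtest["pvalue"]),
                 ties = ties, n = sm$n, n_events = sm$nevent,
                 n_excluded = sum(!keep)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, %d events, %d excluded\n",
              x$ties, x$n, x$n_events, x$n_excluded))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    se = x$se, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("model chi-square %.2f(%d), P = %.4g\n", x$model_chi_square,
              x$df, x$model_p))
  invisible(x)
}

km_median <- function(times, events) km_estimate(times, events)$median_survival

#' Prognostic cutoff by maximal median-survival difference
#'
#' Screens the continuous marker by Cox regression first; the cutoff scan
#' only proceeds if the screen is significant at `screen_alpha`
#' (overridable with `force`). The scan dichotomizes the marker at each
#' grid value, keeps cutoffs whose arms both hold at least
#' `min_arm_fraction` of the cohort and have defined Kaplan-Meier
#' medians, and selects the cutoff maximizing |median(high) -
#' median(low)| (ties -> smaller cutoff). The selected cutoff is
#' evaluated by log-rank and, when adjustment covariates are supplied, an
#' adjusted Cox model. The log-rank p at the selected cutoff is reported
#' unadjusted; `multiple_testing_warning` flags the selection-induced
#' optimism.
#'
#' @param cohort data.frame with marker, time and event columns.
#' @param marker_col marker column (e.g. % GFAP+ non-classical monocytes).
#' @param time_col,event_col survival columns.
#' @param covariates covariates for the adjusted Cox model at the selected
#'   cutoff (NULL to skip).
#' @param grid cutoff grid; default the unique observed marker values.
#' @param min_arm_fraction minimum fraction of subjects per arm.
#' @param screen_alpha significance gate for the continuous Cox screen.
#' @param force proceed even if the screen fails (decision is recorded).
#' @param ties ties method passed to [cox_fit()].
#' @return A `survival_cutoff` (or, when the screen fails and `force` is
#'   FALSE, a `survival_screen` carrying only the screen result).
#' @export
max_median_diff_cutoff <- function(cohort, marker_col,
                                   time_col = "os_months",
                                   event_col = "os_event",
                                   covariates = NULL, grid = NULL,
                                   min_arm_fraction = 0.10,
                                   screen_alpha = 0.05, force = FALSE,
                                   ties = "breslow") {
  keep <- stats::complete.cases(cohort[, c(marker_col, time_col, event_col)])
  df <- cohort[keep, ]
  screen <- cox_fit(df, time_col, event_col, covariates = marker_col,
                    ties = ties)
  screen_p <- unname(screen$p_values[1])
  if (screen_p >= screen_alpha && !force) {
    return(structure(list(marker = marker_col, screen = screen,
                          screen_p = screen_p, scanned = FALSE,
                          reason = sprintf(
                            "continuous Cox screen p = %.3g >= %.3g; scan not run",
                            screen_p, screen_alpha)),
                     class = "survival_screen"))
  }
  x <- df[[marker_col]]
  tt <- df[[time_col]]
  ev <- as.logical(df[[event_col]])
  if (is.null(grid)) grid <- sort(unique(x))
  n <- nrow(df)
  min_arm <- ceiling(min_arm_fraction * n)
  scan <- data.frame(cutoff = grid, n_low = NA_integer_, n_high = NA_integer_,
                     median_low = NA_real_, median_high = NA_real_,
                     admissible = FALSE, skip_reason = "")
  for (i in seq_along(grid)) {
    hi <- x > grid[i]
    scan$n_low[i] <- sum(!hi); scan$n_high[i] <- sum(hi)
    if (sum(hi) < min_arm || sum(!hi) < min_arm) {
      scan$skip_reason[i] <- "arm below minimum size"
      next
    }
    m_lo <- km_median(tt[!hi], ev[!hi])
    m_hi <- km_median(tt[hi], ev[hi])
    scan$median_low[i] <- m_lo; scan$median_high[i] <- m_hi
    if (is.na(m_lo) || is.na(m_hi)) {
      scan$skip_reason[i] <- "undefined median in an arm"
      next
    }
    scan$admissible[i] <- TRUE
  }
  adm <- which(scan$admissible)
  if (!length(adm))
    stop("no admissible cutoff: ",
         paste(unique(scan$skip_reason[scan$skip_reason != ""]),
               collapse = "; "))
  diffs <- abs(scan$median_high[adm] - scan$median_low[adm])
  best <- adm[which(diffs >= max(diffs) - 1e-9)[1L]]  # ties -> smaller cutoff
  cutoff <- scan$cutoff[best]
  hi <- x > cutoff
  lr <- logrank_test(tt, ev, hi)
  adj <- NULL
  if (!is.null(covariates)) {
    df$.arm_high <- as.numeric(hi)
    adj <- cox_fit(df, time_col, event_col,
                   covariates = c(".arm_high", covariates), ties = ties)
  }
  structure(list(marker = marker_col, cutoff = cutoff,
                 n_low = scan$n_low[best], n_high = scan$n_high[best],
                 median_low = scan$median_low[best],
                 median_high = scan$median_high[best],
                 logrank_chi_square = lr$chi_square, logrank_df = lr$df,
                 logrank_p = lr$p,
                 screen = screen, screen_p = screen_p,
                 forced = screen_p >= screen_alpha,
                 adjusted_cox = adj, scan = scan, scanned = TRUE,
                 multiple_testing_warning = paste(
                   "cutoff selected by maximizing the median-survival",
                   "difference over the grid; the reported log-rank p is",
                   "unadjusted for this selection and is optimistic")),
            class = "survival_cutoff")
}

#' @export
print.survival_cutoff <- function(x, ...) {
  cat(sprintf("Prognostic cutoff for %s: %.4g\n", x$marker, x$cutoff))
  cat(sprintf("  arms: %d low (median %.2f mo) vs %d high (median %.2f mo)\n",
              x$n_low, x$median_low, x$n_high, x$median_high))
  cat(sprintf("  log-rank chi-square %.2f(%d), P = %.4g\n",
              x$logrank_chi_square, x$logrank_df, x$logrank_p))
  cat(sprintf("  continuous-marker screen p = %.4g%s\n", x$screen_p,
              if (x$forced) " (scan forced past a failed screen)" else ""))
  if (!is.null(x$adjusted_cox))
    cat(sprintf("  adjusted HR (high vs low) = %.3f, model chi-square %.2f(%d), P = %.4g\n",
                x$adjusted_cox$hazard_ratios[1],
                x$adjusted_cox$model_chi_square, x$adjusted_cox$df,
                x$adjusted_cox$p_values[1]))
  cat("  note:", x$multiple_testing_warning, "\n")
  invisible(x)
}

#' @export
print.survival_screen <- function(x, ...) {
  cat("Prognostic scan for", x$marker, "not run:", x$reason, "\n")
  invisible(x)
}
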