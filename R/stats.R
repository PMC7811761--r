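#' Group comparisons with the cohort's test-selection rules
#'
#' `method = "auto"` screens each group for normality (Shapiro-Wilk at
#' alpha 0.05) and uses one-way ANOVA followed by Tukey's multiple
#' comparison test when all groups pass, otherwise rank tests
#' (Mann-Whitney U for two groups; Kruskal-Wallis with pairwise
#' Mann-Whitney follow-ups for more). Repeated analyses are Bonferroni
#' corrected: adjusted p = min(1, m x raw p).
#'
#' @param cohort a data.frame (typically a [cohort_table()] merged with
#'   profiles).
#' @param variable numeric column to compare.
#' @param grouping grouping column (default `diagnosis_group`).
#' @param method `auto`, `anova_tukey`, `mann_whitney`, `kruskal_wallis`.
#' @param n_comparisons Bonferroni m; default = number of pairwise tests.
#' @param alpha significance level (default 0.05).
#' @return A `group_comparison` data.frame: one row per comparison
#'   (omnibus first when >2 groups) with statistic, raw and adjusted p,
#'   and the test used; attribute `n_missing` counts dropped values.
#' @export
compare_groups <- function(cohort, variable, grouping = "diagnosis_group",
                           method = c("auto", "anova_tukey", "mann_whitney",
                                      "kruskal_wallis"),
                           n_comparisons = NULL, alpha = 0.05) {
  method <- match.arg(method)
  x <- cohort[[variable]]
  g <- as.character(cohort[[grouping]])
  keep <- !is.na(x) & !is.na(g)
  n_missing <- sum(!keep)
  x <- x[keep]; g <- g[keep]
  groups <- split(x, g)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  if (method == "auto") {
    normal <- vapply(groups, function(v) {
      if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v[seq_len(min(length(v), 5000))])$p.value > 0.05
    }, logical(1))
    method <- if (all(normal)) "anova_tukey" else
      if (length(groups) == 2L) "mann_whitney" else "kruskal_wallis"
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- list()
  add <- function(cmp, test, stat, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, comparison = cmp, test_used = test,
      statistic = stat, p_raw = p, note = note, stringsAsFactors = FALSE)
  }
  gf <- factor(g)
  if (method == "anova_tukey") {
    fit <- stats::aov(x ~ gf)
    an <- summary(fit)[[1]]
    if (length(groups) > 2L)
      add("omnibus", "anova", an[1, "F value"], an[1, "Pr(>F)"])
    tk <- stats::TukeyHSD(fit)$gf
    for (i in seq_len(nrow(tk)))
      add(rownames(tk)[i], "anova_tukey", tk[i, "diff"], tk[i, "p adj"],
          note = "Tukey-adjusted")
  } else {
    if (length(groups) > 2L && method == "kruskal_wallis") {
      kw <- stats::kruskal.test(x, gf)
      add("omnibus", "kruskal_wallis", unname(kw$statistic), kw$p.value)
    }
    for (pr in pairs) {
      a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
      if (length(a) < 2L || length(b) < 2L) {
        add(paste(pr, collapse = " vs "), "mann_whitney", NA, NA,
            note = "skipped: group with <2 observations")
        next
      }
      exact <- length(a) <= 12L && length(b) <= 12L &&
        !any(duplicated(c(a, b)))
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = !exact))
      add(paste(pr, collapse = " vs "), "mann_whitney",
          unname(wt$statistic), wt$p.value,
          note = if (exact) "exact" else "normal approximation")
    }
  }
  out <- do.call(rbind, rows)
  m <- if (is.null(n_comparisons)) sum(out$comparison != "omnibus") else
    n_comparisons
  out$p_adjusted <- ifelse(out$test_used == "anova_tukey", out$p_raw,
                           pmin(1, m * out$p_raw))
  out$m <- m
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  attr(out, "n_missing") <- n_missing
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Correlation between two cohort variables
#'
#' Spearman rank correlation by default (robust for skewed rare-event
#' fractions); Pearson available. Pairs with missing values are dropped
#' and the complete-pair count reported.
#'
#' @param cohort data.frame.
#' @param x,y column names.
#' @param method `"spearman"` or `"pearson"`.
#' @return A `correlation_result` list: `x`, `y`, `method`, `r`, `p`, `n`.
#' @export
correlate <- function(cohort, x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  xv <- cohort[[x]]; yv <- cohort[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("correlation undefined: zero variance in ",
         if (stats::sd(xv) == 0) x else y)
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method))
  structure(list(x = x, y = y, method = method, r = unname(ct$estimate),
                 p = ct$p.value, n = length(xv)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s ~ %s (%s): r = %.3f, P = %.4g, n = %d\n",
              x$y, x$x, x$method, x$r, x$p, x$n))
  invisible(x)
}
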