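#' Per-sample monocyte metrics
#'
#' Reduces a gated, positivity-labelled sample to the metrics all
#' downstream analyses use. "CD16+ monocytes" means the union of the
#' intermediate (CD14+CD16+) and non-classical (CD14-CD16+) subsets;
#' `pct_gfap_cd16` is 100 x (GFAP+ events in that union) / (events in that
#' union). Absolute counts are (population events / CD45+ leukocyte
#' events) x the sample's leukocyte concentration.
#'
#' Percentages come in two flavours: the raw measured fraction (reported
#' as-is, no background subtraction), and a `background_adjusted` variant
#' that removes the expected false-positive contribution of the positivity
#' quantile q, p_adj = (p_raw/100 - (1-q)) / q, used when comparing to
#' ground truth. The adjustment assumes marker-negative events share the
#' background distribution the threshold was derived from.
#'
#' @param gating a `gating_result`.
#' @param gfap_flags,plp1_flags per-event logical flags from
#'   [label_marker_positive()] (`plp1_flags` optional).
#' @param wbc_count leukocytes/ul, or `NA` (absolute fields then missing).
#' @param positivity_quantile the quantile used for the positivity
#'   threshold (for the background adjustment; NA disables it).
#' @param min_denominator CD16+ event floor below which GFAP percentages
#'   are flagged low-confidence.
#' @return A `monocyte_profile` (one-row data.frame plus flags).
#' @export
monocyte_profile <- function(gating, gfap_flags, plp1_flags = NULL,
                             wbc_count = NA, positivity_quantile = 0.995,
                             min_denominator = 100) {
  stopifnot(inherits(gating, "gating_result"))
  a <- gating$assignment
  cd16 <- a %in% c("intermediate_mono", "nonclassical_mono")
  ncl <- a == "nonclassical_mono"
  n_cd16 <- sum(cd16)
  n_ncl <- sum(ncl)
  flags <- character()
  pct <- function(flagvec, denom_idx) {
    n_d <- sum(denom_idx)
    if (n_d == 0L) return(NA_real_)
    100 * sum(flagvec[denom_idx], na.rm = TRUE) / n_d
  }
  adj <- function(p) {
    if (is.na(p) || is.na(positivity_quantile)) return(NA_real_)
    q <- positivity_quantile
    max(0, (p / 100 - (1 - q)) / q) * 100
  }
  pct_gfap_cd16 <- pct(gfap_flags, cd16)
  pct_gfap_ncl <- pct(gfap_flags, ncl)
  if (n_cd16 == 0L) flags <- c(flags, "zero CD16+ denominator")
  else if (n_cd16 < min_denominator)
    flags <- c(flags, sprintf("low-confidence: CD16+ denominator %d < %d",
                              n_cd16, as.integer(min_denominator)))
  if (n_ncl == 0L) flags <- c(flags, "zero non-classical denominator")
  pct_plp1_cd16 <- if (is.null(plp1_flags)) NA_real_ else pct(plp1_flags, cd16)
  pct_dual_cd16 <- if (is.null(plp1_flags)) NA_real_ else
    pct(gfap_flags & plp1_flags, cd16)
  cnt <- gating$counts
  n_leuk <- gating$n_leukocyte
  abs_of <- function(n_events) {
    if (is.na(wbc_count) || n_leuk == 0L) return(NA_real_)
    n_events / n_leuk * wbc_count
  }
  n_gfap_cd16 <- sum(gfap_flags[cd16], na.rm = TRUE)
  out <- data.frame(
    sample_id = gating$sample_id,
    n_leukocyte_events = n_leuk,
    n_cd16_events = n_cd16,
    pct_monocytes_of_leukocytes = if (n_leuk) 100 * gating$n_monocyte / n_leuk else NA_real_,
    pct_classical = if (gating$n_monocyte) 100 * cnt[["classical_mono"]] / gating$n_monocyte else NA_real_,
    pct_intermediate = if (gating$n_monocyte) 100 * cnt[["intermediate_mono"]] / gating$n_monocyte else NA_real_,
    pct_nonclassical = if (gating$n_monocyte) 100 * cnt[["nonclassical_mono"]] / gating$n_monocyte else NA_real_,
    pct_gfap_cd16 = pct_gfap_cd16,
    pct_gfap_cd16_adj = adj(pct_gfap_cd16),
    pct_gfap_nonclassical = pct_gfap_ncl,
    pct_gfap_nonclassical_adj = adj(pct_gfap_ncl),
    pct_plp1_cd16 = pct_plp1_cd16,
    pct_dual_cd16 = pct_dual_cd16,
    abs_gfap_cd16 = abs_of(n_gfap_cd16),
    abs_classical = abs_of(cnt[["classical_mono"]]),
    abs_intermediate = abs_of(cnt[["intermediate_mono"]]),
    abs_nonclassical = abs_of(cnt[["nonclassical_mono"]]),
    stringsAsFactors = FALSE)
  structure(out, flags = flags, class = c("monocyte_profile", "data.frame"))
}

#' @export
print.monocyte_profile <- function(x, ...) {
  cat("Monocyte profile:", x$sample_id, "\n")
  cat(sprintf("  GFAP+ of CD16+ monocytes: %.3f%% (n=%d)\n",
              x$pct_gfap_cd16, x$n_cd16_events))
  cat(sprintf("  GFAP+ of non-classical:   %.3f%%\n", x$pct_gfap_nonclassical))
  if (!is.na(x$abs_gfap_cd16))
    cat(sprintf("  absolute GFAP+CD16+: %.1f cells/ul\n", x$abs_gfap_cd16))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Gate, threshold and profile one sample in a single call
#'
#' Convenience wrapper running the gating tree, the lymphocyte-background
#' thresholds for GFAP (and PLP1 when present) and [monocyte_profile()].
#'
#' @param table an [event_table()].
#' @param tree gate tree (default [default_timascan_tree()]).
#' @param quantile positivity quantile.
#' @param wbc_count leukocytes/ul or NA.
#' @param ... passed to [monocyte_profile()].
#' @return A `monocyte_profile`.
#' @export
profile_sample <- function(table, tree = default_timascan_tree(),
                           quantile = 0.995, wbc_count = NA, ...) {
  gating <- apply_gate_tree(table, tree)
  thr_g <- lymphocyte_background_threshold(table, gating, "GFAP",
                                           quantile = quantile)
  gfap <- label_marker_positive(table, gating, "GFAP", thr_g)
  plp1 <- NULL
  if ("PLP1" %in% table$channels) {
    thr_p <- lymphocyte_background_threshold(table, gating, "PLP1",
                                             quantile = quantile)
    plp1 <- label_marker_positive(table, gating, "PLP1", thr_p)
  }
  monocyte_profile(gating, gfap, plp1, wbc_count = wbc_count,
                   positivity_quantile = quantile, ...)
}
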