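# Small builders shared across test files.

# two-population sample: lymphocytes + one monocyte subset mix, scaled down
small_sample <- function(n_events = 20000, gfap_fracs = NULL, seed = 1L,
                         marker_shift = 2.5) {
  simulate_sample(sample_spec(
    n_events = n_events,
    populations = default_populations(gfap_fracs = gfap_fracs),
    marker_shift = marker_shift, seed = seed))
}

tiny_event_table <- function(n = 5, channels = c(gating_channels(), "PLP1"),
                             seed = 42L) {
  set.seed(seed)
  m <- matrix(stats::runif(n * length(channels), 0, 5), nrow = n,
              dimnames = list(NULL, channels))
  event_table(m, sample_id = "tiny")
}

# cohort metadata data.frame with sane defaults, overridable per column
meta_row <- function(sample_id = "S1", patient_id = sample_id,
                     diagnosis_group = "GBM", ...) {
  out <- data.frame(sample_id = sample_id, patient_id = patient_id,
                    diagnosis_group = diagnosis_group,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# brute-force closest-sens-spec oracle, independent of roc_curve()
brute_force_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  best <- NULL
  for (th in cand) {
    sens <- mean(scores[labels] >= th)
    spec <- mean(scores[!labels] < th)
    key <- c(abs(sens - spec), -(sens + spec), th)
    if (is.null(best) || key[1] < best[1] - 1e-9 ||
        (abs(key[1] - best[1]) <= 1e-9 && key[2] < best[2] - 1e-9) ||
        (abs(key[1] - best[1]) <= 1e-9 && abs(key[2] - best[2]) <= 1e-9 &&
         key[3] < best[3]))
      best <- c(key, sens, spec)
  }
  list(cutoff = best[3], sensitivity = best[4], specificity = best[5])
}

# brute-force survival cutoff oracle using survival::survfit medians
brute_force_survival_cutoff <- function(times, events, marker, grid,
                                        min_arm) {
  best <- NULL
  for (cu in grid) {
    hi <- marker > cu
    if (sum(hi) < min_arm || sum(!hi) < min_arm) next
    med <- function(sel) {
      if (sum(events[sel]) == 0) return(NA_real_)
      sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
      # first time S(t) <= 0.5 (same 1e-9 slack as the implementation)
      i <- which(sf$surv <= 0.5 + 1e-9 & sf$n.event > 0)
      if (!length(i)) NA_real_ else sf$time[i[1]]
    }
    m0 <- med(!hi); m1 <- med(hi)
    if (is.na(m0) || is.na(m1)) next
    d <- abs(m1 - m0)
    if (is.null(best) || d > best$diff + 1e-9)
      best <- list(cutoff = cu, diff = d, median_low = m0, median_high = m1)
  }
  best
}
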