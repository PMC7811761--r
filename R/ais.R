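#' Flag threshold exceedances in a stroke marker time course
#'
#' An exceedance is a timepoint with marker strictly above the cutoff
#' (a value exactly at the cutoff is not an exceedance); the decision
#' window contains the timepoints at or before `window_hours` after
#' onset.
#'
#' @param series data.frame with `hours_since_onset` and `pct_gfap_cd16`
#'   for one patient (strictly increasing times).
#' @param cutoff % GFAP+CD16+ monocytes (default 0.6).
#' @param window_hours decision window after onset (default 8).
#' @return A `timecourse_flags` data.frame with `exceeds_cutoff` and
#'   `in_window` columns; cutoff and window kept as attributes.
#' @export
flag_timecourse <- function(series, cutoff = 0.6, window_hours = 8) {
  stopifnot(all(c("hours_since_onset", "pct_gfap_cd16") %in% names(series)))
  t <- series$hours_since_onset
  if (length(t) < 1L || any(t < 0)) stop("need >= 1 timepoint with hours >= 0")
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  out <- series
  out$exceeds_cutoff <- series$pct_gfap_cd16 > cutoff
  out$in_window <- t <= window_hours
  structure(out, cutoff = cutoff, window_hours = window_hours,
            class = c("timecourse_flags", "data.frame"))
}

#' Classify infarct size from a flagged time course
#'
#' A large infarct is predicted when at least `min_points` in-window
#' exceedances occur ("multiple time points above the cutoff, all within
#' the window"). When infarct volume is known, the truth label is volume
#' >= `large_volume` cm3 and concordance is reported.
#'
#' @param flags a [flag_timecourse()] result.
#' @param min_points minimum in-window exceedances to call a large
#'   infarct (default 2).
#' @param infarct_volume cm3, optional (taken from the flags table when
#'   present).
#' @param large_volume truth threshold in cm3 (default 100, >= convention).
#' @return An `infarct_call` list.
#' @export
classify_infarct_size <- function(flags, min_points = 2,
                                  infarct_volume = NULL,
                                  large_volume = 100) {
  stopifnot(inherits(flags, "timecourse_flags"))
  n_exc <- sum(flags$exceeds_cutoff & flags$in_window)
  if (is.null(infarct_volume) && "infarct_volume" %in% names(flags))
    infarct_volume <- flags$infarct_volume[1]
  truth <- if (is.null(infarct_volume) || is.na(infarct_volume)) NA else
    infarct_volume >= large_volume
  predicted <- n_exc >= min_points
  structure(list(patient_id = if ("patient_id" %in% names(flags))
                   flags$patient_id[1] else NA_character_,
                 predicted_large = predicted,
                 n_exceedances_in_window = n_exc,
                 truth_large = truth,
                 concordant = if (is.na(truth)) NA else predicted == truth,
                 min_points = min_points,
                 cutoff = attr(flags, "cutoff"),
                 window_hours = attr(flags, "window_hours")),
            class = "infarct_call")
}

#' @export
print.infarct_call <- function(x, ...) {
  cat(sprintf("%s: %d in-window exceedance(s) of %.2f%% -> predicted %s infarct",
              x$patient_id, x$n_exceedances_in_window, x$cutoff,
              if (x$predicted_large) "LARGE" else "small"))
  if (!is.na(x$truth_large))
    cat(sprintf(" (truth %s, %s)", if (x$truth_large) "large" else "small",
                if (x$concordant) "concordant" else "discordant"))
  cat("\n")
  invisible(x)
}

#' Classify every patient in a stroke time-series table
#'
#' @param series data.frame with `patient_id`, `hours_since_onset`,
#'   `pct_gfap_cd16` and optionally `infarct_volume`.
#' @param cutoff,window_hours,min_points see [flag_timecourse()] and
#'   [classify_infarct_size()].
#' @return data.frame, one row per patient.
#' @export
classify_ais_cohort <- function(series, cutoff = 0.6, window_hours = 8,
                                min_points = 2) {
  calls <- lapply(split(series, series$patient_id), function(s) {
    cl <- classify_infarct_size(
      flag_timecourse(s[order(s$hours_since_onset), ], cutoff, window_hours),
      min_points = min_points)
    data.frame(patient_id = cl$patient_id,
               predicted_large = cl$predicted_large,
               n_exceedances_in_window = cl$n_exceedances_in_window,
               truth_large = cl$truth_large,
               concordant = cl$concordant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
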