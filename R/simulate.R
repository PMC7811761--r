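# Synthetic cytometry cohorts with known ground truth.
#
# The event model is a per-population multivariate Gaussian with diagonal
# covariance on the working scale (asinh-transformed fluorescence, linear
# scatter). Doublets are encoded as a population whose FSC-A sits at twice
# the singlet level while FSC-H stays at singlet level. GFAP/PLP1 for
# marker-negative events of every population are drawn from one shared
# background distribution (the lymphocyte background), which is what makes
# a lymphocyte-based positivity threshold well-posed; marker-positive
# events get an additive intensity shift.

POPULATION_NAMES <- c("debris", "doublet", "lymphocyte", "classical_mono",
                      "intermediate_mono", "nonclassical_mono", "dendritic",
                      "other_leukocyte")

#' Population specification for the event simulator
#'
#' @param name one of `debris, doublet, lymphocyte, classical_mono,
#'   intermediate_mono, nonclassical_mono, dendritic, other_leukocyte`.
#' @param weight expected fraction of events.
#' @param mean,sd named numeric vectors of per-channel location and spread
#'   on the working scale (GFAP/PLP1 are governed by the sample-level
#'   background model, not by these).
#' @param gfap_pos_fraction,plp1_pos_fraction fraction of the population
#'   carrying the marker (meaningful for monocyte subsets).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, weight, mean, sd,
                            gfap_pos_fraction = 0, plp1_pos_fraction = 0) {
  name <- match.arg(name, POPULATION_NAMES)
  stopifnot(weight >= 0, all(sd > 0),
            gfap_pos_fraction >= 0, gfap_pos_fraction <= 1,
            plp1_pos_fraction >= 0, plp1_pos_fraction <= 1)
  structure(list(name = name, weight = weight, mean = mean, sd = sd,
                 gfap_pos_fraction = gfap_pos_fraction,
                 plp1_pos_fraction = plp1_pos_fraction),
            class = "population_spec")
}

# Default leukocyte mixture. Scatter in arbitrary linear units (~1e5 scale),
# fluorescence on the asinh scale; populations are separated by >= 4 SD on
# every channel the default gate tree cuts on.
default_population_params <- function() {
  # columns: FSC-A, FSC-H, SSC-A (x1000), CD45, HLA-DR, CD300e, CD14, CD16
  tab <- rbind(
    debris            = c(30,  30,  12,  0.5, 0.4, 0.4, 0.5, 0.5),
    doublet           = c(300, 155, 70,  4.7, 2.0, 1.5, 2.0, 1.0),
    lymphocyte        = c(120, 120, 35,  5.0, 0.8, 0.5, 0.5, 0.6),
    classical_mono    = c(180, 180, 90,  4.5, 4.0, 4.0, 4.5, 0.8),
    intermediate_mono = c(185, 185, 95,  4.5, 4.2, 4.0, 4.2, 3.8),
    nonclassical_mono = c(175, 175, 85,  4.5, 4.2, 4.0, 1.2, 4.2),
    dendritic         = c(170, 170, 80,  4.5, 4.5, 0.8, 1.0, 0.8),
    other_leukocyte   = c(190, 190, 210, 3.5, 0.6, 0.8, 1.2, 0.7))
  sds <- rbind(
    debris            = c(8,  8,  4,  rep(0.3, 5)),
    doublet           = c(30, 20, 15, rep(0.4, 5)),
    lymphocyte        = c(15, 8,  8,  rep(0.3, 5)),
    classical_mono    = c(20, 10, 15, rep(0.3, 5)),
    intermediate_mono = c(20, 10, 15, rep(0.3, 5)),
    nonclassical_mono = c(20, 10, 15, rep(0.3, 5)),
    dendritic         = c(20, 10, 15, rep(0.3, 5)),
    other_leukocyte   = c(25, 12, 30, rep(0.3, 5)))
  ch <- c("FSC-A", "FSC-H", "SSC-A", "CD45", "HLA-DR", "CD300e", "CD14", "CD16")
  colnames(tab) <- colnames(sds) <- ch
  tab[, 1:3] <- tab[, 1:3] * 1000
  sds[, 1:3] <- sds[, 1:3] * 1000
  list(mean = tab, sd = sds)
}

#' Default leukocyte population mix
#'
#' The default weights emulate a dexamethasone-exposed brain-tumour
#' cohort: non-classical monocytes are a minority of the CD16+ pool
#' (glucocorticoids deplete them preferentially), which also keeps the
#' pooled CD16+ positivity on the sub-percent scale while per-sample
#' non-classical positivity can reach tens of percent.
#'
#' @param gfap_fracs named vector of true GFAP-positive fractions per
#'   population (proportions, e.g. `c(intermediate_mono = 0.02)`).
#' @param plp1_fracs same for PLP1.
#' @param weights named population weights; must sum to 1.
#' @return List of [population_spec()] objects.
#' @export
default_populations <- function(gfap_fracs = NULL, plp1_fracs = NULL,
                                weights = NULL) {
  if (is.null(weights))
    weights <- c(debris = 0.05, doublet = 0.03, lymphocyte = 0.30,
                 classical_mono = 0.18, intermediate_mono = 0.045,
                 nonclassical_mono = 0.008, dendritic = 0.015,
                 other_leukocyte = 0.372)
  par <- default_population_params()
  lapply(names(weights), function(nm) {
    population_spec(nm, weights[[nm]], par$mean[nm, ], par$sd[nm, ],
                    gfap_pos_fraction = if (nm %in% names(gfap_fracs)) gfap_fracs[[nm]] else 0,
                    plp1_pos_fraction = if (nm %in% names(plp1_fracs)) plp1_fracs[[nm]] else 0)
  })
}

#' Single-sample simulation specification
#'
#' @param sample_id sample name.
#' @param n_events total events to draw.
#' @param populations list of [population_spec()]; weights must sum to 1.
#' @param marker_shift additive intensity shift on the marker channel for
#'   marker-positive events (working scale). The default 2.5 is ~7
#'   background SDs, i.e. a cleanly resolved positive population.
#' @param background mean/sd of the shared GFAP and PLP1 background.
#' @param seed integer seed; identical spec + seed gives identical events.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(sample_id = "S1", n_events = 100000,
                        populations = default_populations(),
                        marker_shift = 2.5,
                        background = c(mean = 0.5, sd = 0.35),
                        seed = 1L) {
  stopifnot(n_events >= 1, marker_shift > 0)
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("spec error: population weights sum to ", sum(w), ", not 1")
  structure(list(sample_id = sample_id, n_events = as.integer(n_events),
                 populations = populations, marker_shift = marker_shift,
                 background = background, seed = as.integer(seed)),
            class = "sample_spec")
}

#' Simulate one event-level sample
#'
#' Event counts per population are multinomial in the spec weights; within
#' each population a Bernoulli(`gfap_pos_fraction`) subset receives
#' `+marker_shift` on GFAP (likewise PLP1). Marker-negative events of all
#' populations share the lymphocyte background distribution.
#'
#' @param spec a [sample_spec()].
#' @return An [event_table()] with `truth_labels` and attributes
#'   `truth_gfap`, `truth_plp1` (per-event logical ground truth).
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  set.seed(spec$seed)
  w <- vapply(spec$populations, `[[`, numeric(1), "weight")
  counts <- as.integer(stats::rmultinom(1, spec$n_events, w))
  gate_ch <- c("FSC-A", "FSC-H", "SSC-A", "CD45", "HLA-DR", "CD300e",
               "CD14", "CD16")
  n <- spec$n_events
  values <- matrix(NA_real_, n, length(gate_ch) + 2L,
                   dimnames = list(NULL, c(gate_ch, "GFAP", "PLP1")))
  labels <- character(n)
  truth_gfap <- logical(n)
  truth_plp1 <- logical(n)
  bg <- spec$background
  row0 <- 0L
  for (i in seq_along(spec$populations)) {
    p <- spec$populations[[i]]
    k <- counts[i]
    if (k == 0L) next
    idx <- row0 + seq_len(k)
    for (ch in gate_ch)
      values[idx, ch] <- stats::rnorm(k, p$mean[[ch]], p$sd[[ch]])
    if (p$name != "doublet") {
      # within a singlet, pulse height tracks area: FSC-H rides on the
      # event's own FSC-A (cell-size correlation), not on an independent draw
      values[idx, "FSC-H"] <- values[idx, "FSC-A"] *
        (p$mean[["FSC-H"]] / p$mean[["FSC-A"]]) +
        stats::rnorm(k, 0, p$sd[["FSC-H"]])
    }
    gpos <- stats::runif(k) < p$gfap_pos_fraction
    ppos <- stats::runif(k) < p$plp1_pos_fraction
    values[idx, "GFAP"] <- stats::rnorm(k, bg[["mean"]], bg[["sd"]]) +
      spec$marker_shift * gpos
    values[idx, "PLP1"] <- stats::rnorm(k, bg[["mean"]], bg[["sd"]]) +
      spec$marker_shift * ppos
    labels[idx] <- p$name
    truth_gfap[idx] <- gpos
    truth_plp1[idx] <- ppos
    row0 <- row0 + k
  }
  tbl <- event_table(values, sample_id = spec$sample_id,
                     truth_labels = labels,
                     transform = asinh_transform())
  attr(tbl, "truth_gfap") <- truth_gfap
  attr(tbl, "truth_plp1") <- truth_plp1
  tbl
}

#' Translate target CD16+ positivity into per-subset fractions
#'
#' Given a target % GFAP+ among CD16+ monocytes (intermediate and
#' non-classical pooled) and a target % among non-classical monocytes
#' alone, returns the per-subset positive fractions that realize them for
#' the given subset weights.
#'
#' @param pct_cd16 target % GFAP+ among CD16+ monocytes.
#' @param pct_nonclassical target % GFAP+ among non-classical monocytes.
#' @param w_intermediate,w_nonclassical expected subset weights.
#' @return Named vector of proportions for the two subsets.
#' @export
subset_fractions_for_targets <- function(pct_cd16, pct_nonclassical,
                                         w_intermediate = 0.045,
                                         w_nonclassical = 0.008) {
  t_c <- pct_cd16 / 100
  t_n <- min(pct_nonclassical / 100, 1)
  t_i <- (t_c * (w_intermediate + w_nonclassical) - t_n * w_nonclassical) /
    w_intermediate
  c(intermediate_mono = min(max(t_i, 0), 1), nonclassical_mono = t_n)
}

group_spec <- function(n_samples, frac_meanlog, frac_sdlog = 0.9,
                       nc_ratio_meanlog = log(5.5), nc_ratio_sdlog = 0.75,
                       size_mean_cm = NA, size_coupling = 0.6,
                       age_mean = 60, pct_male = 0.62, dexa_p = 0.5) {
  list(n_samples = n_samples, frac_meanlog = frac_meanlog,
       frac_sdlog = frac_sdlog, nc_ratio_meanlog = nc_ratio_meanlog,
       nc_ratio_sdlog = nc_ratio_sdlog, size_mean_cm = size_mean_cm,
       size_coupling = size_coupling, age_mean = age_mean,
       pct_male = pct_male, dexa_p = dexa_p)
}

#' Default cohort specification
#'
#' Group sizes mirror the cross-sectional glioma/metastasis/healthy design
#' (145 glioblastoma, 28 diffuse astrocytoma, 32 oligodendroglioma, 2
#' WHO-I, 21 metastasis, 38 healthy controls). True GFAP+CD16+ monocyte
#' fractions are lognormal per group, ordered healthy < tumour groups; the
#' non-classical-only fraction is a correlated lognormal multiple of the
#' CD16+ fraction. Glioblastoma survival is Weibull per prognostic arm
#' (true non-classical fraction above/below the prognostic threshold) with
#' arm medians 11.8 and 8.8 months.
#'
#' @param n_events events per simulated sample.
#' @param groups optional named list of group specs (see source).
#' @param prognostic_threshold % GFAP+ non-classical dichotomy driving the
#'   survival hazard.
#' @param os_median_low,os_median_high months; Kaplan-Meier arm medians the
#'   Weibull arms are solved for (low = marker below threshold).
#' @param weibull_shape Weibull shape for survival times.
#' @param censoring_rate probability a subject gets an independent
#'   Uniform(0, `censoring_horizon`) censoring time.
#' @param censoring_horizon months.
#' @return A `cohort_spec` list.
#' @export
default_cohort_spec <- function(n_events = 30000, groups = NULL,
                                prognostic_threshold = 20,
                                os_median_low = 11.8, os_median_high = 8.8,
                                weibull_shape = 2.5,
                                censoring_rate = 0.2,
                                censoring_horizon = 60) {
  if (is.null(groups))
    groups <- list(
      "healthy"             = group_spec(38, log(0.25), 0.7, age_mean = 51, dexa_p = 0),
      "WHO-I"               = group_spec(2, log(0.8), 0.9, size_mean_cm = 3.6, age_mean = 57),
      "diffuse-astrocytoma" = group_spec(28, log(1.0), 0.9, size_mean_cm = 2.8, age_mean = 51),
      "oligodendroglioma"   = group_spec(32, log(1.0), 0.9, size_mean_cm = 3.5, age_mean = 55),
      "GBM"                 = group_spec(145, log(1.2), 0.9, size_mean_cm = 3.5, age_mean = 63, dexa_p = 0.65),
      "metastasis"          = group_spec(21, log(1.3), 0.9, size_mean_cm = 2.7, age_mean = 61, dexa_p = 0.76))
  if (length(groups) == 0L) stop("spec error: cohort needs at least one group")
  bad <- setdiff(names(groups), diagnosis_groups())
  if (length(bad)) stop("spec error: unknown group(s): ", paste(bad, collapse = ", "))
  structure(list(groups = groups, n_events = as.integer(n_events),
                 prognostic_threshold = prognostic_threshold,
                 os_median_low = os_median_low,
                 os_median_high = os_median_high,
                 weibull_shape = weibull_shape,
                 censoring_rate = censoring_rate,
                 censoring_horizon = censoring_horizon),
            class = "cohort_spec")
}

weibull_scale_for_median <- function(median, shape) median / log(2)^(1 / shape)

#' Simulate a whole cohort with ground truth
#'
#' Draws per-sample true marker fractions, clinical covariates and
#' survival, and (optionally) the event-level samples themselves. Pure
#' function of (spec, seed).
#'
#' @param spec a [default_cohort_spec()]-style `cohort_spec`.
#' @param out_dir if non-NULL, event files (one per sample), `cohort.csv`
#'   and `truth.csv` are written there; otherwise everything is returned
#'   in memory.
#' @param seed integer master seed.
#' @param format event-file format when writing (`"csv"` or `"fcs"`).
#' @param events simulate event-level data (set FALSE to generate only the
#'   per-sample truth/metadata, e.g. for statistics-only studies).
#' @return List with `cohort` (a [cohort_table()]), `truth` (data.frame of
#'   generator ground truth) and `events` (list of [event_table()] or file
#'   paths).
#' @export
simulate_cohort <- function(spec, out_dir = NULL, seed = 1L, format = "csv",
                            events = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  rows <- list()
  truth <- list()
  k <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    if (g$n_samples == 0L) next
    for (j in seq_len(g$n_samples)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", gname), j)
      size <- if (is.na(g$size_mean_cm)) NA_real_ else
        g$size_mean_cm * stats::rlnorm(1, 0, 0.3)
      # tumour volume weakly drives the marker fraction (diagnostic groups)
      coupling <- if (is.na(size)) 0 else
        g$size_coupling * (log(size) - log(max(g$size_mean_cm, 0.1)))
      t_c <- exp(g$frac_meanlog + coupling + g$frac_sdlog * stats::rnorm(1))
      t_c <- min(t_c, 45)
      t_n <- min(t_c * stats::rlnorm(1, g$nc_ratio_meanlog, g$nc_ratio_sdlog), 95)
      # the two targets can be jointly infeasible (intermediate fraction
      # would go negative); ground truth records what the event model can
      # actually realize, i.e. the clipped per-subset fractions re-pooled
      fr <- subset_fractions_for_targets(t_c, t_n)
      t_n <- 100 * fr[["nonclassical_mono"]]
      t_c <- 100 * (0.045 * fr[["intermediate_mono"]] +
                      0.008 * fr[["nonclassical_mono"]]) / 0.053
      diam <- if (is.na(size)) rep(NA_real_, 3) else size * stats::rlnorm(3, 0, 0.12)
      arm_high <- !is.na(t_n) && gname == "GBM" && t_n > spec$prognostic_threshold
      os <- os_ev <- NA
      if (gname %in% c("GBM", "diffuse-astrocytoma", "oligodendroglioma",
                       "metastasis")) {
        med <- if (gname == "GBM") {
          if (arm_high) spec$os_median_high else spec$os_median_low
        } else 24
        tt <- stats::rweibull(1, spec$weibull_shape,
                              weibull_scale_for_median(med, spec$weibull_shape))
        cc <- if (stats::runif(1) < spec$censoring_rate)
          stats::runif(1, 0, spec$censoring_horizon) else Inf
        cc <- min(cc, spec$censoring_horizon)
        os <- min(tt, cc); os_ev <- tt <= cc
      }
      rows[[k]] <- data.frame(
        sample_id = id, patient_id = paste0("P_", id),
        diagnosis_group = gname,
        age = round(min(max(stats::rnorm(1, g$age_mean, 12), 18), 88)),
        sex = if (stats::runif(1) < g$pct_male) "M" else "F",
        kps = sample(c(60, 70, 80, 90, 100), 1,
                     prob = c(0.05, 0.1, 0.2, 0.45, 0.2)),
        dexamethasone_use = stats::runif(1) < g$dexa_p,
        dexamethasone_dose = if (stats::runif(1) < g$dexa_p)
          sample(c(2, 4, 6, 8), 1) else 0,
        diameter1 = diam[1], diameter2 = diam[2], diameter3 = diam[3],
        wbc_count = stats::rlnorm(1, log(7000), 0.3),
        plasma_gfap = stats::rlnorm(1, log(0.05), 1.2),
        os_months = os, os_event = os_ev,
        sampling_timing = sample(c("pre-operative", "per-operative"), 1,
                                 prob = c(0.7, 0.3)),
        stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        sample_id = id, diagnosis_group = gname,
        true_pct_gfap_cd16 = t_c, true_pct_gfap_nonclassical = t_n,
        prognostic_arm_high = arm_high, stringsAsFactors = FALSE)
    }
  }
  cohort <- cohort_table(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  ev <- NULL
  if (events) {
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
    ev <- vector("list", nrow(cohort))
    names(ev) <- cohort$sample_id
    for (i in seq_len(nrow(cohort))) {
      fr <- subset_fractions_for_targets(truth$true_pct_gfap_cd16[i],
                                         truth$true_pct_gfap_nonclassical[i])
      sspec <- sample_spec(cohort$sample_id[i], n_events = spec$n_events,
                           populations = default_populations(
                             gfap_fracs = fr, plp1_fracs = 0.25 * fr),
                           seed = seeds[i])
      tbl <- simulate_sample(sspec)
      if (is.null(out_dir)) {
        ev[[i]] <- tbl
      } else {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        path <- file.path(out_dir, paste0(cohort$sample_id[i], ".", format))
        write_event_table(tbl, path, format = format)
        ev[[i]] <- path
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_metadata(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(cohort = cohort, truth = truth, events = ev)
}

#' Default acute-ischaemic-stroke profiles
#'
#' Nine patients mirroring the stroke arm of the study design: infarct
#' volumes spanning lacunar (0 cm3) to large territorial (>200 cm3)
#' infarcts. Large infarcts (>=100 cm3) peak at 2% GFAP+CD16+ monocytes
#' around 4 h with a 12 h decay half-life; small infarcts stay near the
#' 0.3% baseline region; two borderline patients produce a single marginal
#' excursion just above the detection cutoff.
#'
#' @return data.frame of per-patient profile parameters.
#' @export
default_ais_profiles <- function() {
  data.frame(
    patient_id = c("AIS001", "AIS002", "AIS004", "AIS005", "AIS007",
                   "AIS008", "AIS010", "AIS013", "AIS014"),
    infarct_volume = c(16.7, 25.2, 0.1, 191.2, 0, 96.1, 33.2, 219.1, 120),
    peak_pct = c(0.7, 0.3, 0.25, 2.0, 0.25, 0.7, 0.3, 2.2, 1.9),
    peak_h = c(4, 4, 4, 4, 4, 4, 4, 4, 4),
    half_life_h = c(2, 12, 12, 12, 12, 2, 12, 12, 12),
    baseline_pct = 0.1,
    stringsAsFactors = FALSE)
}

ais_curve <- function(t, peak, peak_h, half_life, baseline) {
  r <- ifelse(t <= peak_h, t / peak_h, 2^(-(t - peak_h) / half_life))
  baseline + (peak - baseline) * r
}

#' Simulate acute-stroke marker time courses
#'
#' The noiseless curve rises linearly to its peak and decays exponentially
#' with the given half-life; measurement noise is multiplicative
#' lognormal.
#'
#' @param profiles data.frame as [default_ais_profiles()].
#' @param sampling_times hours since onset, strictly increasing.
#' @param noise_sdlog lognormal measurement noise (0 = noiseless).
#' @param seed integer seed.
#' @return data.frame: `patient_id`, `hours_since_onset`, `pct_gfap_cd16`
#'   (noisy), `true_pct` (noiseless), `infarct_volume`.
#' @export
simulate_ais_timecourse <- function(profiles = default_ais_profiles(),
                                    sampling_times = c(2, 4, 6, 8, 12, 24,
                                                       48, 72, 96),
                                    noise_sdlog = 0.12, seed = 1L) {
  if (any(diff(sampling_times) <= 0))
    stop("spec error: sampling times must be strictly increasing")
  set.seed(seed)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    tr <- ais_curve(sampling_times, p$peak_pct, p$peak_h, p$half_life_h,
                    p$baseline_pct)
    data.frame(patient_id = p$patient_id,
               hours_since_onset = sampling_times,
               pct_gfap_cd16 = tr * stats::rlnorm(length(tr), 0, noise_sdlog),
               true_pct = tr, infarct_volume = p$infarct_volume,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
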