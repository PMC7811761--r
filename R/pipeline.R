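#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow: simulation scale,
#' gating coordinates, positivity quantile, diagnostic split settings,
#' survival-scan settings and stroke-classification settings. The master
#' seed drives all randomness and is recorded in every output.
#'
#' @param out_dir output directory for report files.
#' @param seed master integer seed.
#' @param n_events events per simulated sample.
#' @param format event-file format, `"csv"` or `"fcs"`.
#' @param gate gate coordinates, a [gate_config()].
#' @param positivity_quantile lymphocyte-background quantile.
#' @param train_fraction diagnostic training fraction of lesion patients.
#' @param prognostic_marker cohort column scanned for the survival cutoff.
#' @param survival_covariates adjustment covariates for the selected
#'   cutoff.
#' @param min_arm_fraction minimum arm size fraction in the survival scan.
#' @param survival_grid cutoff grid for the survival scan (NULL = unique
#'   observed values).
#' @param survival_force run the cutoff scan even when the continuous
#'   Cox screen is not significant.
#' @param ais_cutoff,ais_window_hours,ais_min_points stroke settings.
#' @param cohort_spec a `cohort_spec` (default [default_cohort_spec()]
#'   at `n_events`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("timascan_"), seed = 1L,
                            n_events = 30000, format = "csv",
                            gate = gate_config(),
                            positivity_quantile = 0.995,
                            train_fraction = 0.33,
                            prognostic_marker = "pct_gfap_nonclassical_adj",
                            survival_covariates = c("sex_male", "age", "kps",
                                                    "tumour_size"),
                            min_arm_fraction = 0.10,
                            survival_grid = seq(10, 30, 5),
                            survival_force = FALSE,
                            ais_cutoff = 0.6, ais_window_hours = 8,
                            ais_min_points = 2,
                            cohort_spec = NULL) {
  if (is.null(cohort_spec)) cohort_spec <- default_cohort_spec(n_events)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_events = n_events, format = format, gate = gate,
              positivity_quantile = positivity_quantile,
              train_fraction = train_fraction,
              prognostic_marker = prognostic_marker,
              survival_covariates = survival_covariates,
              min_arm_fraction = min_arm_fraction,
              survival_grid = survival_grid,
              survival_force = survival_force,
              ais_cutoff = ais_cutoff, ais_window_hours = ais_window_hours,
              ais_min_points = ais_min_points, cohort_spec = cohort_spec)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Only scalar settings can be overridden from file; anything not present
#' keeps its [pipeline_config()] default.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

write_report_csv <- function(df, path, config) {
  df$seed <- config$seed
  df$config_hash <- config_hash(config)
  df$positivity_quantile <- config$positivity_quantile
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the end-to-end workflow
#'
#' Commands: `simulate` (synthetic cohort + stroke series to disk),
#' `gate`/`quantify` (per-sample gating and profiling -> profiles.csv),
#' `stats` (group comparisons and correlations), `diagnose` (train/
#' validation split, ROC, cutoff, validation report), `survival`
#' (continuous screen + median-difference cutoff scan in the
#' glioblastoma group), `ais` (time-course classification), or `all`.
#' Every report row carries seed, config hash and positivity quantile;
#' a `manifest.json` records the run. Outputs are a pure function of
#' (config, seed): re-running a command overwrites byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param command one of simulate, gate, quantify, stats, diagnose,
#'   survival, ais, all.
#' @return Invisibly, a list of the in-memory results of the commands
#'   run.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         command = c("all", "simulate", "gate", "quantify",
                                     "stats", "diagnose", "survival",
                                     "ais")) {
  command <- match.arg(command)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  steps <- if (command == "all")
    c("simulate", "quantify", "stats", "diagnose", "survival", "ais")
  else if (command == "gate") "quantify" else command
  res <- list()

  if ("simulate" %in% steps) {
    sim <- simulate_cohort(config$cohort_spec,
                           out_dir = file.path(out, "events"),
                           seed = config$seed, format = config$format)
    ais <- simulate_ais_timecourse(seed = config$seed + 1L)
    utils::write.csv(ais, file.path(out, "ais_timecourse.csv"),
                     row.names = FALSE)
    res$simulate <- sim
  }

  if ("quantify" %in% steps) {
    cohort_path <- file.path(out, "events", "cohort.csv")
    if (!file.exists(cohort_path))
      stop("missing input: ", cohort_path, " (run 'simulate' first)")
    cohort <- read_cohort_metadata(cohort_path)
    tree <- default_timascan_tree(config$gate)
    profs <- lapply(cohort$sample_id, function(id) {
      path <- file.path(out, "events", paste0(id, ".", config$format))
      tbl <- read_event_table(path, format = config$format)
      wbc <- cohort$wbc_count[cohort$sample_id == id]
      p <- profile_sample(tbl, tree, quantile = config$positivity_quantile,
                          wbc_count = wbc)
      p$qc_flags <- paste(attr(p, "flags"), collapse = "; ")
      p
    })
    profiles <- do.call(rbind, profs)
    write_report_csv(profiles, file.path(out, "profiles.csv"), config)
    res$profiles <- profiles
  }

  needs_merged <- intersect(c("stats", "diagnose", "survival"), steps)
  if (length(needs_merged)) {
    cohort_path <- file.path(out, "events", "cohort.csv")
    if (!file.exists(cohort_path))
      stop("missing input: ", cohort_path, " (run 'simulate' first)")
    cohort <- read_cohort_metadata(cohort_path)
    prof_path <- file.path(out, "profiles.csv")
    if (!file.exists(prof_path))
      stop("missing input: ", prof_path, " (run 'quantify' first)")
    profiles <- utils::read.csv(prof_path, stringsAsFactors = FALSE)
    merged <- merge(as.data.frame(cohort),
                    profiles[, setdiff(names(profiles),
                                       c("seed", "config_hash",
                                         "positivity_quantile"))],
                    by = "sample_id")
    merged$sex_male <- as.numeric(merged$sex == "M")
  }

  if ("stats" %in% steps) {
    cmp <- compare_groups(merged, "pct_gfap_cd16", "diagnosis_group",
                          method = "kruskal_wallis")
    write_report_csv(cmp, file.path(out, "group_comparisons.csv"), config)
    cors <- list()
    for (g in c("GBM", "metastasis")) {
      sub <- merged[merged$diagnosis_group == g, ]
      if (sum(stats::complete.cases(sub[, c("tumour_size",
                                            "pct_gfap_cd16")])) >= 3) {
        ct <- correlate(sub, "tumour_size", "pct_gfap_cd16")
        cors[[g]] <- data.frame(group = g, x = ct$x, y = ct$y,
                                method = ct$method, r = ct$r, p = ct$p,
                                n = ct$n)
      }
    }
    if (length(cors))
      write_report_csv(do.call(rbind, cors),
                       file.path(out, "correlations.csv"), config)
    res$stats <- cmp
  }

  if ("diagnose" %in% steps) {
    split <- split_train_validation(merged, config$train_fraction,
                                    seed = config$seed)
    # the healthy controls are the only lesion-negative class, so they
    # serve as negatives for the training ROC as well as for validation
    healthy <- merged[merged$diagnosis_group == "healthy", ]
    tr <- rbind(merged[merged$sample_id %in% split$train, ], healthy)
    va <- merged[merged$sample_id %in% split$validation, ]
    roc_tr <- roc_curve(tr$pct_gfap_cd16, tr$diagnosis_group %in% lesion_groups())
    cut <- closest_sens_spec_cutoff(roc_tr)
    roc_va <- roc_curve(va$pct_gfap_cd16, va$diagnosis_group %in% lesion_groups())
    val <- evaluate_cutoff(va$pct_gfap_cd16,
                           va$diagnosis_group %in% lesion_groups(),
                           cut$cutoff)
    diag <- list(seed = config$seed, config_hash = config_hash(config),
                 positivity_quantile = config$positivity_quantile,
                 n_train = nrow(tr), n_validation = nrow(va),
                 training_auc = roc_tr$auc, validation_auc = roc_va$auc,
                 cutoff_pct = cut$cutoff, criterion = cut$criterion,
                 tie_break = cut$tie_break,
                 training_sensitivity = cut$sensitivity,
                 training_specificity = cut$specificity,
                 validation_sensitivity = val$sensitivity,
                 validation_sensitivity_ci = val$sensitivity_ci,
                 validation_specificity = val$specificity,
                 validation_specificity_ci = val$specificity_ci,
                 ci_method = val$ci_method,
                 chi_square = val$chi_square, df = val$df, p = val$p,
                 cross_tab = as.list(as.data.frame(val$table)),
                 positive_call = val$positive_call)
    jsonlite::write_json(diag, file.path(out, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report_csv(data.frame(threshold = roc_tr$thresholds,
                                sensitivity = roc_tr$sensitivity,
                                specificity = roc_tr$specificity),
                     file.path(out, "roc_training.csv"), config)
    res$diagnostics <- list(split = split, roc_train = roc_tr,
                            roc_validation = roc_va, cutoff = cut,
                            validation = val)
  }

  if ("survival" %in% steps) {
    gbm <- merged[merged$diagnosis_group == "GBM", ]
    sc <- max_median_diff_cutoff(gbm, config$prognostic_marker,
                                 covariates = config$survival_covariates,
                                 grid = config$survival_grid,
                                 min_arm_fraction = config$min_arm_fraction,
                                 force = config$survival_force)
    if (inherits(sc, "survival_cutoff")) {
      write_report_csv(sc$scan, file.path(out, "survival_scan.csv"), config)
      surv <- list(seed = config$seed, config_hash = config_hash(config),
                   marker = sc$marker, cutoff_pct = sc$cutoff,
                   n_low = sc$n_low, n_high = sc$n_high,
                   median_os_low = sc$median_low,
                   median_os_high = sc$median_high,
                   logrank_chi_square = sc$logrank_chi_square,
                   logrank_df = sc$logrank_df, logrank_p = sc$logrank_p,
                   screen_p = sc$screen_p,
                   adjusted_hr = unname(sc$adjusted_cox$hazard_ratios[1]),
                   adjusted_model_chi_square = sc$adjusted_cox$model_chi_square,
                   adjusted_model_df = sc$adjusted_cox$df,
                   adjusted_p = unname(sc$adjusted_cox$p_values[1]),
                   multiple_testing_warning = sc$multiple_testing_warning)
    } else {
      surv <- list(seed = config$seed, marker = sc$marker,
                   screen_p = sc$screen_p, scanned = FALSE,
                   reason = sc$reason)
    }
    jsonlite::write_json(surv, file.path(out, "survival.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$survival <- sc
  }

  if ("ais" %in% steps) {
    ais_path <- file.path(out, "ais_timecourse.csv")
    if (!file.exists(ais_path))
      stop("missing input: ", ais_path, " (run 'simulate' first)")
    series <- utils::read.csv(ais_path, stringsAsFactors = FALSE)
    calls <- classify_ais_cohort(series, cutoff = config$ais_cutoff,
                                 window_hours = config$ais_window_hours,
                                 min_points = config$ais_min_points)
    write_report_csv(calls, file.path(out, "ais_calls.csv"), config)
    res$ais <- calls
  }

  manifest <- list(package_version = as.character(
    utils::packageVersion("timascan")),
    seed = config$seed, config_hash = config_hash(config),
    command = command,
    gate_tree_hash = gate_tree_hash(default_timascan_tree(config$gate)),
    positivity_quantile = config$positivity_quantile)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
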