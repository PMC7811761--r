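#' Recognized diagnosis groups
#' @export
diagnosis_groups <- function() {
  c("WHO-I", "diffuse-astrocytoma", "oligodendroglioma", "GBM", "metastasis",
    "other-tumour", "healthy", "AIS")
}

#' Groups counted as carrying a brain lesion for diagnostic evaluation
#' @export
lesion_groups <- function() {
  setdiff(diagnosis_groups(), c("healthy", "AIS"))
}

cohort_columns <- list(
  sample_id = "character", patient_id = "character",
  diagnosis_group = "character", age = "numeric", sex = "character",
  kps = "numeric", dexamethasone_use = "logical",
  dexamethasone_dose = "numeric",
  diameter1 = "numeric", diameter2 = "numeric", diameter3 = "numeric",
  tumour_size = "numeric", wbc_count = "numeric", plasma_gfap = "numeric",
  os_months = "numeric", os_event = "logical",
  pfs_months = "numeric", pfs_event = "logical",
  hours_since_onset = "numeric", infarct_volume = "numeric",
  sampling_timing = "character")

#' Construct and validate a per-sample clinical metadata table
#'
#' One row per sample: diagnosis group, demographics, Karnofsky
#' performance score (KPS), dexamethasone use, tumour diameters (cm),
#' leukocyte count (cells/ul), plasma GFAP (ug/l), survival follow-up,
#' and — for stroke samples — hours since onset and infarct volume (cm3).
#' `tumour_size` is derived as the arithmetic mean of the three broadest
#' tumour diameters when present.
#'
#' @param df data.frame; columns beyond the documented dictionary are kept.
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("sample_id", "diagnosis_group") %in% names(df)))
    stop("cohort metadata needs at least sample_id and diagnosis_group")
  if (anyDuplicated(df$sample_id))
    stop("validation error: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!"patient_id" %in% names(df)) df$patient_id <- df$sample_id
  for (nm in intersect(names(cohort_columns), names(df))) {
    df[[nm]] <- switch(cohort_columns[[nm]],
                       character = as.character(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = parse_bool(df[[nm]]))
  }
  bad <- setdiff(unique(df$diagnosis_group), diagnosis_groups())
  if (length(bad))
    stop("validation error: unknown diagnosis group(s): ",
         paste(bad, collapse = ", "))
  dias <- c("diameter1", "diameter2", "diameter3")
  if (all(dias %in% names(df))) {
    derived <- rowMeans(df[, dias])
    if (!"tumour_size" %in% names(df)) df$tumour_size <- NA_real_
    have <- !is.na(derived)
    df$tumour_size[have] <- derived[have]
  }
  for (tm in c("os_months", "pfs_months"))
    if (tm %in% names(df) && any(df[[tm]] < 0, na.rm = TRUE))
      stop("validation error: negative survival time in ", tm)
  class(df) <- c("cohort_table", "data.frame")
  df
}

parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

#' Read cohort metadata from CSV
#'
#' @param path CSV file with the documented column dictionary (see
#'   [cohort_table()]).
#' @return A validated `cohort_table`.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort_table(utils::read.csv(path, check.names = FALSE,
                               stringsAsFactors = FALSE))
}

#' Write cohort metadata to CSV
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_cohort_metadata <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "samples,", length(unique(x$patient_id)),
      "patients\n")
  print(table(x$diagnosis_group))
  invisible(x)
}
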