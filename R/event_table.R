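#' Channels required by the default gating hierarchy
#'
#' @return Character vector of channel names that must be present in an
#'   event table before gating.
#' @export
gating_channels <- function() {
  c("FSC-A", "FSC-H", "SSC-A", "CD45", "HLA-DR", "CD300e", "CD14", "CD16",
    "GFAP")
}

#' Scale transform for fluorescence channels
#'
#' Constructs the transform applied when reading raw event data. Gating
#' operates on asinh-transformed fluorescence with a configurable cofactor;
#' scatter channels (FSC/SSC) stay linear. `no_transform()` leaves all
#' channels untouched (used for event tables already stored on the
#' transformed scale, e.g. simulator CSV output).
#'
#' @param cofactor asinh cofactor in raw fluorescence units; transformed
#'   value is `asinh(raw / cofactor)`.
#' @param channels channels to transform; `NULL` means every channel whose
#'   name does not start with FSC or SSC.
#' @return An object of class `scale_transform` with `forward` and
#'   `inverse` functions.
#' @export
asinh_transform <- function(cofactor = 150, channels = NULL) {
  stopifnot(is.numeric(cofactor), cofactor > 0)
  structure(list(type = "asinh", cofactor = cofactor, channels = channels,
                 forward = function(x) asinh(x / cofactor),
                 inverse = function(x) sinh(x) * cofactor),
            class = "scale_transform")
}

#' @rdname asinh_transform
#' @export
no_transform <- function() {
  structure(list(type = "none", cofactor = NA_real_, channels = character(),
                 forward = identity, inverse = identity),
            class = "scale_transform")
}

transform_channels <- function(channels, transform) {
  if (identical(transform$type, "none")) return(character())
  if (!is.null(transform$channels)) return(intersect(transform$channels, channels))
  channels[!grepl("^(FSC|SSC)", channels)]
}

#' Event-level cytometry table
#'
#' One sample's events-by-channels matrix of (transformed) intensities.
#' Values are assumed compensated; fluorescence is stored on the configured
#' transformed scale (asinh by default when reading raw files).
#'
#' @param values numeric matrix, events in rows, channels in columns
#'   (column names are the channel names).
#' @param sample_id sample identifier.
#' @param truth_labels optional per-event population tag (simulator only).
#' @param transform the `scale_transform` the values are stored under
#'   (provenance; defaults to `no_transform()`).
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, sample_id = "sample", truth_labels = NULL,
                        transform = no_transform()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L) stop("event table needs at least one event")
  ch <- colnames(values)
  if (is.null(ch) || anyDuplicated(ch))
    stop("channel names must be present and unique")
  if (!all(is.finite(values)))
    stop("all event intensities must be finite")
  if (!is.null(truth_labels) && length(truth_labels) != nrow(values))
    stop("truth_labels length must equal the number of events")
  structure(list(sample_id = as.character(sample_id), channels = ch,
                 values = values, truth_labels = truth_labels,
                 transform = transform),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table:", x$sample_id, "\n")
  cat("  ", nrow(x$values), "events x", length(x$channels), "channels\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  scale:", x$transform$type,
      if (!is.na(x$transform$cofactor)) sprintf("(cofactor %g)", x$transform$cofactor) else "",
      "\n")
  if (!is.null(x$truth_labels)) cat("  truth labels present\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

#' Read an event table from FCS 3.1 or CSV
#'
#' Raw values are passed through `transform` (fluorescence channels only;
#' see [asinh_transform()]). CSV event tables are comma-separated with a
#' header row of channel names and are read untransformed by default, the
#' convention used by the simulator, which stores the transformed scale
#' directly.
#'
#' @param path file path.
#' @param format `"fcs"` or `"csv"`; default guessed from the extension.
#' @param sample_id defaults to the file stem.
#' @param transform a `scale_transform`; default [no_transform()] for csv
#'   and [asinh_transform()] for fcs.
#' @return An [event_table()].
#' @export
read_event_table <- function(path, format = c("auto", "fcs", "csv"),
                             sample_id = NULL, transform = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(transform))
    transform <- if (format == "fcs") asinh_transform() else no_transform()
  values <- if (format == "fcs") read_fcs_matrix(path) else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (nrow(df) == 0L) stop("format error: csv has a header but no events: ", path)
    as.matrix(df)
  }
  tc <- transform_channels(colnames(values), transform)
  if (length(tc)) values[, tc] <- transform$forward(values[, tc])
  event_table(values, sample_id = sample_id, transform = transform)
}

#' Write an event table to FCS 3.1 or CSV
#'
#' FCS files hold raw-scale intensities: the inverse of the table's
#' stored transform is applied before writing, so a read with the same
#' transform round-trips. CSV event tables store the working
#' (transformed) scale as-is and round-trip under [no_transform()]. FCS
#' output carries channel names in $PnN keywords and stores float32
#' list-mode data.
#'
#' @param table an [event_table()].
#' @param path output path.
#' @param format `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(table, "event_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  values <- table$values
  if (format == "fcs") {
    tc <- transform_channels(colnames(values), table$transform)
    if (length(tc)) values[, tc] <- table$transform$inverse(values[, tc])
    write_fcs_matrix(values, path)
  } else {
    utils::write.csv(as.data.frame(values, check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Sample-level quality control
#'
#' Reports (never raises) named failures: too few events or missing
#' required channels. An empty flag list means the sample is usable. The
#' default event floor reflects that rare-event (<1%) fractions need a
#' denominator of at least 10^4 leukocyte events.
#'
#' @param table an [event_table()].
#' @param min_events minimum acceptable event count (default 20000).
#' @param required_channels channels that must be present
#'   (default [gating_channels()]).
#' @return A `qc_report` list with `sample_id`, `n_events`, `flags`.
#' @export
validate_sample <- function(table, min_events = 20000,
                            required_channels = gating_channels()) {
  stopifnot(inherits(table, "event_table"))
  flags <- character()
  if (nrow(table$values) < min_events)
    flags <- c(flags, sprintf("too few events (%d < %d)", nrow(table$values),
                              as.integer(min_events)))
  missing <- setdiff(required_channels, table$channels)
  if (length(missing))
    flags <- c(flags, paste("missing channel", missing))
  structure(list(sample_id = table$sample_id, n_events = nrow(table$values),
                 flags = flags, usable = length(flags) == 0L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$sample_id, "-", x$n_events, "events;",
      if (x$usable) "usable" else paste("flags:", paste(x$flags, collapse = "; ")),
      "\n")
  invisible(x)
}
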