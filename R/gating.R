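# Hierarchical gating. Gates are static 2-D regions (rectangles, convex
# polygons, or a diagonal band for the singlet gate) applied consecutively;
# interval membership is half-open [low, high), so an event exactly on a
# low bound is inside and one exactly on a high bound is outside.

#' 2-D gate constructors
#'
#' @param name gate name.
#' @param channel_x,channel_y channel names the gate cuts on.
#' @param xlim,ylim numeric length-2 bounds, half-open `[low, high)`;
#'   use `-Inf`/`Inf` for open sides.
#' @param parent parent gate name, or `"root"`.
#' @param stage gating stage number (provenance only).
#' @return A `gate2d` object.
#' @export
gate_rect <- function(name, channel_x, channel_y, xlim = c(-Inf, Inf),
                      ylim = c(-Inf, Inf), parent = "root", stage = NA) {
  structure(list(name = name, type = "rect", channel_x = channel_x,
                 channel_y = channel_y, xlim = xlim, ylim = ylim,
                 parent = parent, stage = stage), class = "gate2d")
}

#' @rdname gate_rect
#' @param x,y polygon vertex coordinates (closed implicitly).
#' @export
gate_polygon <- function(name, channel_x, channel_y, x, y, parent = "root",
                         stage = NA) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(name = name, type = "polygon", channel_x = channel_x,
                 channel_y = channel_y, px = x, py = y, parent = parent,
                 stage = stage), class = "gate2d")
}

#' @rdname gate_rect
#' @param slope,halfwidth band `|y - slope*x| <= halfwidth` (the
#'   singlet/doublet discriminator on FSC-A vs FSC-H).
#' @export
gate_band <- function(name, channel_x, channel_y, slope = 1,
                      halfwidth, parent = "root", stage = NA) {
  structure(list(name = name, type = "band", channel_x = channel_x,
                 channel_y = channel_y, slope = slope,
                 halfwidth = halfwidth, parent = parent, stage = stage),
            class = "gate2d")
}

gate_membership <- function(gate, values) {
  x <- values[, gate$channel_x]
  y <- values[, gate$channel_y]
  switch(gate$type,
    rect = x >= gate$xlim[1] & x < gate$xlim[2] &
           y >= gate$ylim[1] & y < gate$ylim[2],
    band = abs(y - gate$slope * x) <= gate$halfwidth,
    polygon = point_in_polygon(x, y, gate$px, gate$py))
}

# even-odd ray casting; boundary treatment follows the crossing count
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

TERMINAL_POPULATIONS <- c("debris_doublets_excluded", "lymphocyte",
                          "monocyte", "classical_mono", "intermediate_mono",
                          "nonclassical_mono", "dendritic")

#' Gate coordinates for the default monocyte gating hierarchy
#'
#' Defaults are co-designed with the simulator's default populations
#' (working scale: linear scatter, asinh fluorescence). Every value can be
#' overridden.
#'
#' @param singlet_slope,singlet_halfwidth FSC-H vs FSC-A singlet band.
#' @param fsc_min,ssc_min debris exclusion lower bounds.
#' @param fsc_range,ssc_range leukocyte region on FSC-A/SSC-A.
#' @param cd45_min CD45 floor for leukocytes.
#' @param lymph_ssc_max,lymph_cd45_min lymphocyte region (SSC-low,
#'   CD45-high).
#' @param hladr_split,cd300e_split HLA-DR / CD300e cuts separating
#'   lymphocytes, dendritic cells and monocytes.
#' @param cd14_split,cd16_split monocyte subset cuts.
#' @return Named list of gate coordinates.
#' @export
gate_config <- function(singlet_slope = 1, singlet_halfwidth = 35000,
                        fsc_min = 60000, ssc_min = 5000,
                        fsc_range = c(60000, 6e5), ssc_range = c(0, 4e5),
                        cd45_min = 2.5,
                        lymph_ssc_max = 65000, lymph_cd45_min = 4.0,
                        hladr_split = 2.4, cd300e_split = 2.4,
                        cd14_split = 2.6, cd16_split = 2.4) {
  as.list(environment())
}

#' Build the default consecutive gating tree
#'
#' Stages, in order: (1) singlets on FSC-A vs FSC-H; (2) debris exclusion
#' on FSC-A vs SSC-A; (3) leukocyte region on SSC-A vs FSC-A; (4) CD45+
#' leukocytes on SSC-A vs CD45; (5) lymphocytes as the SSC-low/CD45-high,
#' HLA-DR-/CD300e- branch; (6) HLA-DR+ cells split by CD300e into
#' monocytes (CD300e+) and dendritic cells (CD300e-); (7) monocyte
#' confirmation on CD300e vs CD14; (8) monocyte subsets on CD14 vs CD16:
#' classical CD14+CD16-, intermediate CD14+CD16+, non-classical
#' CD14-CD16+ (the HLA-DR+ requirement of stage 6 doubles as the HLA-DR
#' vs CD14 cross-check).
#'
#' @param config a [gate_config()] list; entries set to `NULL` raise a
#'   configuration error naming the missing gate.
#' @return A `gate_tree`.
#' @export
default_timascan_tree <- function(config = gate_config()) {
  need <- function(key, gate) {
    if (is.null(config[[key]]))
      stop("configuration error, missing gate: ", gate)
    config[[key]]
  }
  g <- list(
    gate_band("singlets", "FSC-A", "FSC-H",
              slope = need("singlet_slope", "FSC-A/FSC-H singlet band"),
              halfwidth = need("singlet_halfwidth", "FSC-A/FSC-H singlet band"),
              parent = "root", stage = 1),
    gate_rect("non_debris", "FSC-A", "SSC-A",
              xlim = c(need("fsc_min", "FSC-A/SSC-A debris"), Inf),
              ylim = c(need("ssc_min", "FSC-A/SSC-A debris"), Inf),
              parent = "singlets", stage = 2),
    gate_rect("leukocyte_region", "FSC-A", "SSC-A",
              xlim = need("fsc_range", "SSC-A/FSC-A leukocyte region"),
              ylim = need("ssc_range", "SSC-A/FSC-A leukocyte region"),
              parent = "non_debris", stage = 3),
    gate_rect("cd45_pos", "SSC-A", "CD45",
              ylim = c(need("cd45_min", "SSC-A/CD45"), Inf),
              parent = "leukocyte_region", stage = 4),
    gate_rect("lymph_region", "SSC-A", "CD45",
              xlim = c(-Inf, need("lymph_ssc_max", "lymphocyte SSC/CD45")),
              ylim = c(need("lymph_cd45_min", "lymphocyte SSC/CD45"), Inf),
              parent = "cd45_pos", stage = 5),
    gate_rect("lymphocyte", "HLA-DR", "CD300e",
              xlim = c(-Inf, need("hladr_split", "HLA-DR/CD300e")),
              ylim = c(-Inf, need("cd300e_split", "CD300e")),
              parent = "lymph_region", stage = 5),
    gate_rect("hladr_pos", "HLA-DR", "CD300e",
              xlim = c(need("hladr_split", "HLA-DR/CD300e"), Inf),
              parent = "cd45_pos", stage = 6),
    gate_rect("monocyte_gate", "HLA-DR", "CD300e",
              ylim = c(need("cd300e_split", "CD300e"), Inf),
              parent = "hladr_pos", stage = 6),
    gate_rect("dendritic", "HLA-DR", "CD300e",
              ylim = c(-Inf, need("cd300e_split", "CD300e")),
              parent = "hladr_pos", stage = 6),
    gate_rect("monocyte_confirm", "CD300e", "CD14",
              xlim = c(need("cd300e_split", "CD300e"), Inf),
              parent = "monocyte_gate", stage = 7),
    gate_rect("classical_mono", "CD14", "CD16",
              xlim = c(need("cd14_split", "CD14/CD16"), Inf),
              ylim = c(-Inf, need("cd16_split", "CD14/CD16")),
              parent = "monocyte_confirm", stage = 8),
    gate_rect("intermediate_mono", "CD14", "CD16",
              xlim = c(need("cd14_split", "CD14/CD16"), Inf),
              ylim = c(need("cd16_split", "CD14/CD16"), Inf),
              parent = "monocyte_confirm", stage = 8),
    gate_rect("nonclassical_mono", "CD14", "CD16",
              xlim = c(-Inf, need("cd14_split", "CD14/CD16")),
              ylim = c(need("cd16_split", "CD14/CD16"), Inf),
              parent = "monocyte_confirm", stage = 8))
  names(g) <- vapply(g, `[[`, character(1), "name")
  structure(list(gates = g,
                 terminals = c("lymphocyte", "dendritic", "classical_mono",
                               "intermediate_mono", "nonclassical_mono"),
                 n_stages = 8L, config = config),
            class = "gate_tree")
}

#' @export
print.gate_tree <- function(x, ...) {
  cat("Gate tree:", length(x$gates), "gates,", x$n_stages, "stages\n")
  for (g in x$gates)
    cat(sprintf("  [stage %s] %s (%s vs %s) <- %s\n", g$stage, g$name,
                g$channel_x, g$channel_y, g$parent))
  cat("terminal populations:", paste(x$terminals, collapse = ", "), "\n")
  invisible(x)
}

gate_tree_hash <- function(tree) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(tree[c("gates", "terminals")], f)
  unname(tools::md5sum(f))
}

#' Apply a gating tree to an event table
#'
#' Each event is assigned to exactly one terminal population, to
#' `debris_doublets_excluded` (failed the singlet or debris gates), or to
#' `ungated`. Assignment is a deterministic function of (table, tree);
#' intervals are half-open `[low, high)`.
#'
#' @param table an [event_table()].
#' @param tree a `gate_tree` from [default_timascan_tree()].
#' @return A `gating_result`: per-event `assignment`, per-population
#'   `counts`, derived `n_monocyte` (sum of the three subsets),
#'   `n_leukocyte` (CD45+ leukocyte denominator) and provenance.
#' @export
apply_gate_tree <- function(table, tree) {
  stopifnot(inherits(table, "event_table"), inherits(tree, "gate_tree"))
  needed <- unique(unlist(lapply(tree$gates, function(g)
    c(g$channel_x, g$channel_y))))
  missing <- setdiff(needed, table$channels)
  if (length(missing))
    stop("missing channel: ", paste(missing, collapse = ", "))
  v <- table$values
  n <- nrow(v)
  member <- list(root = rep(TRUE, n))
  for (g in tree$gates) {
    if (is.null(member[[g$parent]])) stop("gate '", g$name,
                                          "' has unknown parent ", g$parent)
    member[[g$name]] <- member[[g$parent]] & gate_membership(g, v)
  }
  assignment <- rep("ungated", n)
  assignment[!member$non_debris] <- "debris_doublets_excluded"
  for (term in tree$terminals)
    assignment[member[[term]]] <- term
  lev <- c(TERMINAL_POPULATIONS[TERMINAL_POPULATIONS != "monocyte"], "ungated")
  assignment <- factor(assignment, levels = lev)
  counts <- table(assignment)
  subsets <- c("classical_mono", "intermediate_mono", "nonclassical_mono")
  structure(list(sample_id = table$sample_id,
                 assignment = assignment,
                 counts = counts,
                 n_monocyte = sum(counts[subsets]),
                 n_leukocyte = sum(member$cd45_pos),
                 provenance = list(gate_tree_hash = gate_tree_hash(tree),
                                   transform = table$transform$type,
                                   cofactor = table$transform$cofactor)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("Gating:", x$sample_id, "-", length(x$assignment), "events\n")
  print(x$counts)
  cat("monocytes (subset sum):", x$n_monocyte,
      " CD45+ leukocytes:", x$n_leukocyte, "\n")
  invisible(x)
}

#' Marker positivity threshold from the lymphocyte background
#'
#' Marker positivity in monocytes is called against the fluorescence
#' background of the same sample's lymphocytes: the threshold is an
#' empirical quantile (type-7 interpolation) of the marker intensity among
#' gated lymphocytes.
#'
#' @param table an [event_table()].
#' @param gating the sample's `gating_result`.
#' @param marker `"GFAP"` or `"PLP1"`.
#' @param quantile background quantile (default 0.995, i.e. a 0.5%
#'   expected false-positive rate among marker-negative events).
#' @param background_population gate used as the internal negative
#'   control.
#' @param min_background_events QC floor for the background population.
#' @return A `positivity_call` carrying the threshold and its provenance.
#' @export
lymphocyte_background_threshold <- function(table, gating,
                                            marker = c("GFAP", "PLP1"),
                                            quantile = 0.995,
                                            background_population = "lymphocyte",
                                            min_background_events = 500) {
  marker <- match.arg(marker)
  stopifnot(quantile > 0, quantile < 1)
  if (!marker %in% table$channels) stop("missing channel: ", marker)
  bg_idx <- gating$assignment == background_population
  n_bg <- sum(bg_idx)
  if (n_bg < min_background_events)
    stop("QC error: only ", n_bg, " ", background_population,
         " events (need >= ", min_background_events,
         "); flag this sample rather than thresholding")
  thr <- unname(stats::quantile(table$values[bg_idx, marker],
                                probs = quantile, type = 7))
  structure(list(marker = marker, threshold = thr,
                 background_population = background_population,
                 quantile = quantile, n_background = n_bg),
            class = "positivity_call")
}

#' @export
print.positivity_call <- function(x, ...) {
  cat(sprintf("%s positivity threshold %.4f (q=%.4g of %d %s events)\n",
              x$marker, x$threshold, x$quantile, x$n_background,
              x$background_population))
  invisible(x)
}

#' Flag marker-positive events
#'
#' An event is positive iff its marker intensity is strictly greater than
#' the threshold (boundary events are negative — conservative for a
#' rare-event assay).
#'
#' @param table an [event_table()].
#' @param gating the sample's `gating_result`.
#' @param marker channel name.
#' @param threshold numeric threshold, or a `positivity_call`.
#' @param populations if given, flags outside these populations are `NA`.
#' @return Logical per-event flags.
#' @export
label_marker_positive <- function(table, gating, marker, threshold,
                                  populations = NULL) {
  if (inherits(threshold, "positivity_call")) threshold <- threshold$threshold
  stopifnot(is.finite(threshold))
  if (!marker %in% table$channels) stop("missing channel: ", marker)
  flags <- table$values[, marker] > threshold
  if (!is.null(populations))
    flags[!(gating$assignment %in% populations)] <- NA
  flags
}
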