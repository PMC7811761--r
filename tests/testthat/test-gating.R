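test_that("default tree has the documented structure", {
  tree <- default_timascan_tree()
  expect_s3_class(tree, "gate_tree")
  expect_equal(tree$n_stages, 8L)
  expect_setequal(tree$terminals,
                  c("lymphocyte", "dendritic", "classical_mono",
                    "intermediate_mono", "nonclassical_mono"))
  # overriding one bound changes only that gate
  tree2 <- default_timascan_tree(gate_config(cd16_split = 3.0))
  expect_equal(tree2$gates$classical_mono$ylim[2], 3.0)
  expect_equal(tree2$gates$singlets$halfwidth, tree$gates$singlets$halfwidth)
  # omitting a stage names the missing gate
  cfg <- gate_config(); cfg$cd300e_split <- NULL
  expect_error(default_timascan_tree(cfg), "missing gate: CD300e")
})

test_that("gating recovers simulated populations with high precision/recall", {
  tbl <- small_sample(n_events = 50000, seed = 17)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  for (pop in c("lymphocyte", "classical_mono", "intermediate_mono",
                "nonclassical_mono", "dendritic")) {
    pred <- g$assignment == pop
    truth <- tbl$truth_labels == pop
    expect_gt(sum(pred & truth) / sum(truth), 0.98, label = paste("recall", pop))
    expect_gt(sum(pred & truth) / sum(pred), 0.98, label = paste("precision", pop))
  }
})

test_that("terminal assignments partition the events", {
  tbl <- small_sample(n_events = 20000, seed = 23)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  expect_equal(sum(g$counts), nrow(tbl$values))
  subsets <- c("classical_mono", "intermediate_mono", "nonclassical_mono")
  expect_equal(g$n_monocyte, sum(g$counts[subsets]))
})

test_that("gate intervals are half-open [low, high)", {
  tree <- default_timascan_tree()
  cfg <- tree$config
  ch <- c(gating_channels(), "PLP1")
  mk <- function(cd14, cd16) {
    v <- matrix(0, 1, length(ch), dimnames = list(NULL, ch))
    v[, "FSC-A"] <- 180000; v[, "FSC-H"] <- 180000; v[, "SSC-A"] <- 90000
    v[, "CD45"] <- 4.5; v[, "HLA-DR"] <- 4.0; v[, "CD300e"] <- 4.0
    v[, "CD14"] <- cd14; v[, "CD16"] <- cd16
    event_table(v, "probe")
  }
  # exactly on the CD14 low bound of the classical gate -> inside
  on_low <- apply_gate_tree(mk(cfg$cd14_split, cfg$cd16_split - 1), tree)
  expect_equal(as.character(on_low$assignment), "classical_mono")
  # exactly on the CD16 high bound of the classical gate -> outside (falls
  # into the intermediate gate, whose low bound it sits on)
  on_high <- apply_gate_tree(mk(cfg$cd14_split, cfg$cd16_split), tree)
  expect_equal(as.character(on_high$assignment), "intermediate_mono")
})

test_that("an empty region gate drains its branch and nothing else", {
  tbl <- small_sample(n_events = 10000, seed = 29)
  cfg <- gate_config(cd16_split = 1e9)  # no event reaches CD16+ gates
  g <- apply_gate_tree(tbl, default_timascan_tree(cfg))
  expect_equal(unname(g$counts[["intermediate_mono"]]), 0L)
  expect_equal(unname(g$counts[["nonclassical_mono"]]), 0L)
  g0 <- apply_gate_tree(tbl, default_timascan_tree())
  expect_equal(g$counts[["lymphocyte"]], g0$counts[["lymphocyte"]])
})

test_that("missing channels are reported by name", {
  tbl <- small_sample(n_events = 2000)
  keep <- setdiff(tbl$channels, "CD300e")
  crippled <- event_table(tbl$values[, keep], "x")
  expect_error(apply_gate_tree(crippled, default_timascan_tree()),
               "missing channel: CD300e")
})

test_that("gating is invariant under a common positive rescaling", {
  tbl <- small_sample(n_events = 10000, seed = 37)
  s <- 2.5
  scaled <- event_table(tbl$values * s, "scaled")
  cfg <- gate_config()
  scaled_cfg <- gate_config(
    singlet_halfwidth = cfg$singlet_halfwidth * s,
    fsc_min = cfg$fsc_min * s, ssc_min = cfg$ssc_min * s,
    fsc_range = cfg$fsc_range * s, ssc_range = cfg$ssc_range * s,
    cd45_min = cfg$cd45_min * s, lymph_ssc_max = cfg$lymph_ssc_max * s,
    lymph_cd45_min = cfg$lymph_cd45_min * s,
    hladr_split = cfg$hladr_split * s, cd300e_split = cfg$cd300e_split * s,
    cd14_split = cfg$cd14_split * s, cd16_split = cfg$cd16_split * s)
  a <- apply_gate_tree(tbl, default_timascan_tree())
  b <- apply_gate_tree(scaled, default_timascan_tree(scaled_cfg))
  expect_identical(as.character(a$assignment), as.character(b$assignment))
})

test_that("background threshold is the type-7 quantile of lymphocyte marker", {
  tbl <- small_sample(n_events = 20000, seed = 41)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  # constant background -> threshold equals the constant
  const <- tbl
  const$values[, "GFAP"] <- 7.7
  thr <- lymphocyte_background_threshold(const, g, "GFAP")
  expect_equal(thr$threshold, 7.7)
  # values 1..1000 -> closed-form type-7 order statistic at q = 0.995:
  # h = (n-1)q + 1 = 995.005
  n_l <- sum(g$assignment == "lymphocyte")
  ramp <- tbl
  ramp$values[g$assignment == "lymphocyte", "GFAP"] <- seq_len(n_l)
  thr2 <- lymphocyte_background_threshold(ramp, g, "GFAP", quantile = 0.995)
  expect_equal(thr2$threshold, (n_l - 1) * 0.995 + 1, tolerance = 1e-12)

  small <- small_sample(n_events = 300, seed = 43)
  gs <- apply_gate_tree(small, default_timascan_tree())
  expect_error(lymphocyte_background_threshold(small, gs, "GFAP"),
               "QC error")
})

test_that("positivity is strict and monotone in the quantile", {
  tbl <- small_sample(n_events = 20000,
                      gfap_fracs = c(intermediate_mono = 0.02,
                                     nonclassical_mono = 0.02), seed = 47)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  v <- tbl$values[, "GFAP"]
  expect_equal(sum(label_marker_positive(tbl, g, "GFAP", max(v))), 0L)
  # an event exactly at the threshold is negative
  expect_equal(sum(label_marker_positive(tbl, g, "GFAP", v[5]) &
                     seq_along(v) == 5), 0L)
  counts <- sapply(c(0.90, 0.95, 0.99, 0.995, 0.999), function(q) {
    thr <- lymphocyte_background_threshold(tbl, g, "GFAP", quantile = q)
    sum(label_marker_positive(tbl, g, "GFAP", thr))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("measured positive fraction equals truth plus background rate", {
  q <- 0.995
  tbl <- small_sample(n_events = 100000,
                      gfap_fracs = c(intermediate_mono = 0.02,
                                     nonclassical_mono = 0.02), seed = 53)
  g <- apply_gate_tree(tbl, default_timascan_tree())
  thr <- lymphocyte_background_threshold(tbl, g, "GFAP", quantile = q)
  flags <- label_marker_positive(tbl, g, "GFAP", thr)
  cd16 <- g$assignment %in% c("intermediate_mono", "nonclassical_mono")
  measured <- mean(flags[cd16])
  expected <- 0.02 + (1 - 0.02) * (1 - q)
  se <- sqrt(expected * (1 - expected) / sum(cd16))
  expect_lt(abs(measured - expected), 3 * se + 0.0015)
})
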