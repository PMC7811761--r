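---
title: "Methods: quantifying GFAP-carrying blood monocytes and deriving clinical cutoffs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GFAP-carrying blood monocytes and deriving clinical cutoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timascan)
```

## The assay and the statistical problem

Blood monocytes phagocytose debris in damaged tissue; a fraction of the
resulting tissue macrophages re-enters the circulation still carrying
tissue-specific proteins. Glial fibrillary acidic protein (GFAP) is
essentially restricted to astrocytes and gliomas, so GFAP detected
*inside* circulating CD16+ monocytes (the intermediate CD14+CD16+ and
non-classical CD14−CD16+ subsets) is a minimally invasive signal of brain
tissue damage. `timascan` implements the full analysis chain for this
assay:

1. **Gating** — a fixed, consecutive gating hierarchy assigns each
   cytometry event to a leukocyte population.
2. **Positivity** — GFAP (and PLP1) positivity is called per sample
   against the fluorescence background of that sample's own lymphocytes.
3. **Quantification** — per-sample fractions (`% GFAP+ of CD16+
   monocytes`, `% GFAP+ of non-classical monocytes`) and absolute counts.
4. **Diagnostics** — a detection cutoff on the pooled CD16+ fraction,
   derived on a training split by the closest sensitivity–specificity
   criterion and validated on held-out samples (2×2 table, Wilson CIs,
   Pearson chi-square).
5. **Prognosis** — dichotomization of glioblastoma survival at the
   non-classical fraction maximizing the between-arm difference in
   Kaplan–Meier median survival, screened by a continuous Cox model.
6. **Stroke monitoring** — classification of acute-ischaemic-stroke
   patients as large-infarct (≥100 cm³) when the fraction exceeds the
   detection cutoff at multiple time points within 8 h of onset.

Because no event-level clinical data are publicly deposited, every
quantitative claim the package tests is made on synthetic cohorts with
known ground truth, generated by the package's own simulator.

## Scale and transform

Gating operates on a working scale: scatter channels (FSC/SSC) linear,
fluorescence asinh-transformed with cofactor 150
(`asinh_transform()`). The cofactor is conventional for
photomultiplier-based cytometers; the source study does not state its
display transform, so the transform type and cofactor are recorded in
every `gating_result`'s provenance. Gating outcomes are invariant under a
common positive rescaling of data and gate coordinates (a property the
test suite asserts), so the particular monotone display scale is not
load-bearing; only the gate coordinates expressed on it are.

FCS 3.1 files store raw intensities and are transformed at read time; CSV
event tables store the working scale directly (the simulator's native
output). Events are assumed compensated — spillover handling is
instrument-specific and out of scope.

## The gating hierarchy

`default_timascan_tree()` builds eight consecutive stages: singlets
(FSC-A vs FSC-H band, |FSC-H − a·FSC-A| ≤ b), debris exclusion (FSC-A,
SSC-A floors), a permissive leukocyte region, CD45+ leukocytes,
lymphocytes (SSC-low/CD45-high, HLA-DR−CD300e−), the HLA-DR+ split into
monocytes (CD300e+) versus dendritic cells (CD300e−), a CD300e vs CD14
confirmation, and the CD14/CD16 subset split. Intervals are half-open
`[low, high)`: an event exactly on a low bound is inside, on a high bound
outside — so the three monocyte subset gates tile the CD14×CD16 plane
without overlap or gaps.

Gates are static and config-defined rather than data-driven: the source
workflow gates manually in a commercial tool, and fixed gates make every
downstream number a deterministic function of (data, configuration). The
default coordinates are co-designed with the simulator's default
populations, which are separated by ≥4 SD on every channel a gate cuts
on; on such data gating recovers every population with precision and
recall above 0.98 (asserted at 100,000 events).

## Positivity against the internal lymphocyte background

Monocyte GFAP positivity is called against the *same sample's*
lymphocytes: the threshold is the type-7 empirical quantile (default
0.995) of lymphocyte GFAP intensity, and an event is positive only if
*strictly above* it. Lymphocytes are a valid internal negative control
because marker-negative events of all populations share one background
distribution — an assumption the simulator implements literally and real
instruments approximate after compensation.

Two consequences are worth stating precisely:

* The raw measured positive fraction estimates `p + (1 − p)(1 − q)`, not
  `p`: a 0.5-point background false-positive rate at the default
  q = 0.995. Reported percentages are deliberately *not*
  background-subtracted (matching the assay's reporting convention), but
  `monocyte_profile()` also returns `*_adj` columns with the inversion
  `p̂ = (measured − (1 − q)) / q`, which is what truth-recovery checks
  and the prognostic marker use. For fractions near 0.2% the adjustment
  is the difference between a usable and a severely biased estimator.
* The sampling noise of the adjusted estimator is binomial at the *raw*
  call rate rescaled by 1/q (plus a small contribution from estimating
  the threshold itself). Recovery tests therefore use
  `SE = sqrt(p_raw(1 − p_raw)/n)/q` as the yardstick.

Raising the quantile trades background bias against variance; the
monotonicity of the positive count in the quantile is asserted as a
property test.

## The synthetic cohort generator

`simulate_sample()` draws multinomial population counts and per-population
Gaussian channel values (diagonal covariance) on the working scale;
FSC-H is generated as a noisy multiple of the event's own FSC-A so that
the singlet band is meaningful, and doublets sit at twice the singlet
FSC-A with singlet-level FSC-H. A Bernoulli subset of each monocyte
population receives an additive GFAP shift of 2.5 (≈7 background SDs — a
cleanly resolved positive population, as in the assay's dot plots).

`simulate_cohort()` mirrors the cross-sectional study design: 145
glioblastoma, 28 diffuse astrocytoma, 32 oligodendroglioma, 2 WHO-I, 21
metastasis and 38 healthy-control samples. Per sample, the true pooled
CD16+ positive fraction is lognormal per diagnosis group (healthy median
0.25%, glioma/metastasis medians 1.0–1.3%, chosen so the group ordering
and a ~0.9 truth-level AUC match the published violin/ROC figures
qualitatively — configuration, not a claim about the original data), and
the non-classical-only fraction is a correlated lognormal multiple of it.
Tumour size couples weakly to the fraction on the log scale
(Spearman r ≈ 0.1–0.2 in glioblastoma, the published correlation scale).

Two targets, one event model: the pooled and non-classical-only fractions
cannot always be realized simultaneously (the implied intermediate-subset
fraction can go negative), so the generator clips per-subset fractions
into [0, 1] and records the **realized** values as ground truth. To keep
the pooled fraction on the sub-percent diagnostic scale while
non-classical positivity reaches the tens-of-percent prognostic scale,
non-classical monocytes are a minority (~15%) of the CD16+ pool in the
default mix — consistent with a largely dexamethasone-exposed tumour
cohort, since glucocorticoids preferentially deplete non-classical
monocytes.

Survival is Weibull per prognostic arm (shape 2.5 — realistically
concentrated glioblastoma survival; scale solved so Kaplan–Meier arm
medians are 11.8 and 8.8 months for true non-classical fractions
below/above 20%). The hazard depends on the marker only through this
dichotomy, mirroring the analysis being validated. Censoring applies an
independent Uniform(0, 60 months) censoring time with probability 0.2
plus an administrative horizon — the source describes no censoring
process, so the simplest ignorable mechanism is used.

Stroke profiles rise linearly to a peak and decay exponentially: large
infarcts (≥100 cm³) peak at ~2% around 4 h with a 12 h half-life; small
infarcts stay near baseline 0.1–0.3%; two borderline patients produce a
single marginal excursion (peak 0.7%, 2 h half-life) — the qualitative
patterns reported for the nine monitored patients. Measurement noise is
multiplicative lognormal (sdlog 0.12).

What the simulator does **not** emulate: spectral spillover and
compensation error, acquisition drift, non-Gaussian population shapes,
inter-sample gate misalignment, batch effects, or informative censoring.
Passing tests therefore validate the *analysis chain* under its stated
assumptions, not the assay's clinical performance.

## Diagnostic cutoff derivation

Patients (not samples) are the unit of the 33/67 training/validation
split, stratified by diagnosis group. Healthy controls are excluded from
the training *selection* but serve as the negative class of both ROC
curves — they are the only lesion-negative samples in the design, so a
training ROC is impossible without them. The empirical ROC uses midpoint
candidate thresholds with ±∞ sentinels and calls positive at
score ≥ threshold; AUC is computed in the rank-statistic form, which
equals the trapezoidal area exactly (ties included — an identity the
suite asserts on 1,000 random instances). The cutoff minimizes
|sensitivity − specificity|, ties broken by larger sensitivity +
specificity, then by the smaller threshold; comparison keys are rounded
to 9 decimals so float noise cannot split genuine ties (sens/spec are
small-denominator rationals, so true gaps are many orders larger).
Validation reports the 2×2 table, Wilson 95% CIs (better small-sample
behaviour than Wald), and Pearson chi-square without continuity
correction.

## Prognostic cutoff by maximal median-survival difference

The continuous marker is screened by Cox regression first; the
dichotomization scan runs only if the screen is significant at 0.05
(`force = TRUE` bypasses the gate, e.g. for recovery experiments — the
dichotomy-coupled generator gives the linear screen only ~75% power at
n = 137). The scan dichotomizes at each grid value, requires both arms to
hold ≥10% of the cohort *and* have defined KM medians, and selects the
maximal |median difference| (ties → smaller cutoff). The selected cutoff
is then evaluated by log-rank and by a Cox model adjusted for sex, age,
Karnofsky score and tumour size. The scan-selected log-rank p is reported
unadjusted, as is conventional for this procedure, and the result object
always carries a `multiple_testing_warning` field because maximizing over
cutoffs makes that p anti-conservative.

Numerical conventions: the KM median is the first time with
S(t) ≤ 0.5 + 1e-9 (the tolerance keeps the exact-0.5 plateau, reachable
at even n without prior censoring, from being decided by floating-point
rounding); events precede censorings at tied times; Cox ties use the
Breslow approximation by default (Efron available). The default scan
grid is the unique observed marker values; for cohort-scale recovery
studies a coarse clinical grid (10–30% in 5-point steps) is preferable,
because the expected median-difference curve has a shallow right flank —
moving the cutoff above the true threshold shrinks an already-small arm
without changing its expected median much, so fine grids let the argmax
wander among near-ties.

## Stroke classification

`flag_timecourse()` marks strict exceedances of the cutoff (default
0.6%) and the ≤8 h decision window; `classify_infarct_size()` predicts a
large infarct when at least `min_points = 2` in-window exceedances occur
("multiple time points"), with ground truth at volume ≥ 100 cm³. Raising
the cutoff can only remove exceedances, so predictions are monotone in
the cutoff (asserted).

## Problem sizes and determinism

Default study sizes used by the test suite and the acceptance script:
100,000 events for the gating benchmark; 30,000 events per sample
elsewhere (CD16+ denominators ≈1,600, lymphocyte backgrounds ≈9,000);
266-sample cohorts for the diagnostic pipeline; n = 137 glioblastoma
cohorts for the prognostic scan; 2,000 replicates for log-rank
calibration; 200 replicates for rare-fraction recovery. Stochastic
recovery criteria (Cox log-HR, KM median, scan cutoff and arm medians)
are judged at the median of a handful of seeded replicates, since a
single draw sits within ~1 SE of the stated bands. Every random step is
seeded; the whole pipeline is a pure function of (configuration, seed),
and byte-identical reports across reruns are part of the acceptance
suite.

## Known limitations

* Gate coordinates are tied to the working scale and the simulator's
  population layout; real instruments need a recalibrated
  `gate_config()`. A data-driven valley-finding adjuster is a documented
  extension point, deliberately not implemented.
* The background-adjustment formula assumes the lymphocyte background is
  exchangeable with the monocyte background; autofluorescence differences
  between lineages would bias it.
* The max-median-difference scan is a noisy estimator of an underlying
  threshold even in the best case; its selected-cutoff p-values are
  optimistic (hence the mandatory warning field), and its arm medians are
  selection-inflated by construction.
* The FCS writer targets the package's own round-trip needs (list-mode
  float32, $PnN names); it is not a general cytometry-standard
  implementation.
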