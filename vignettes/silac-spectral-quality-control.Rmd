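---
title: "Quality control of SILAC spectra: model, tagging rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of SILAC spectra: model, tagging rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(silacqc)
```

## The quality-control model

`silacqc` scores peptide-spectrum matches (PSMs) from SILAC experiments
so that spectra with unreliable profiles can be removed before
quantification. The central assumption is that spectral *profile*
quality — not the estimated heavy:light ratio — predicts whether a
spectrum's ratio estimate can be trusted. The classifier therefore sees
exactly thirteen profile features and never the ratio itself; ratios
enter only (a) when deriving training tags on a sample whose true mix
ratio is constant, and (b) when evaluating how concentrated the
surviving ratios are.

The thirteen features and what each one assumes:

| feature | detects | assumption |
|---|---|---|
| MassDev (ppm) | mis-identification | true peptides match their theoretical mass up to a small, roughly constant instrument bias |
| PPR | co-eluting contaminant | a peak just before the mono-isotopic peak of comparable height means overlap; absence of a preceding peak is benign (PPR = 0) |
| S/N | weak signal | the median detected peak intensity in the precursor's spectrum region is a fair noise level |
| IsoDev (×6) | cluster distortion | the experimental isotopologue ladder of each cluster should match the theoretical pattern after mono-peak normalization |
| SID (×4) | unstable elution | within the extracted ion chromatogram, neighboring scans should reproduce the theoretical second-to-first peak ratio |

The theoretical isotope pattern uses a Poisson approximation to the
averagine distribution, `TP_i ∝ λ^i/i!` with `λ = c·M_t` and
`c = 4.938e-4` per Da. This is a deliberate simplification: it needs
only the peptide mass, is monotone in it, and any per-peptide pattern
computed upstream can override it through the optional `TP_0..TP_3`
input columns, which take precedence.

Two definitions were genuinely open and are fixed as follows:

* **The SID reference `M_0` is `TP_1/TP_0`**, the theoretical
  second-to-first abundance ratio. Defining `M_0` as the target scan's
  own observed ratio would make `SID_0` identically zero and hence
  useless as a feature; anchoring all four SIDs to the theoretical
  pattern makes them jointly interpretable as deviations from what the
  identified peptide should look like.
* **Scan-triplet semantics**: scan 0 is the identification scan; scans
  1 and 2 are the two retention-time-adjacent scans carrying the XIC.
  The generator and the feature code only require that scan 0's first
  and second peaks equal the cluster's `EP_0`/`EP_1`; whether the
  neighbors are the next two scans or previous+next is up to the
  upstream extractor.

## Missing-value conventions and degenerate inputs

Missingness is meaningful here, so it is encoded, not imputed:

* missing preceding peak → `PPR = 0` (no contamination evidence);
* missing scan (any unidentified peak, or a non-positive pooled first
  peak) → that scan's `SID = −1` and exclusion from the `SID_sum`
  pools; all scans missing → all four SIDs are −1. Because genuine SIDs
  of present scans can approach −1 only in the limit of a vanishing
  second peak, −1 acts as a recognizable sentinel for the trees;
* missing mono-isotopic peak of a cluster → the three IsoDev values of
  that cluster are set to the sentinel `9.99` (a deviation far beyond
  anything a real pattern produces) and the record is flagged
  low-confidence rather than dropped. A missing *light* mono peak makes
  PPR and S/N undefined as well and is treated as a hard input error;
* `asap_ratio` may be absent or `−1` in input files (−1 cannot be a
  global sentinel because it is a legal SID value); such records are
  tagged negative and excluded from tag-rule estimation;
* in tables, missing is the empty field; numeric fields are written
  with 15 significant digits so a write/read round trip is the identity
  up to float formatting.

Degenerate statistical inputs resolve conservatively: zero spread in
log2 ratios tags every valid record positive (nothing is an outlier);
zero spread in mass deviations tags everything positive with a warning;
a constant sample's KDE mode is that constant; a constant sample's
Chebyshev coverage is 1; the log-scale CV of fewer than two values is
an error, not 0.

## Tagging rules and their parameters

* `sigma_multiplier = 3` (ratio-tag): the window mean ± 3 SD on log2
  ratios keeps at least 8/9 of any distribution by Chebyshev's
  inequality, so the rule can only trim clear outliers — it narrows the
  candidate set without presuming normality.
* `mass_threshold = 0.5` (mass-tag, standardized units): the window is
  centered on the *mode* of the standardized mass deviations, not on
  zero, because mass measurement has a systematic bias; ±0.5 SD around
  the mode retains the central mass-accurate population and excludes
  the heavy tails. Both interval checks are closed (boundary values
  pass), reading "falls in the interval" inclusively.
* KDE mode: Gaussian kernel, Scott's bandwidth (`bw.nrd`) by default
  with Silverman (`bw.nrd0`) selectable, evaluated on a 512-point grid
  spanning the data range. The mode is a grid argmax, so its resolution
  is (range/511); ties resolve to the first grid point, which only
  matters for pathological flat densities.
* Standardization of mass deviations is per sample (per input table),
  matching the per-sample tagging workflow; pooling across mixes would
  let one sample's bias shift another's window.
* The final tag is the AND of the two rules: a positive training
  example must look right in both ratio and mass.

## Re-balancing and the classifier

Good spectra dominate realistic data, so the negative (low-quality)
class is the minority. `smote()` equalizes it to the majority count by
interpolating toward one of the `k = 5` nearest minority neighbors
with a uniform random factor — vector interpolation,
`x + u·(x̂ − x)`, the standard construction; interpolating a scalar
distance would leave the direction undefined. Distances are Euclidean
on raw feature values (a standardize-first option exists but is off by
default, matching common SMOTE implementations). If the minority class
has at most `k` members, `k` is reduced to minority−1 with a warning.
Original rows always pass through bit-identical, synthetics appended.

The boosted-tree classifier runs with tuned defaults
(`learning_rate = 0.197`, `n_estimators = 11`, `max_depth = 10`,
`gamma = 0.04`, `colsample_bytree = 0.97`, `subsample = 0.96`), all
constrained to the search box learning_rate (0.01–0.3), n_estimators
(10–2000), max_depth (3–10), gamma (0–0.05), colsample_bytree and
subsample (0.7–1). `tune_hyperparameters()` searches that box by
maximizing the mean AUC of stratified 10-fold cross-validation in
which **only the k−1 training folds are over-sampled** — the held-out
fold keeps the original class ratio, since evaluating on synthetic
points would reward interpolation rather than discrimination. Folding
is stratified because with ~10% negatives and 10 folds an unstratified
fold can lose the minority class entirely.

The search itself is a small in-package Gaussian-process
expected-improvement optimizer: parameters scaled to the unit cube,
squared-exponential kernel with fixed length-scale 0.2, signal variance
set to the variance of the observed scores, nugget 1e-6·variance for
numerical stability, 500 random candidates per round, ties broken
first-found; `n_estimators` and `max_depth` are rounded before every
evaluation. A pure random search over the same box is selectable
(`method = "random"`) and satisfies the same contract. The fixed
length-scale is crude but adequate for a 6-dimensional box and a
30-evaluation budget; with so few evaluations, fitting kernel
hyperparameters would mostly fit noise.

Determinism: a single master seed derives per-stage seeds (split,
folding, per-fold SMOTE, each fit, the search) via a string-hash map
kept below 2^31; boosted fits run single-threaded so repeated runs are
bit-identical. The class-weighted SVM baseline (RBF kernel, minority
weight 6 — the weight matching an approximately 6:1 imbalance) shares
the prediction contract; its probability calibration is itself
stochastic, hence also seeded.

## Evaluation

For log2-transformed ratios the usual CV = σ/μ is meaningless (μ can be
0); the package uses `CV = sqrt(2^((ln 2)σ²) − 1)`, the exact
coefficient of variation of `2^X` for normal `X`, so a CV computed from
log2 ratios is comparable with a raw-scale CV. `filter_sweep()` drops
the `⌊f·n⌋` lowest-scoring spectra for each fraction `f` — rank-based
filtering, because "fraction filtered" is the natural x-axis for
comparing controllers at equal cost; a fixed score threshold of 0.5 is
also exposed through `predict_quality()`'s `keep` column. Ties in
scores are broken by record order, making sweeps reproducible.
Protein-level summaries report mean ± SD of raw ratios per protein over
kept records (SD = 0 for singletons), where the expected benefit of
filtering is a smaller within-protein SD. Sample (n−1) SDs are used
throughout.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces the full input schema with known
ground-truth quality. It emulates: Poisson/averagine isotope ladders;
tryptic peptides terminating in the labeled K or R; log-normal
abundances (median mono intensity 1e6); a 3-scan elution profile
(relative apexes 1, 0.75, 0.5) with 8% multiplicative scan jitter; a
mass-deviation distribution with systematic bias −0.13·`ppm_sd`
(`ppm_sd = 2` ppm) for good spectra and a Student-t (3 df, scale
16 ppm) tail for corrupted ones; log-normal ratio noise (SD 0.3 log2
units good, 1.2 corrupted); and a default 15% corrupted fraction, each
corrupted spectrum drawing one corruption aimed at one feature family
(pattern distortion → IsoDev/SID, preceding-peak contaminant →
PPR ≈ 0.7–1.3, raised noise floor → S/N ≈ 1.5, ratio blow-up with
disturbed neighbor scans), plus a 15% chance of losing a neighbor scan.
These magnitudes are chosen once as clearly-corrupted-but-plausible
operating points; they are the study conditions of the package's
end-to-end tests, not tuning knobs.

It does **not** emulate: chromatographic peak shapes beyond three
scans, charge-state or retention-time effects on features,
inter-peptide intensity correlation within proteins, isotope-cluster
overlap between co-eluting peptides, or instrument-specific noise
structure. Consequently, passing end-to-end tests demonstrates that the
pipeline recovers *planted* corruption of the kinds the features are
built to detect — it bounds implementation correctness, not real-data
performance, where corruption is messier and labels are noisier.

## Problem sizes and tolerances used by the checks

The test-suite and acceptance script run at sizes chosen to keep the
whole suite fast while leaving no statistical ambiguity: unit fixtures
of 2–40 records; property loops over 50 random distributions;
Monte-Carlo validation of the CV closed form with 1e6 draws per σ
(agreement demanded within 1%); and an end-to-end study of five
generated 1:1 datasets of 3000 spectra each, demanding held-out AUC
≥ 0.90 against ground truth, CV reduction after 30% filtering and
SMOTE minority-recall parity in at least 4 of 5 seeds. One check
compares against a published reference feature table that cannot be
redistributed; it runs only where the user has converted and installed
that table (`scripts/convert_reference_xls.py`).

## Known limitations

* The Poisson isotope model degrades above ~4 kDa; supply real
  patterns via `TP_0..TP_3` where available.
* Tag noise is inherent: a corrupted spectrum can pass both tag rules
  (correct ratio by luck, small mass error), so tags are a proxy for
  quality, and classifier AUC against tags overstates AUC against
  truth.
* Gain importances are reported as normalized shares (summing to 1),
  so they compare features within a model, not across models.
* The SVM baseline's probability calibration uses internal
  cross-validation; its scores are comparable at the ranking level, not
  as calibrated probabilities.
* No correction is attempted for systematic bias of the upstream ratio
  estimator; evaluation therefore emphasizes concentration (CV), not
  closeness of the mean to the nominal mix.
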