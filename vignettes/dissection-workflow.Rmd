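---
title: "Multi-modal characterization of dissected aortic tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal characterization of dissected aortic tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortadissect)
```

## The problem

Acute type A aortic dissection splits the aortic wall into three tissue
regions — the false lumen (FL), the dissection flap (FP) and the true lumen
(TL) — whose mechanical integrity differs in ways that matter for surgical
decision-making. `aortadissect` implements, as one tested pipeline, the
analyses that characterize these regions from three kinds of data:

1. **REIMS/iKnife spectra.** Rapid evaporative ionization mass spectrometry
   records, at ~1 Hz, centroided negative-mode spectra (m/z 50–1200) of the
   aerosol produced while tissue is cauterized. Each cauterization "burn
   event" (10–30 s of elevated total ion current) becomes one observation.
2. **Stained sections.** Verhoeff–van Gieson (VVG) and Picrosirius Red (PSR)
   histology, quantified per image as percentage tissue area of collagen and
   elastin.
3. **Per-sample measurements.** Shear storage and loss moduli G′ and G″
   (kPa), collagen/elastin/glycosaminoglycan content (µg/mg), age and
   indexed aortic size.

Because no patient-level data are distributable, the package ships a
synthetic-data generator that emulates the cohort layout (10 FL, 10 FP and
6 TL samples from 10 patients, with three latent FL sub-groups) with known
ground truth, so every stage is testable end to end.

## Burn-event processing

The total ion current (TIC) of a scan is the sum of all its ion
intensities. `detect_burn_events()` takes the run baseline to be the
*median* TIC (cauterization occupies a minority of scans) and reports
maximal contiguous windows with TIC above `threshold_factor` (default 5)
times the baseline; windows shorter than 3 scans are discarded as spikes.

Real burns are ragged. `pseudo_gaussianize()` replaces each detected window
by a canonical trace defined by three properties: it is **35 scans** long,
exactly **12 scans** lie above the burn-level threshold, and the maximum
falls at **scan 18** (1-based). We realize this as a discrete Gaussian
`w_k ∝ exp(-(k - μ)² / 2σ²)` whose width σ is solved numerically so that
exactly 12 of the 35 values, scaled to the window's total TIC, exceed the
detection threshold. A symmetric Gaussian centred on an integer scan always
has an odd number of values above any threshold, so the centre sits at
μ = 17.51: the integer-scan argmax is 18 while the above-threshold block is
the even-sized run 12–23. The trace conserves TIC (its sum equals the
window total), and the same Gaussian weights, mapped linearly across the
window, average the window's scans into one consensus spectrum for binning.
For extreme windows (e.g. a single scan whose total TIC is less than 12
times the threshold) no width can satisfy the span exactly; the converter
then warns and takes the closest achievable span — length and conservation
still hold.

Scan indices are 1-based everywhere in this package, matching both the
language and the "maximum at scan 18" convention.

`lockmass_correct()` finds the most intense peak within ±0.5 Da of
554.2615 Da — the [M−H]⁻ ion of leucine-enkephalin, the standard
negative-mode reference infused alongside REIMS acquisition — and shifts
all m/z values by the single constant that puts it on the reference. The
operation is idempotent, and a missing reference peak leaves the spectrum
unchanged with a warning. `bin_spectrum()` then sums intensities into
half-open 1 Da bins over [50, 1200) (width configurable down to 0.1 Da) and
divides by the total, so each burn event becomes a unit-sum feature vector.
Neither the bin width nor TIC normalization is uniquely dictated by the
upstream instrument software; both are explicit, logged parameters.

## Histology quantification

All quantities are ratios of pixel counts, so no spatial calibration is
needed. The chain is:

* **Tissue mask.** The blue channel separates tissue from the bright blank
  slide best; the modal blue value (ties broken towards the brightest,
  since the mode is the blank slide) is the background, and pixels strictly
  below it are tissue. Connected components smaller than `min_fragment_px`
  are dropped and interior holes up to `max_hole_px` are filled. The
  morphological steps use `EBImage::bwlabel`, whose connected components
  are 4-connected.
* **Collagen index.** `R/50 − G/20 + B/30` on raw 8-bit values. Collagen
  stains pink through magenta to dark red; under these weights such hues
  score above 1.0 while non-collagen tissue scores below. The published
  index ranges (−0.75 to 1.0 non-collagen, 1.0–1.75 collagen) describe
  typical stained-tissue pixels, not analytic bounds — pure white scores
  0.85, and saturated magenta exceeds 1.75.
* **Elastin index.** Elastin stains grey-to-black, so the channels are
  equally weighted into the darkness `1 − (R+G+B)/765` on [0, 1], with the
  nominal boundary at 0.5.
* **Thresholding.** The stained fraction is the count of masked pixels
  *strictly above* the threshold over the mask size; boundary pixels count
  as unstained. The fraction is therefore exactly non-increasing in the
  threshold.
* **PSR calibration.** The collagen threshold (nominally 1.0) is calibrated
  per section so the VVG fraction matches the collagen fraction of the
  adjacent PSR section, measured as red-dominant pixels (R exceeding both G
  and B by a 30-count margin). The search grid is nominal ± 0.75 in steps
  of 0.01, ties resolved towards the nominal value. A flat index map makes
  the target unreachable; the nominal threshold is returned with a warning.
* **Errors.** Thresholds are varied by ±δ (default 0.05):
  `err_high = f(t−δ) − f(t)` and `err_low = f(t) − f(t+δ)`, both
  non-negative by monotonicity. Index histograms dense near the threshold
  yield large errors, sparse ones small errors.

## PLS-DA workflow

Exploration uses `stats::prcomp` on centred, unit-variance data
(zero-variance columns get unit scale), with a deterministic sign
convention. Classification is partial least squares discriminant analysis:
class labels are one-hot encoded, X is autoscaled, Y centred, and a PLS2
decomposition extracted by NIPALS (tolerance 1e-10, at most 500 iterations
per component). Predicted class is the argmax of the continuous class
scores. Evaluation follows the repeated-split design: 50 stratified 80/20
train/test splits; on each training half the number of components
(1–10) is chosen by stratified 2-fold cross-validation, taking the smallest
count attaining the minimal misclassification; accuracy, macro precision,
recall and F1 are averaged over the 50 test halves. Splits stratify by
tissue type at the sample level; with `pieces_per_patient > 1` the
generator can create patient-correlated duplicates for studying
patient-level leakage, but the default is one piece per patient per region.

Variable importance in projection is
`VIP_j = sqrt(p · Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`, which satisfies
`Σ_j VIP_j² = p` identically; the refined model keeps features whose VIP
mean *and* median over the 50 repeats are both strictly greater than 1.
The ROC reduces the 3-class problem to FL-versus-rest — the clinically
salient contrast, and the only reduction that yields a single curve — and
pools the held-out FL scores across the repeated splits before the
threshold sweep (trapezoid AUC, equal to the rank statistic).

## Cluster stability

Heterogeneity within the FL cohort is assessed by Ward hierarchical
clustering (`hclust`, method `ward.D2`, i.e. Ward's criterion on Euclidean
distances) of the TIC-normalized binned spectra. Uncertainty comes from
multiscale bootstrap resampling of the *feature* dimension, the scheme the
pvclust package defined: the clustered samples stay fixed, and for each
scale r in {0.5, …, 1.4} we draw 1000 resamples of `round(p·r)` feature
columns, recluster, and record per node the bootstrap probability BP(r)
that the node's exact leaf set reappears. Resampling rows instead would cap
BP for a k-leaf node at the probability that all k rows are drawn
(≈ 0.65^k at n = 10) and break the probit extrapolation; feature
resampling has no such defect, which is why the method resamples the
dimension over which distances are computed. Because a column resample
with multiplicities `cnt` turns each squared Euclidean distance into
`Σ_b cnt_b (x_ib − x_jb)²`, all replicate distance matrices are exact
linear maps of one precomputed pair-by-feature matrix — 10 scales × 1000
replicates take seconds at n = 10.

The probit-transformed recovery probabilities are fitted across scales by
weighted least squares to `z(r) = v·√r + c/√r`, separating the signed
distance v of the cluster boundary from its curvature c; the approximately
unbiased p-value is `AU = 1 − Φ(v − c)`. Only scales with informative BP
(neither 0 nor 1) constrain the fit — at least three are required; a node
recovered always (or never) carries no curvature information and its AU
falls back to the mean BP (1 or 0), flagged `fit_ok = FALSE`. Weights use
the binomial variance of BP. "Stable" clusters are the maximal disjoint
nodes with AU strictly above 0.90, chosen top-down; the root is never a
candidate, and uncovered leaves are reported as singletons.

## Non-parametric tests

Three-group comparisons use the tie-corrected Kruskal–Wallis H
(`stats::kruskal.test`; all-tied data are defined to give H = 0, p = 1)
with Dunn's post hoc z on joint mean ranks and Holm adjustment
(`stats::p.adjust`) across the three pairs within each variable. Two-group
cluster comparisons use Mann–Whitney U reported as `min(U_a, U_b)`; for
groups of at most 8 the two-sided p is exact by full enumeration of the
`choose(n_a+n_b, n_a)` assignments (ties contribute half-counts to U, so
tied data remain exact), otherwise a tie- and continuity-corrected normal
approximation is used. All tests are two-sided.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults define the study conditions: 10 FL / 10 FP /
6 TL samples from 10 patients, three latent FL sub-groups.

* **Feature table.** All variables log-normal (hence positive). G′, G″ and
  GAG have a lower location in FL — a 1.5 SD shift on the log scale at
  `class_effect = 1` — reflecting the more compliant, GAG-depleted false
  lumen; collagen and elastin carry the sub-group signature (sub-group 1
  collagen-rich/elastin-poor, 2 elastin-rich, 3 depleted in both). Age and
  indexed aortic size are patient-level. Baselines (G′ 20 kPa, G″ 5 kPa,
  collagen 200, elastin 150, GAG 30 µg/mg) are plausible aortic-media
  values chosen once as generator defaults; they are not estimates from any
  dataset.
* **Spectra.** Each class template is a shared ~30-peak backbone
  (concentrated in the lipid-rich 600–900 m/z region) plus 8 class marker
  peaks scaled by `class_effect`; FL sub-templates add 5 equal-height
  marker peaks each, scaled by `subcluster_effect`. Marker positions are
  drawn from a minimum-spacing pool and snapped to bin centres, so no two
  marker sets overlap and every marker peak has the identical discrete
  profile: the three sub-templates are exactly equidistant, and only noise
  (and Ward's size weighting of the 4/3/3 split) distinguishes one pairing
  of sub-groups from another. Peaks are narrow (σ = 0.75 Da at 1 Da bins),
  as binned centroided data are. Per-bin multiplicative log-normal noise
  (CV 0.2) precedes TIC normalization. The default `subcluster_effect = 2`
  separates sub-templates by well over the within-group spread — the
  "clearly resolved sub-groups" regime; at these settings the AU analysis
  recovers the three planted sub-groups across seeds, while weaker settings
  make the dendrogram's join nodes intermittently stable (Ward's
  size-weighted merge cost favours joining the two triplets).
* **Burn runs.** A baseline TIC of 1000 with an irregular log-normal
  plateau 50-fold higher for the burn duration; flanking baseline scans are
  kept in the majority so the median-TIC baseline estimator is valid. Scans
  carry a lipid-like profile plus a lockmass peak, optionally mis-calibrated
  by a constant to exercise correction.
* **Images.** A contiguous wobbled-ellipse tissue footprint on a
  near-white slide whose blue channel is exactly modal; within the tissue,
  pixel-exact counts are painted in collagen hues (index > 1, brightness
  above the elastin cut), grey-to-black elastin hues, and a van
  Gieson-like counterstain, with per-pixel colour noise bounded away from
  every index threshold. PSR companions share the footprint with collagen
  in saturated red at the VVG fraction ± a small section-adjacency jitter.

What the generator does **not** emulate: chemically annotated lipid peaks
or isotope patterns, instrument drift, staining variability that crosses
the index thresholds, spatially correlated histology textures, or
patient-level confounding between modalities. Passing tests therefore
demonstrate that the pipeline's algorithms recover known structure under
the stated noise model — not that real dissected tissue will separate this
cleanly.

## Numerical choices and problem sizes

* σ of the canonical trace is searched on a 0.005 grid over [0.5, 14]; the
  middle of the feasible interval is used.
* NIPALS: tolerance 1e-10 on the score vector, 500 iterations maximum;
  zero-variance columns receive unit scale and end up with zero weight.
* Component selection ties resolve to the smallest count; stratification
  keeps any class with fewer members than folds in training, with a
  message.
* BP fitting needs ≥ 3 informative scales; degenerate nodes fall back to
  mean BP. WLS weights `n_boot·φ(z)²/(BP(1−BP))`.
* Strict inequalities at every threshold (stain indices, VIP > 1,
  AU > 0.90), so boundary cases are conservative.
* Default problem sizes: 1150 bins, 50 evaluation repeats, 1000 bootstrap
  replicates per scale; `run_config(fast = TRUE)` shrinks these to 10
  repeats, 200 replicates and 64 px images for quick runs. The test suite
  uses the full 50 repeats and 1000 replicates where a guarantee is stated
  at that scale, and smaller sizes elsewhere.
* Every random stage derives its seed from one master seed by fixed
  offsets, so the whole report is reproducible bit for bit.

## Known limitations

* The AU extrapolation is asymptotic in both n_boot and the scale grid;
  with 10 samples the per-node AU retains visible Monte-Carlo noise even at
  1000 replicates, and borderline nodes (AU near 0.90) can cross the
  threshold between seeds.
* With 4-vs-3 cluster sizes the exact Mann–Whitney two-sided p cannot go
  below 2/35 ≈ 0.057: histology contrasts between small clusters are
  reported, but "significance" at 0.05 is unattainable at these sizes —
  an honest property of the design, not a defect.
* The PSR red-dominance rule and several upstream conventions (bin width,
  TIC normalization, the ROC class reduction) are declared package choices
  where the upstream instrument software leaves them unstated.
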