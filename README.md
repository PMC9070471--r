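# aortadissect

Multi-modal characterization of acute aortic dissection tissue: ambient
mass spectrometry (REIMS/iKnife), quantitative stain histology and
non-parametric statistics, built as one tested, reproducible pipeline.

Dissection splits the aortic wall into a false lumen (FL), a dissection
flap (FP) and a true lumen (TL). Whether the false lumen retains mechanical
integrity matters for how much aorta a surgeon replaces, and tissue removed
at surgery carries that information. This package implements the analysis
chain that extracts it — for surgical-proteomics and cardiovascular ECM
researchers who want the full workflow runnable, testable and inspectable
without access to patient data.

## What it computes

* **Burn-event processing.** Per-scan centroided spectra are reduced to one
  observation per cauterization "burn event": events are detected where the
  total ion current TIC(t) exceeds 5x the median baseline, and each ragged
  event is redistributed onto a canonical pseudo-Gaussian trace — 35 scans,
  burn spanning 12 scans, maximum at scan 18, sum(TIC) conserved — whose
  weights also average the event's scans into one consensus spectrum,
  lock-mass corrected on leucine-enkephalin (m/z 554.2615) and binned to
  unit-sum vectors over m/z 50–1200.
* **Stain quantification.** Collagen area from the weighted index
  `C = R/50 − G/20 + B/30` (threshold ~1.0, calibrated against the paired
  Picrosirius-Red section), elastin area from the darkness index
  `E = 1 − (R+G+B)/765` (threshold 0.5), both as pixel-count fractions of a
  blue-channel tissue mask, with threshold-variation error bars.
* **Classification.** PLS-DA (NIPALS PLS2, one-hot Y, argmax decision) of
  the three tissue types over 50 stratified 80/20 splits, components chosen
  per split by 2-fold CV; feature refinement by VIP
  (`VIP_j = sqrt(p Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`, keep mean and
  median > 1); pooled FL-vs-rest ROC/AUC.
* **Cluster stability.** Ward clustering (`ward.D2`) of the FL spectra with
  multiscale-bootstrap approximately unbiased p-values
  (`AU = 1 − Φ(v − c)` from the WLS fit `Φ⁻¹(1−BP_r) = v√r + c/√r`);
  clusters with AU > 0.90 are stable.
* **Statistics.** Tie-corrected Kruskal–Wallis with Dunn post hoc and Holm
  adjustment; exact-enumeration Mann–Whitney U for small clusters.
* **Synthetic data.** A generator for the full cohort — feature tables,
  spectra with planted class and sub-cluster markers, raw burn runs, and
  VVG/PSR image pairs with pixel-exact painted fractions — so every claim
  above is verified against known ground truth.

## Worked example

The `analysis/` directory holds the numbered study-analogue scripts
(`01_simulate.R` … `06_histology.R`); each writes its tables under
`results/`. Running them in order on the default seed prints, among other
things:

```
$ Rscript analysis/02_reims_preprocess.R
1 burn event(s) detected; first spans scans 21-32
Pseudo-Gaussian burn trace: 35 scans, 12 above threshold, maximum at scan 18, total TIC 659402
lock-mass shift applied: 0.04 Da

$ Rscript analysis/04_classify.R
full-feature model:
PLS-DA repeated evaluation: 50 stratified 80/20 splits
  mean accuracy 1.000, precision 1.000, recall 1.000, f1 1.000
325 of 1150 bins kept by VIP mean & median > 1
pooled FL-vs-rest AUC (refined model, held-out scores): 1

$ Rscript analysis/05_fl_clusters.R
3 stable cluster(s) at AU > 0.9
3 stable clusters; agreement with planted sub-groups:
    1 2 3
  1 4 0 0
  2 0 0 3
  3 0 3 0
```

Reading: the burn-event converter honours its 35/12/18 contract with TIC
conserved; at the generator's default class separation the held-out
classification is at ceiling (synthetic classes are cleaner than tissue —
see the vignette for what that does and does not show); and Ward +
multiscale bootstrap recovers exactly the three planted false-lumen
sub-groups, each stable cluster mapping one-to-one onto a ground-truth
sub-template. The same pipeline is callable in one stroke:

```r
library(aortadissect)
report <- run_all(run_config(seed = 42))
report$fl_clusters$n_clusters   # 3
```

Methods, parameter choices and limitations are documented in
`vignettes/dissection-workflow.Rmd`.

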