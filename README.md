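# neurostate

Spatiotemporal brain-state dynamics for pre/post rehabilitation cohorts.

Motor rehabilitation helps some Parkinson's disease patients much more than
others, and the neural signature of that responsiveness is visible in the
*dynamics* of resting-state activity: how long the brain dwells in, how
often it visits, and how it transitions between a small repertoire of
states. `neurostate` implements the full analysis chain such a cohort study
needs, for researchers working with paired (pre/post intervention) EEG,
fMRI and clinical assessments:

* **EEG microstates** — global field power (GFP), topographies at GFP
  peaks, polarity-invariant *modified k-means* (assignment by squared
  spatial correlation, template update by dominant eigenvector), selection
  of the number of classes k by the cross-validation criterion
  CV(k) = σ̂²ₖ·((C−1)/(C−1−k))², group templates sorted to the canonical
  A–D taxonomy, back-fitting with 30-ms minimum-duration smoothing, and the
  temporal metrics GEV, coverage, occurrence, duration and segment-level
  transition probabilities.
* **fMRI coactivation patterns (CAPs)** — per-ROI z-scoring, cosine
  k-means over individual frames (k = 14), Wilcoxon signed-rank z-maps
  named by their activated/deactivated networks over the canonical seven
  resting-state networks (VN, SMN, DAN, VAN, LN, FPN, DMN), and fractional
  occupancy, dwell time and appearance rate per subject and state.
* **Group statistics** — responder stratification by the 3.25-point
  MDS-UPDRS III minimal clinically important difference,
  Shapiro–Wilk-routed univariate tests, 2×2 mixed ANOVA
  (group × time) with partial eta squared, Bonferroni simple effects, and
  Spearman correlation of clinical reduction rates with neural change
  rates.
* **Responder prediction** — binary SVM on four baseline features
  (MDS-UPDRS III total, microstate C and D occurrence, DAN+ VAN− dwell
  time) under repeated stratified nested cross-validation with
  Youden-threshold optimisation, comparing clinical / EEG / fMRI /
  multimodal feature sets on shared splits.
* **A synthetic cohort generator** — semi-Markov microstate EEG, Markov
  CAP BOLD, and coupled integer clinical scores with stored ground truth,
  so the whole chain is testable without patient data.

The methods vignette (`vignettes/neurostate-methods.Rmd`) documents the
models, parameter defaults and design decisions in detail.

## Worked example

The `analysis/` directory is a numbered walkthrough over a simulated
52-subject cohort (24 responders, 28 nonresponders, two timepoints;
60-second EEG recordings to keep the example light):

```sh
Rscript analysis/01_simulate_cohort.R   # write EEG/BOLD/clinical data
Rscript analysis/02_microstates.R       # k selection, templates, metrics
Rscript analysis/03_caps.R              # CAP clustering, names, metrics
Rscript analysis/04_group_stats.R       # stratification, ANOVA, Spearman
Rscript analysis/05_prediction.R        # nested-CV SVM comparison
```

Output of the statistics and prediction stages on this cohort
(seed 1):

```
Stratification: 24 responders / 28 nonresponders (46.2%)
Significant group x time interactions (uncorrected p < 0.05):
  occurrence[C]                F(1,50) = 159.02, p = 0.0000, eta_p2 = 0.761
  occurrence[D]                F(1,50) = 191.99, p = 0.0000, eta_p2 = 0.793
  coverage[C]                  F(1,50) = 168.22, p = 0.0000, eta_p2 = 0.771
  coverage[D]                  F(1,50) = 182.81, p = 0.0000, eta_p2 = 0.785
  dwell_time_s[DAN+ VAN-]      F(1,50) =   9.12, p = 0.0040, eta_p2 = 0.154
  ...
Spearman change-rate correlations with MDS-UPDRS III reduction rate:
  ms_C_occurrence_change       rho = -0.856, p = 0.0000, p_bonf = 0.0000
  ms_D_occurrence_change       rho = +0.867, p = 0.0000, p_bonf = 0.0000
  cap_DANpVANm_dwell_change    rho = +0.368, p = 0.0073, p_bonf = 0.0218
Responder prediction, 5 x 5-fold nested CV, 5 iterations (mean +/- SE %):
  multimodal acc 66.15 +/- 1.44  sens 65.00 +/- 3.86  spec 67.14 +/- 1.34
  eeg        acc 60.77 +/- 0.98  sens 50.83 +/- 3.06  spec 69.29 +/- 2.90
  fmri       acc 57.69 +/- 0.61  sens 53.33 +/- 3.33  spec 61.43 +/- 3.46
  clinical   acc 51.15 +/- 1.98  sens 30.00 +/- 6.10  spec 69.29 +/- 4.60
```

Reading it: the injected intervention effects — responders' microstate-C
occurrence falling, microstate-D occurrence rising, and the DAN+ VAN− CAP
dwelling longer after treatment, with the reverse in nonresponders — are
detected as group × time interactions; the change rates correlate with
clinical improvement in the configured directions; and baseline neural
features outrank the clinical score for predicting response, multimodal
first. The transition-probability table
(`results/microstate_transitions.tsv`) carries the accompanying A/B→D
increases.

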