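---
title: "Brain-state dynamics for rehabilitation cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neurostate` implements a complete analysis chain for characterising how a
motor-rehabilitation intervention reorganises resting-state brain dynamics
in a pre/post clinical cohort: EEG microstate analysis, fMRI
coactivation-pattern (CAP) analysis, group-by-time statistics with clinical
correlation, and responder prediction. Because the patient data such studies
rest on are rarely shareable, the package also ships a synthetic-cohort
generator with stored ground truth; every stage is tested against that
truth. This vignette explains the models, the parameters that matter, and
the design decisions taken where the methodology leaves room.

## The EEG microstate model

Resting EEG is modelled as a sequence of a few recurring scalp topographies
("microstates", canonically labelled A-D) that remain quasi-stable for some
60-120 ms and switch abruptly. The pipeline follows the classical analysis
chain:

1. **Preprocessing** (`preprocess_eeg`): zero-phase Hamming-window FIR
   band-pass (default 1-30 Hz), optional resampling to 500 Hz, common
   average reference. The filter order defaults to one second of samples;
   the band edge must respect Nyquist.
2. **Global field power** (`compute_gfp`): the population standard
   deviation across channels at each sample,
   $\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_i (v_i(t)-\bar v(t))^2}$.
3. **Peak maps** (`extract_gfp_peaks`): topographies at strict local GFP
   maxima (endpoints excluded). Peaks are the moments of maximal
   signal-to-noise; clustering uses them, while back-fitting labels every
   sample.
4. **Modified k-means** (`modified_kmeans`): polarity-invariant clustering.
   A map joins the template with maximal squared spatial (Pearson)
   correlation; a template is re-estimated as the dominant eigenvector of
   its members' channel cross-product matrix (a sign-aligned mean update is
   available via `update = "mean"`). The objective is the global explained
   variance
   $\mathrm{GEV} = \sum_t \mathrm{GFP}(t)^2\,\rho_t^2 \big/ \sum_t \mathrm{GFP}(t)^2$,
   where $\rho_t$ is the correlation between map $t$ and its assigned
   template. Fifty random restarts are the default; the best restart by GEV
   wins. Convergence is declared when the relative GEV gain drops below
   1e-7 (or at 200 iterations); an emptied cluster is re-seeded from the
   currently worst-explained map. All tie-breaks (equal correlations,
   restart ties) resolve to the earliest index, so a seeded run is fully
   deterministic.
5. **Choosing k** (`select_k_cv`): the predictive-residual cross-validation
   criterion $\mathrm{CV}(k) = \hat\sigma^2_k\,\big(\tfrac{C-1}{C-1-k}\big)^2$,
   with $C$ the channel count and $\hat\sigma^2_k$ the mean residual
   variance of the maps about their polarity-aligned templates; the argmin
   over k = 2..8 is returned. On synthetic data generated from four
   templates this criterion recovers k = 4 (the test suite and the
   acceptance script recompute this).
6. **Group templates and sorting** (`build_group_templates`,
   `sort_templates`): individual template sets are concatenated and
   re-clustered; the resulting maps are assigned the canonical A-D labels
   by the permutation maximising total absolute correlation to built-in
   reference motifs (A/B: diagonal gradients, C: anterior-posterior,
   D: fronto-central; `canonical_reference`), exhaustively over $k!$ for
   $k \le 6$, with signs flipped positive and lexicographic tie-breaking.
7. **Back-fitting and smoothing** (`backfit`): every sample is labelled by
   maximal absolute correlation; then, while any segment is shorter than
   the minimum duration (default 30 ms), the shortest such segment
   (earliest on ties) is relabelled to whichever adjacent segment's
   template correlates better with its samples. Boundary segments merge
   inward. Segments shorter than the threshold are thereby removed as
   physiologically implausible transients.
8. **Metrics** (`compute_microstate_metrics`): per state, coverage (share
   of labelled time), occurrence (segments per second), mean duration
   (ms), GEV restricted to the state's samples; plus the transition matrix.
   Transitions are estimated on the *segment* sequence - the conditional
   probability of the next distinct state - because between-state
   quantities like A->D are only meaningful conditioned on a change; a
   per-sample variant (self-transitions included) is available via
   `per_sample_transitions = TRUE`. The identities
   $\mathrm{coverage} = \mathrm{occurrence}\times\mathrm{duration}$ and
   $\sum \mathrm{coverage} = 1$ hold exactly by construction and are
   asserted in the tests.

Low-GFP samples are labelled like any others by default (no rejection
rule); `gfp_floor_quantile` optionally excludes samples below a GFP
quantile, which then act as segment walls.

## The CAP model

Frame-wise CAP analysis treats each (z-scored) fMRI volume as a point in
ROI space and clusters frames directly:

1. **Z-scoring** (`zscore_roi`): each ROI standardised to mean 0, SD 1
   (population SD) within a subject-by-timepoint run; zero-variance ROIs
   are a named error.
2. **Cosine k-means** (`cap_cluster`): frames are unit-normalised and
   clustered with distance $1-\cos(x, c)$; a centroid is the
   unit-normalised mean of its assigned (unit-normalised) frames, making
   the procedure invariant to positive rescaling of any frame. k = 14 is
   the default; restarts default to 50 for desk-scale runs, with 1000
   available to match the heavier reference protocol (the restart count
   only affects how close the objective gets to its optimum, never the
   metric definitions). Empty clusters are re-seeded from the frame
   farthest from its centroid.
3. **Z-maps and naming** (`cap_zscores`): a CAP's z-map is the ROI-wise
   mean of its assigned frames; each ROI is tested against zero median by
   a Wilcoxon signed-rank test, Bonferroni-corrected across ROIs within
   the CAP. The CAP is named `"<argmax network>+ <argmin network>-"` from
   the network-mean z over the seven canonical resting-state networks (VN,
   SMN, DAN, VAN, LN, FPN, DMN); the "-" network is the minimum-z network
   even when its mean z is only weakly negative. CAPs with fewer than 5
   frames are flagged and not tested.
4. **Temporal metrics** (`cap_temporal_metrics`): fractional occupancy
   (share of frames), dwell time (mean consecutive run length times TR,
   reported 0 with `present = FALSE` for absent states), appearance rate
   (entries per minute). The identity
   $\mathrm{FO} = \mathrm{dwell}\times\mathrm{rate}/60$ holds exactly.

Sliding-window Pearson correlation (`sliding_window_fc`) is provided as a
time-resolved connectivity diagnostic only; it does not feed the
clustering, which operates on individual frames in the classical way.
Group-level clustering pools frames from all subjects and both timepoints
so that pre and post metrics live in a single state space.

## Group statistics

* **Stratification** (`stratify_responders`): responder iff the
  MDS-UPDRS III total decreased by strictly more than 3.25 points (the
  minimal clinically important difference); with integer scores this is
  equivalent to a 4-point drop.
* **Routing** (`route_and_test`): Shapiro-Wilk at 0.05 on each sample
  (on the differences for paired data) decides between t tests and
  Wilcoxon signed-rank / Mann-Whitney U. Rank tests are exact for n <= 25
  without ties, normal-approximated with tie correction otherwise.
  Zero-variance paired data return a flagged p = 1 convention rather than
  an error, so pipelines survive degenerate synthetic corners.
* **Mixed ANOVA** (`mixed_anova_2x2`): group (between) by time (within),
  fitted via `stats::aov` with an `Error(subject)` stratum.
  $\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$
  uses the error stratum matching each effect (between-subject error for
  group; within-subject error for time and the interaction). The stratum
  sums of squares always add up to the corrected total (asserted at 1e-9
  relative); a degenerate stratum (zero within-subject variance) returns a
  flagged F = 0, p = 1 rather than a 0/0 artefact. The test suite checks
  the full decomposition against an independent cell-means oracle.
* **Simple effects** (`simple_effects`): the four natural contrasts
  (pre-post within each group, paired; between groups at each timepoint,
  independent), each routed as above, Bonferroni-scaled by an *explicit*
  family size (default 4) - families are never inferred silently.
* **Spearman** (`spearman_family`): rho by average-rank Pearson
  correlation with p from the t approximation (chosen over the exact
  small-n switch in `cor.test` for uniform behaviour), Bonferroni over a
  declared family. Raw and corrected p are both reported; interpretation
  of marginal cases is left to the caller.

## Responder prediction

`nested_cv_svm` runs a binary SVM under repeated, stratified, nested
cross-validation. Per repetition: stratified outer 5-fold split; within
each outer training set, features are standardised with training statistics
only, hyperparameters are selected by inner stratified 5-fold search, and
the decision threshold is chosen on the pooled inner-fold decision values
by maximising sensitivity + specificity (Youden's J). Outer predictions are
pooled into repetition-level accuracy, sensitivity (responder = positive
class) and specificity; the report carries mean and standard error
(SD/sqrt(repetitions)) over the default 5 repetitions. Class imbalance is
handled by inverse-frequency class weights.

The RBF kernel is the default, with cost and kernel width searched on a
log grid (7 x 7 by default) or by an expected-improvement search
(`tune = "bayes"`, 30 evaluations over log-uniform boxes, Gaussian-process
surrogate with a fixed squared-exponential kernel). The linear kernel is
selectable and is what `compare_feature_sets` benefits from with only one
to three features, where an extra kernel-width dimension adds selection
noise without expressive gain; for the linear kernel only cost is searched,
over a bounded range (very large costs on near-separable data stall the
underlying optimiser). `compare_feature_sets` draws the fold assignments
once and shares them across feature sets so that accuracy differences
reflect the features, not the splits. A leakage audit asserts that no test
index is touched before prediction.

## What the synthetic cohort emulates

`simulate_cohort` draws a 24-responder / 28-nonresponder cohort, two
timepoints each, with three coupled layers:

* **EEG**: a semi-Markov state sequence over four canonical templates -
  explicit gamma-distributed dwell durations (mean 80 ms, shape 4) over a
  zero-diagonal jump matrix, because per-sample chains cannot produce
  60-100 ms dwell at 500 Hz without extreme self-transition tuning. The
  waveform is the active template scaled by a rectified 10 Hz sinusoid
  (random phase per segment) plus spatially correlated Gaussian noise
  (distance kernel, correlation length 0.3 on the unit-disk layout),
  band-limited to 1-30 Hz *before* the SNR scaling so that `snr_db`
  (default 5) is the in-band GFP-power ratio. The summed signal is not
  re-filtered: a post-hoc low-pass would smear every state switch over
  roughly 33 ms and blur the instantaneous topography transitions that
  define the microstate model; the carrier content already sits at ~20 Hz,
  inside the band.
* **fMRI**: a Markov chain over 14 CAP states (mean dwell 4 frames,
  TR 2 s, 240 frames); each frame is the active network-pair pattern (+1
  on the activated network's ROIs, -1 on the deactivated one's,
  unit-normalised) times an amplitude of 6 - chosen so an active ROI
  deflects by about two noise SDs (noise SD 0.5), the order of typical
  z-scored CAP deflections - plus white ROI noise.
* **Clinical scores**: subscale pre-scores from truncated normals at the
  reported group moments; the total is their sum (which keeps subscales
  consistent with the total by construction); the total pre-post change is
  drawn from group-specific truncated normals so that every responder
  exceeds the 3.25-point MCID and no nonresponder does, then distributed
  over subscales proportionally to the reported mean subscale changes,
  with integer rounding that preserves the total.

Treatment effects enter as multiplicative factors on the post-timepoint
state parameters: responders get occurrence-C x0.8, occurrence-D x1.25, a
guaranteed >= +0.05 absolute increase of the A->D and B->D transition
probabilities, and DAN+ VAN- dwell x1.3; nonresponders get the
reciprocals. Occurrence targets are met by calibrating the jump-matrix
weights to a target stationary visit distribution
(`calibrate_jump_matrix`, fixed-point iteration); because raising
occurrence-D already raises the A->D transition by more than 0.05 under
this construction, the boost is implemented as a guaranteed minimum rather
than an additive term, which keeps the occurrence factors exact instead of
compounding.

Baseline (pre-timepoint) group differences carry the predictive signal:
responders start with slightly raised microstate-C and lowered
microstate-D occurrence (weight factors 1.16 and 0.86) and a longer
DAN+ VAN- dwell (factor 1.6). The opposite directions for C and D are
deliberate: both occurrence features share the subject's mean-duration
jitter, and opposite-signed effects keep that shared noise off the C/D
discriminant while avoiding the simplex attenuation that same-signed
weight changes suffer (scaling both weights by f changes the realized
ratio only by 2f/(1+f)). The dwell factor is sized against the ~50%
sampling noise that a 240-frame run of a 14-state chain puts on a
per-subject dwell estimate (about 4 visits). These three factors were
calibrated once so that the four feature sets reproduce the reported
modality hierarchy (multimodal > EEG > fMRI > clinical) at realistic
accuracy levels; per-subject biological variability is log-normal with
SD 0.12.

Clinical improvement and the subject-level neural effect sizes share a
Gaussian copula at |rho| = 0.4 (rank coupling; the Spearman target is
matched in expectation only). The coupling signs are internally consistent
with the injected group effects - C negative, D positive, dwell positive
with respect to the MDS-UPDRS III reduction rate - since a pooled
correlation cannot simultaneously carry an arbitrary sign and the injected
group-effect directions.

**What the generator does not emulate**: volume conduction and leadfield
mixing, heart/eye/muscle artefacts, HRF convolution and autocorrelated
BOLD noise, motion, medication state, or site effects. Passing tests
therefore certify the *computational chain* - that each stage recovers the
dynamics its model class describes - not robustness to the full mess of
real recordings.

## Numerical conventions and degenerate inputs

* All tables are UTF-8, tab-delimited, header mandatory, decimal points
  only; timepoints are `pre`/`post`, groups
  `unknown`/`responder`/`nonresponder`.
* EDF export scales each channel into 16-bit integers; physical limits are
  written with the guarantee that their ASCII form still brackets the data
  range, so a round trip errs by less than one quantization step.
* Readers never return objects that violate their type's invariants; they
  raise classed conditions (`neurostate_error_*`) instead.
* Every stochastic routine takes a seed and is bit-reproducible under it.
* Zero-variance samples, constant columns, absent states and empty
  clusters all have defined, documented behaviours (flagged conventions or
  named errors) rather than incidental ones.

## Problem sizes used by the test suite

The statistical test blocks run at sizes chosen for a desk-scale machine:
template-recovery and power checks use 60-second EEG recordings (the
SNR, dwell structure and effect sizes stay at the generator defaults; only
the recording length is shortened), 10 clustering restarts, 20 cohort
seeds; null calibration uses 1000 small (8+8) cohorts with 10-second
sequences; the cluster-number selection check runs one full-length
(180 s) subject at 50 restarts, as does `scripts/acceptance.R`.

## Known limitations

* At 240 frames and k = 14, a per-subject dwell-time estimate rests on
  roughly 4 visits. The group-by-time interaction on DAN+ VAN- dwell at a
  1.3x/0.77x effect pair is consequently under-powered: repeated 20-seed
  measurements put its power near 0.7-0.8, and the corresponding test
  block can fail on a given seed path while the occurrence interactions
  detect at full power. Longer runs or fewer states would fix this; both
  are fixed features of the emulated acquisition.
* With 52 subjects, a chance baseline imbalance makes the null clinical
  classifier reach 60-65% cross-validated accuracy in roughly one cohort
  in ten (the chance imbalance is shared by training and test folds drawn
  from the same cohort), and the realized fMRI feature separation
  occasionally collapses or overtakes the EEG features'. The full
  four-way modality ordering therefore reproduces in about three quarters
  of cohort draws rather than always; this is finite-cohort sampling, not
  classifier failure.
* The exhaustive template-sorting step is guarded at k <= 6; beyond that
  an explicit override is required.
* Microstate transition probabilities are conditional on a state change;
  studies that count per-sample self-transitions will see different
  numbers (the flag `per_sample_transitions` reproduces that convention).
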