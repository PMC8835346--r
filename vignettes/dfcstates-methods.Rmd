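---
title: "Dynamic functional connectivity states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The problem

Static functional connectivity (SFC) — one Pearson correlation per
region pair over a whole resting-state scan — assumes the coupling
between brain regions is stationary over the scan. Dynamic functional
connectivity (DFC) drops that assumption: correlations are re-estimated
inside a short sliding window, producing a *time series* of connectivity
matrices whose temporal structure itself becomes the object of study.
`dfcstates` implements the complete ROI-level DFC workflow used in
clinical resting-state studies (the motivating application is a chronic
tinnitus cohort scanned before and after treatment, but nothing in the
code is specific to it):

1. temporal preprocessing of region-averaged BOLD signals;
2. sliding-window tapered correlation with the 1/w filtering scheme;
3. three temporal-variability metrics per connection;
4. connectivity-state discovery by L1 k-means with transition
   probabilities;
5. covariate-adjusted group and clinical statistics.

A synthetic-cohort generator with a known latent-state ground truth
backs every stage with testable expectations.

## Preprocessing model

The pipeline starts from a time × region matrix (e.g. 90 AAL regions
without cerebellum) sampled at TR seconds, together with an SPM-style
6-column motion-parameter file. Spatial preprocessing (realignment,
normalization, smoothing) is assumed done upstream; `extract_roi_signals()`
can average a 4D NIfTI within an integer-labelled atlas when region
tables are not already available.

The temporal chain is fixed: **discard → nuisance regression → detrend +
band-pass → scrubbing**.

* **Discard**: the first 5 volumes (pre-steady-state magnetization) are
  dropped; 217 acquired volumes leave 212 for analysis.
* **Nuisance regression**: least-squares removal of an intercept, the
  Friston-24 motion expansion (6 parameters, their one-volume backward
  lags zero-padded at the first row, and both sets squared), and any
  external regressors such as white-matter/CSF means. Collinear columns
  are dropped with a warning rather than failing.
* **Detrend + band-pass**: linear detrend, then a zero-phase order-2
  Butterworth band-pass at 0.01–0.08 Hz, the conventional resting-state
  band. Zero phase (forward–backward filtering) matters here because any
  phase shift would displace windows in time. Columns are demeaned and
  symmetrically reflection-padded before filtering to suppress edge
  transients; symmetric (even) reflection is used because it preserves
  both constant levels and Nyquist-rate alternation, and the signals are
  already detrended so the slope crease of even reflection is harmless.
* **Scrubbing**: framewise displacement uses the Power convention,
  FD(t) = Σ|Δtranslation| + 50 mm × Σ|Δrotation| (the formula and radius
  are the dominant convention for a 0.2 mm threshold; neither is
  universal). Frames with FD > 0.2 mm are *replaced*, not deleted, by a
  natural cubic spline through the surviving frames (nearest-value at
  the sequence edges), keeping the time grid intact — essential because
  the window count floor((T − w)/step) + 1 is part of the design.
  Scrubbing runs last; whether it should precede filtering is genuinely
  ambiguous in common practice, so the order is a documented choice
  rather than a claim. Mean FD is computed on the pre-scrub series and
  carried as a statistical covariate.

## Sliding-window DFC and the 1/w scheme

The default window is 12 TRs (28.8 s at TR 2.4 s) stepped by 1 TR with a
Hamming taper (symmetric, a₀ = 0.54). A window of length w seconds
cannot resolve fluctuations slower than 1/w Hz — they masquerade as
spurious DFC — so the scheme filters twice: ROI signals are
**high-passed at 1/w** before windowing, and each connection's windowed
correlation series is **low-passed at 1/w** afterwards (sampling
interval step × TR). Both are zero-phase order-2 Butterworth filters;
series too short for the IIR warm-up fall back to FFT-mask filtering.

Within a window the taper enters through weighted correlation: with
normalized Hamming weights \(w_t\) and weighted-demeaned segments
\(x' = x - \sum_t w_t x(t)\),

\[
r_{ij} \;=\; \frac{\sum_t w_t\, x'_i(t)\, x'_j(t)}
{\sqrt{\sum_t w_t\, x'_i(t)^2 \; \sum_t w_t\, x'_j(t)^2}} .
\]

This is the standard tapered dFNC construction; an explicit
sum-of-weights oracle pins the algebra in the tests, and with a
rectangular taper spanning the full series it reduces *exactly* to
static FC. Correlations are Fisher z-transformed (atanh) after clipping
|r| ≤ 1 − 10⁻⁷; the diagonal is never a feature, so 90 regions give
90·89/2 = 4,005 connection features in a fixed row-major upper-triangle
order that is written into every output header (a silent ordering
mismatch is the classic dFNC bug).

Three per-connection summaries describe temporal variability:

* **DFC-Str** — the temporal mean of the windowed z series;
* **DFC-SD** — its sample standard deviation (denominator W − 1; a
  sample statistic over a sampled window series, stated here because
  conventions differ);
* **ALFF-FC** — the mean single-sided FFT amplitude over bins in
  (0, 1/w], DC excluded, after mean removal; the fluctuation amplitude
  of connectivity itself, mirroring the voxel-ALFF convention. It is
  computed after the low-pass (the pipeline's stated order), though the
  band cap makes the order nearly immaterial.

## Connectivity states

State discovery follows the exemplar two-stage scheme. Because 1-TR
stepping makes adjacent windows almost identical, clustering all windows
directly is redundant and slow; instead the windows at *strict local
maxima* of across-connection FC variance (endpoints and plateaus
excluded; global maximum as fallback) serve as exemplars. Exemplars are
clustered by k-means under the **L1 (Manhattan) distance** with many
random restarts (default 500); the resulting centroids initialize a
single clustering of all windows of all subjects. The implementation is
internally consistent with the L1 objective: assignment minimizes
Manhattan distance (ties to the lowest state index), and the update step
is the component-wise **median**, the exact L1 minimizer — an exhaustive
partition search on tiny inputs verifies the objective. Empty clusters
are reseeded to the instance farthest from its assigned centroid, and
the objective trace is checked to be non-increasing.

The number of states is chosen by the elbow criterion on the cluster
validity index, the ratio of within-cluster distance (mean L1 distance
of an instance to its centroid) to between-cluster distance (mean
pairwise centroid L1 distance), over k = 2…20. The elbow is defined
reproducibly as the interior k maximizing the discrete second difference
of the validity curve, ties toward the smaller k; curve and choice are
both persisted so a human can override via configuration. One caveat
found during validation: on *symmetric, equidistant* cluster geometries
the k=2→3 validity drop dominates the curvature and the rule
systematically returns k − 1. Randomly placed well-separated clusters do
not show this, so the selection property is validated on such data; on
real cohorts the persisted curve should always be inspected.

Per subject, consecutive window labels yield a k × k transition
probability (TP) matrix — counts row-normalized, self-transitions
included, never pooling transitions across subject boundaries. States
never occupied as a source get an all-zero row and an explicit
"unvisited" flag.

## Statistics

Group differences in any per-connection metric (SFC, DFC-Str, DFC-SD,
ALFF-FC) use a per-feature GLM: feature ~ intercept + group + age + sex
+ mean FD, with continuous covariates mean-centred and sex a single
indicator so the group coefficient stays an adjusted group difference;
with no covariates the t statistic is algebraically the pooled
two-sample t. Within-group pre/post contrasts regress difference scores
on an intercept plus covariates (the simplest covariate-adjusted paired
design; the t sits on the intercept). Connection-wise p-values are
corrected by Benjamini–Hochberg FDR; the k² TP cells are reported
uncorrected by default with an explicit flag (an optional FDR switch
exists), matching common reporting practice for the small number of
cells. Perfectly fitted features (zero residual variance) are handled
explicitly: t = 0, p = 1 when the effect is also zero, an infinite-t
sentinel with p = 0 otherwise.

Clinical correlations are Pearson by default and Spearman for ordinal
scales; the 0–6 level tinnitus-loudness scale (TDI) is always routed to
Spearman. Demographic tables use Shapiro–Wilk-gated Student's t /
Wilcoxon tests and an uncorrected Pearson chi-square for sex.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions so that every
downstream stage has ground truth: by default 17 patients and 22
controls (12 patients rescanned post-treatment), 217 volumes of
90-region signals at TR 2.4 s. Each scan is generated as

* a latent first-order Markov state sequence at **volume** resolution
  (dwell is a property of the brain, not of the measurement; windows
  inherit a majority label only for evaluation), default 0.88
  self-transition probability;
* multivariate-normal draws from the current state's covariance plus
  white observation noise (SD 0.3 against unit state variance);
* a motion trace (random walk, translation SD 0.01 mm/frame, rotation SD
  2×10⁻⁴ rad/frame) with a 2% rate of single-frame translation spikes of
  0.25–0.5 mm — above the 0.2 mm FD threshold by construction, and
  translation-only so the FD formula's translation term is exactly
  testable;
* a metadata record whose clinical scores are affine functions of the
  subject's planted effect plus Gaussian noise, giving the
  correlation stage a known positive sign. Controls carry no tinnitus
  scales.

Two state families are provided. `make_state_covariances()` builds a
hypo-to-hyper magnitude ramp (block correlation rising from 0 to
`within_r` across states), mirroring the qualitative structure of
reported state centroids. `make_pattern_covariances()` gives each state
its *own* correlated block — states orthogonal in connection space. The
distinction matters: validation showed that magnitude-ramp states place
windows on a one-dimensional continuum that 12-sample windowed
correlations cannot segment reliably (window-label agreement plateaus
near ARI 0.5 regardless of noise level), whereas pattern-distinct states
are recoverable. "Well-separated states" in the recovery guarantees
therefore means pattern separation.

Group and treatment effects are planted through the designated
connection (regions 1–2 by default): a subject with effect scale e has
that connection's across-state correlation deviations scaled by e, so
e > 1 inflates its DFC-SD and ALFF-FC without moving its mean much.
Patients draw per-subject scales around `group_effect` (default 2, a
deliberately large, clearly detectable effect — the underlying study
reports no effect sizes, so this is a free parameter chosen once),
controls sit at 1. Patients' transition matrices additionally shift
`tp_effect` = 0.08 of mass from the state-2 self-transition into the
2→3 transition. Positive definiteness is re-checked after every
modification and fails hard naming the state.

What the generator does *not* emulate: hemodynamic autocorrelation and
smoothing, scanner drift and physiological noise spectra, spatial
structure below the region level, rotation-driven motion, and missing
data. Passing recovery tests therefore show the estimator chain is
correct under its own model, not that real BOLD satisfies that model.

## Numerical choices and validation scales

* Fisher z clipping at |r| = 1 − 10⁻⁷ (z ≈ 8.4); clip events counted.
* Assignment ties and elbow ties break deterministically toward the
  lower index, so runs are bit-reproducible at fixed seeds; one
  top-level seed derives all stage seeds.
* Validation experiments are scaled to run quickly while keeping the
  statistics meaningful, and these sizes are the package's documented
  choices: state recovery uses 6 subjects × 288 windows of 12-region
  pattern states (3 states, self-transition 0.95, noise SD 0.05) and
  requires window-label ARI ≥ 0.8 with per-subject TP max-abs error
  ≤ 0.1; elbow selection uses 20 replicates of 4 × 40 points around
  random centroids in 66-dimensional connection space with ≥ 90%
  correct; calibration uses 13 + 13 subjects × 8 regions × 185 volumes —
  200 null replicates must keep the any-connection false-positive rate
  ≤ 0.08 after BH, and 100 replicates with the default planted effect
  must recover the designated connection at q < 0.05 in ≥ 80%.
* The per-subject TP error bound needs enough windows: at ~150 windows
  and self-transition 0.95 the binomial sampling error of a TP cell is
  already ~0.03, and short dwells absorbed by the 12-TR window bias the
  diagonal upward; 288 windows keep the worst subject safely inside 0.1.

## Known limitations

* Scan-length intuition does not apply to DFC-SD: with a fixed window
  width the per-window sampling error is independent of scan length, so
  DFC-SD converges to a positive constant as T grows. It vanishes only
  as the *window* widens (tested on a single-state noiseless cohort).
* The elbow rule's equidistant-geometry failure mode described above.
* Windows spanning state transitions produce blended connectivity
  vectors; with short dwell times window-level labels are intrinsically
  noisy however good the clustering.
* `scrub_interpolate` interpolates through long high-motion runs rather
  than censoring them; subjects with > 50% flagged frames are only
  flagged unusable, not removed.
* The paired design assumes difference scores are exchangeable across
  subjects after covariate adjustment; no mixed-effects modelling.
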