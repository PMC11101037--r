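---
title: "Measuring consistent facial responses from keypoint trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring consistent facial responses from keypoint trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmface)
```

## The problem

When a cohort of viewers watches the same emotionally evocative video, their
facial responses are partly time-locked to the stimulus. `crmface` quantifies
that shared, stimulus-driven component frame by frame — the facial analogue
of inter-subject correlation in neuroimaging. Two families of per-frame
metrics are provided:

* **AU consistency** (`kappa_AU`): the fraction of subjects whose video is
  FACS-coded as showing the same action unit at a frame,
  $\kappa_{AU}(k,\tau) = \tfrac{1}{n}\sum_i \mu(i,k,\tau)\times 100$, with
  the overall value $\kappa_{AU}(\tau) = \max_k \kappa_{AU}(k,\tau)$. This
  needs manual FACS coding and serves as the reference.
* **Keypoint metrics**: automated statistics on keypoint-movement (KPM)
  vectors $X(\tau)\in\mathbb{R}^{132}$ (x/y displacements of 66 tracked
  landmarks relative to each subject's neutral frame), testing per frame the
  null hypothesis that the cohort-mean displacement is zero.

## Statistical models

Subjects are treated as i.i.d. draws from a time-dependent distribution.

* **Independent univariate Gaussian**: each of the 132 coordinates gets a
  one-sample t-score $t_i = \bar X_i/(s_i/\sqrt n)$ with $n-1$ degrees of
  freedom. `avg_t` is $\tfrac{1}{132}\sum_i |t_i|$ and `max_t` is
  $\max_i |t_i|$.
* **Independent bivariate**: each keypoint's $(\Delta x, \Delta y)$ pair is
  a bivariate normal; the one-sample Hotelling statistic
  $t^2_i = n\,\bar r_i^\top \hat\Sigma_i^{-1}\bar r_i$ yields 66 values,
  summarized by their mean (`avg_t2`) or maximum (`max_t2`).
* **Multivariate with dimensionality reduction** (`pca_t2`): with
  $n \ll 132$, the full 132-dimensional Hotelling statistic is not
  computable, so the pooled data matrix (all subjects, all frames) is
  reduced by truncated SVD to $k$ components (default $k = 5$) and the
  Hotelling statistic is computed on the $k$-dimensional scores.

Some published statements of the two max metrics carry a $1/k$ prefactor on
the maximum. Taken literally that forces `max` $\le$ `avg`, defeating the
stated purpose of the maximum (sensitivity when only a few keypoints move),
and it cannot change any rank-based downstream analysis. We treat the
prefactor as a typographical slip: the default is the plain maximum, and
`literal_scaling = TRUE` reproduces the printed formula.

### Numerical conventions

* **Zero variance**: a coordinate with zero sample variance gets $t = 0$ if
  its mean is zero, otherwise a signed cap (default $\pm 10^6$), keeping
  every metric finite while flagging degenerate coordinates.
* **Structural degeneracy (snap tolerance)**: registration pins some
  coordinates exactly — part anchors land on the reference by construction,
  and the midline x-coordinates equal the nose-bridge x after
  symmetrization. What remains there is floating-point noise
  ($\sim 10^{-14}$ px). Sample SDs and means below `1e-8` px are snapped to
  exact zero so the zero-variance conventions apply; real facial motion is
  at least $10^{-3}$ px, six orders of magnitude away. Without the snap,
  these coordinates would contribute t-ratios of rounding noise and destroy
  the pipeline's invariance to head-pose nuisance.
* **Singular 2×2 covariances** with two live axes are stabilized by a
  relative ridge (`1e-8` times the mean diagonal) with a warning; a
  structurally dead axis falls back to the univariate statistic on the live
  axis. A keypoint frozen in both axes gives $t^2 = 0$ (zero mean) or the
  cap (nonzero mean).
* **PCA centering**: the null hypothesis is "mean displacement zero", i.e.
  the *origin* of KPM space (the neutral face) is meaningful. The reduction
  is therefore an uncentered truncated SVD by default, so the origin maps to
  the origin of score space. `center = TRUE` is available; it shifts the
  tested null to the pooled mean.
* **Conditioning**: the Hotelling statistic's forward error grows with the
  condition number of the 2×2 sample covariance; no double-precision
  implementation can do better. The oracle-equivalence tests therefore draw
  slices whose per-keypoint sample covariances have singular values bounded
  in $[0.5, 2]$ by construction, making a $10^{-10}$ agreement check
  well-posed; unconstrained draws are exercised statistically by the null
  calibration instead.

## Geometric pipeline

Landmarks are normalized in three stages before KPM vectors are formed:

1. **Frontalization**. Full 3D frontalization algorithms exist but their
   internals are out of scope here; the stage is pluggable. The default 2D
   stand-in (adequate for near-frontal recordings) levels the in-plane roll
   about the outer eye-corner axis (landmarks 36–45), then symmetrizes each
   bilateral landmark pair about the vertical midline through the nose
   bridge (landmark 27). `method = "none"` passes data through.
2. **Affine registration**: per frame, the least-squares six-parameter
   affine transform carrying the six anchor landmarks {0, 16, 39, 42, 27,
   33} onto a shared reference face, applied to all 66 points. This removes
   head position, scale and shear-like appearance differences.
3. **Part-wise similarity registration**: residual intra-face geometry
   (inter-ocular distance, nose length, ...) is removed per face part with
   four-parameter similarity fits on part anchors (left brow+eye: 42, 45;
   right brow+eye: 36, 39; nose: 27, translation-only since one
   correspondence identifies nothing more; jawline: 0, 16). Lips have no
   stable anchors and are deliberately exempt — lip motion *is* signal.

**Reference face.** The registration target is the cohort mean of the
subjects' frontalized neutral frames. Each neutral is first brought into a
canonical similarity pose (eye axis level, eye midpoint at the origin,
inter-ocular distance 100 px) before averaging. This extra canonicalization
is a deliberate design choice: without it, per-subject residual scale and
translation left over from frontalization would leak head-pose nuisance into
the reference, and the pipeline's invariance to injected per-frame
similarity nuisance (which we verify to $10^{-6}$) could not hold.

**Neutral frame.** The reference frame for KPM is frame 0 by default
(recordings conventionally start at rest); a fixed index or an automatic
rule (frame closest to the per-coordinate median face) can be configured.

## Cohort analysis

* **Consistency classes**: the per-frame series is split at its empirical
  30th/60th/90th percentiles (nearest-rank) into *Inconsistent*, *Low*,
  *Mild* and *High Consistent* classes; intervals are half-open with
  boundary values going up, so the top class holds the top ~10% of frames.
  The percentile triple is a parameter; the published analysis fixed the
  top split at ~10% after inspecting the CDF of the AU-consistency series.
* **Segment tables**: per emotion segment, the percentage of frames per
  class. Segments are extended through their following inter-segment gap by
  default, since expressions decay slowly after a segment ends. Full
  precision is kept internally; display rounding is half-up (printed rows
  may sum to 99–101).
* **Agreement**: a keypoint metric is compared to the AU reference by (a)
  ordinary least squares / $R^2$ between the two per-frame series and (b)
  the row-wise averaged KL divergence between their class-distribution
  tables (rows normalized to probabilities; zero cells in both operands
  replaced by `epsilon = 1e-12` and renormalized; direction metric → AU;
  all conventions exposed).

### What the printed-table KL comparison can and cannot reproduce

The published row-averaged KL values for the five metrics (0.92, 0.98,
0.93, 0.98, 0.96, with the average t-statistic smallest) were computed from
unrounded tables. Reconstructing them from the *printed integer* tables is
only partly possible: rows of the max-type metrics place 1–6% of their mass
on cells where the printed AU row is 0, and a true cell value of, say,
0.4% printed as 0 shifts a KL term by about one nat. Under the default
convention this package reproduces the average-t value (0.909 vs 0.92) and
the strict ranking, while the max-t reconstruction gives 1.13 vs the
published 0.98 — a discrepancy attributable to table rounding, not to the
implementation. The acceptance suite asserts all three facts and leaves the
max-t clause intentionally failing rather than loosening the tolerance. A
scan over smoothing constants ($10^{-12}$ to $2\times10^{-2}$), both KL
directions, additive vs replacement smoothing, symmetrized KL and JSD shows
no convention that reproduces 0.92 and 0.98 jointly.

## The synthetic cohort generator

Restricted recordings cannot ship with the package, so every stage is
exercised on synthetic cohorts with known ground truth. The generator
emulates a DISFA-like recording:

* a symmetric canonical 66-point face template (~200 px face box);
* per-subject shape variation: a random affine jitter (±5% linear part,
  ±5 px translation) of the template;
* epochs of coherent movement: each epoch names a coded AU, a frame range,
  a participation probability `p`, and an amplitude distribution; a subject
  participates with probability `p`, draws one amplitude, and displaces
  along the AU's unit displacement field scaled by a linear
  onset/apex/offset ramp. Displacement fields encode the qualitative FACS
  appearance changes (inner brows up, lip corners obliquely up and out,
  jaw down, ...) with weights peaking at the focal landmarks and decaying
  over the surrounding region that the muscle group carries along;
* i.i.d. Gaussian tracking jitter (default 0.5 px, sub-pixel tracker
  noise) on every frame except frame 0;
* per-frame in-plane similarity head-pose nuisance (default ±5°, ±5%
  scale, ±10 px — mild near-frontal motion).

**Frame 0 is emitted noise-free** (no jitter, no displacement; pose
nuisance still applies). Frame 0 is the KPM reference, so this makes the
downstream displacement noise i.i.d. across frames and subjects; the null
calibration then matches the exact Student-t and Hotelling-F sampling
distributions, and the closed form
$E|t_\nu| = \sqrt{\nu}\,\Gamma(\tfrac{\nu-1}{2})/(\sqrt{\pi}\,\Gamma(\tfrac{\nu}{2}))$
applies without correction terms. With a jittered reference frame, all
frames would share the reference's noise (pairwise correlation 1/2) and
naive Monte-Carlo error bars would be invalid.

**AU labels and ground truth.** Intensity codes quantize the momentary
displacement amplitude into six equal-width bins over
$[0, 2\cdot\text{amp\_mean}]$. The ground-truth consistency series is the
fraction of subjects whose momentary amplitude quantizes to intensity ≥ 1;
by construction it equals the binarized emitted-label consistency at every
frame. DISFA codes intensities 0–5 but the consistency formula needs binary
presence; the presence threshold (intensity ≥ 1 by default, ≥ 2 as a
stricter convention) is configurable because the published analysis does
not state the one used.

**What a green test establishes — and what it does not.** The synthetic
world validates the statistical machinery (null calibration, power
monotonicity, parameter recovery, registration invariance) and the
pipeline's plumbing. It does not emulate out-of-plane pose, tracker
failures/drift, AU co-occurrence structure, asymmetric expressions
(deliberately: the frontalization stand-in symmetrizes), or inter-coder
disagreement in FACS labels. Quantities that depend on the restricted
recordings themselves ($R^2 = 0.78$ between avg-t and AU consistency, the
published percentile boundary values, "5 components explain 90% of
variance") are shipped as reference numbers only and are replaced by
property-based substitutes in the tests. In this generator's world the
average t-statistic recovers the ground-truth participation series with
$R^2 \approx 0.76$, while the max-type metrics score slightly higher —
expected for region-local signals, where averaging over 132 coordinates
dilutes; the published ranking claim (avg-t closest to the AU reference by
KL) concerns the real-data tables and is asserted on those.

## Known limitations

* The frontalization stand-in corrects only in-plane roll and asymmetry;
  strong out-of-plane pose requires plugging in a true frontalization.
* Metrics are descriptive; no multiple-testing-corrected per-keypoint
  significance maps are produced.
* The per-keypoint Hotelling metrics need $n \ge 3$ subjects; `pca_t2`
  needs $n > k$.
* Config files are JSON only (no YAML parser among the package's
  dependencies).
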