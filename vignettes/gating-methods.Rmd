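---
title: "ECG gating methods for cardiac PET: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG gating methods for cardiac PET: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petgate)
```

## The problem

Cardiac PET acquired in list mode can be gated retrospectively: every
detected event carries a timestamp, and the ECG R peaks recorded by the
scanner partition the acquisition into cardiac cycles (R-R intervals).
Binning events by cardiac phase yields one image per *gate*, from which
end-diastolic volume (EDV), end-systolic volume (ESV) and ejection
fraction (EF = 100·(EDV − ESV)/EDV) of the left ventricle can be measured.
How the gates are defined matters: R-peak detection inside an MR bore is
error-prone, and arrhythmic or artefactually merged beats contaminate the
phase definition. `petgate` implements three gating schemes found on
clinical PET/MR consoles and quantifies their effect on EDV/ESV/EF
accuracy on a fully synthetic beating-LV phantom, where ground truth is
known exactly:

* **STD** — every R-R interval is divided into exactly `n_gates` (default
  8) equal gates. Gate width varies with cycle length, so long abnormal
  beats smear dissimilar cardiac phases into the same gate.
* **STD-BR** — STD restricted to beats whose R-R interval lies inside an
  acceptance window; abnormal beats are rejected outright, at the price of
  discarded acquisition time (count loss).
* **FW** — a single fixed gate width, defined as `1/n_gates` of the mean
  accepted R-R interval, applied from the R peak of *every* beat (up to
  `n_gates` full-width segments per beat; the residual tail of a long beat
  is left unassigned). Because the systolic phase of the LV has nearly
  constant duration regardless of cycle length, early fixed-width gates
  stay phase-pure even on arrhythmic beats.

In the equivalence limit — perfectly regular beats whose length equals the
mean accepted R-R — the three schemes produce identical schedules, which
the test suite asserts exactly.

## The synthetic cohort

### R-peak trains

`simulate_rpeaks()` draws normal R-R intervals from a truncated normal
distribution (mean `mean_rr_ms`, sd `hrv_sd_ms`, floor at 40% of the
mean). Two abnormality mechanisms reproduce what scanners record:

* with probability `p_arrhythmia` an interval is stretched by
  `arrhythmia_scale` (default 2.5) — an arrhythmic long beat;
* with probability `p_missed_peak` an interior R peak is deleted, merging
  two adjacent beats into one double-length interval — an R-peak detection
  artefact. Two consecutive deletions are disallowed so that a merged
  interval always spans exactly two underlying beats.

Because abnormal intervals are *longer* than normal ones, the fraction of
acquisition **time** they occupy exceeds their fraction of the beat
**count**; with 40% abnormal beats at scale 2.5, roughly 60–66% of the
time is rejected by STD-BR. This asymmetry is the mechanism behind the
worst-case subject reported in clinical cohorts (40% abnormal beats, two
thirds of the exam discarded) and is covered by property tests.

### The beating phantom

The LV is an ellipsoidal myocardial shell: a fixed outer (epicardial)
ellipsoid and an inner cavity ellipsoid with fixed axis ratio (default
long/short = 1.55), rescaled isotropically so the cavity volume tracks a
cyclic curve. The default phantom uses a 64³ grid of 2 mm voxels
(matching the ~2 mm reconstructed PET voxel of clinical protocols), EDV
160 mL and ESV 82 mL (typical means for a revascularisation-candidate
cohort), myocardial activity 1 and background 0.05 (high myocardial FDG
contrast under insulin clamping), and a 9 mm wall.

The volume curve is a **cosine systole + linear diastolic refill**: volume
falls from EDV to ESV as a half-cosine over the fixed systole duration
`t_sys_ms` (default 300 ms), then refills linearly to EDV at the next R
peak. The curve family is a modelling choice — only the constancy of
systole duration across cycle lengths is physiologically asserted, and the
code treats the family as pluggable. Phase 0 is anchored at the R peak,
so EDV is attained at the start of the cycle. One subtle consequence of
the linear refill: on a time-averaged 8-gate curve the *last* gate can sit
marginally above gate 0 (both adjacent to the R peak); ED detection simply
takes the curve maximum, so this has no downstream effect.

### Gated count images

`integrate_gated_counts()` integrates the phantom activity over every
time segment a gate owns, in quadrature steps of `dt_ms` (default 10 ms,
midpoint rule; per-gate totals change by <0.5% when the step is halved),
scales the grand total to `total_expected_counts`, and Poisson-samples
each voxel. Per-voxel shell-membership time is accumulated by rank
searching the sorted per-step cavity scales, which is exactly equivalent
to summing rendered frames over the steps (a unit test checks equality
against the brute-force summation) but fast enough to integrate a 42 min
acquisition in about a second. There is no attenuation, scatter, detector
blur or tomographic reconstruction — the images are idealised count maps,
so the study isolates *gating* effects from reconstruction effects.

### The reference modality

`reference_function_params()` emulates the volumetric reference (25-phase
CINE MR): it samples the *analytic* volume curve at 25 equispaced phases
and takes max/min. It is noise-free and segmentation-free. At the default
phantom this gives EDV = 160 mL exactly, ESV ≈ 82.9 mL, EF ≈ 48.2%
(against a true EF of 48.75%): even 25 phases slightly miss end systole.

## Function assessment

Gated images are divided by per-gate exposure (`normalize_by_exposure()`;
zero-exposure gates are marked missing, not zero), then delineated with an
uptake-threshold geometric model (`delineate_lv()`): radial rays are cast
perpendicular to the LV long axis at 20 stations between apex and base
plane, 36 angles per station, sampling the image by trilinear
interpolation every 0.5 mm. On each ray the endocardial edge is the
innermost crossing of `threshold_fraction` (default 0.5) times the ray's
maximum; cavity volume is the sum of circular sectors over stations,
clipped at the base plane. On noiseless frames this recovers the analytic
cavity volume to within ~2% (the 5% bound is tested), and doubling the
station/angle sampling changes the result by <2%. Raising the threshold
moves the edge deeper into the (hot) wall, so measured volume is
monotonically non-decreasing in the threshold — the direction follows
from cold-cavity/hot-myocardium geometry. In simulation the axis is taken
from the phantom geometry, playing the role of a perfect manual axis
definition.

`detect_ed_es()` takes the curve argmax/argmin (ties toward the lower
gate, missing gates skipped), and `function_params()` applies the EF
formula.

**Temporal undersampling.** Eight gates average the volume curve over
1/8-cycle windows, so gated EDV is biased down and gated ESV up —
EF₈ ≤ EF₂₅ on noiseless data. At the default phantom the effect is ≈ 4–5
EF points, dominated by the fast cosine systole inside gate 0's 120 ms
window. This is the direction and rough magnitude of the 8-gate
underestimation seen clinically, and it bounds how well any 8-gate method
can agree with a 25-phase reference.

## Agreement statistics

Four statistics compare each PET gating method against the reference, per
parameter (EDV, ESV, EF), across subjects:

* `pearson_r()` — product-moment correlation (via `stats::cor`).
* `deming_fit()` — errors-in-variables regression with closed-form
  estimate; `lambda_ratio` is var(y-errors)/var(x-errors), default 1
  (orthogonal). The λ → ∞ limit reproduces OLS of y on x, and the
  orthogonal fit obeys the swap symmetry slope′ = 1/slope; both are
  tested, plus equality with a perpendicular-distance grid search.
* `bland_altman_relative()` — relative differences
  d = 100·(ref − test)/denominator with the pairwise mean as default
  denominator (the reference-denominator variant is available since
  published tables rarely state the convention); bias = mean(d), limits of
  agreement = bias ± 1.96·sd(d). The sign convention makes PET
  *under*estimation a *positive* bias.
* `wilcoxon_signed_rank()` — paired two-sided test; zeros dropped, ties
  mid-ranked, exact convolution null for ≤ 15 non-zero pairs (exact even
  with ties), normal approximation with tie and continuity correction
  above. All-zero differences return p = 1 by convention.

## The cohort experiment

`run_experiment()` ties everything together: per subject it draws a mean
R-R (U(850, 1100) ms), an arrhythmia burden from a two-component mixture
(27% of subjects U(0.12, 0.4), the rest U(0, 0.05) — calibrated to
cohorts where about a quarter of subjects exceed 10% abnormal beats), an
EDV from U(100, 230) mL and an EF from U(25, 70)%; simulates a 42 min
acquisition; builds the three schedules; integrates counts with a budget
of `total_counts` (default 10⁶, desk scale) *scaled by the fraction of
acquisition time each schedule actually uses*, so beat rejection pays its
count-loss penalty; assesses function; and summarises agreement. Every
random draw derives from the single config seed, so runs are bit
reproducible. Subjects where a method fails (e.g. an acceptance window
rejecting every beat) are excluded from that method's summary with a
warning.

The cohort default grid is 48³ at 2.5 mm — coarser than the single-subject
default, chosen so a 30-subject, 3-method experiment completes in well
under a minute while leaving delineation error ≈ 2%.

Under this configuration STD shows the largest mean |EF bias| and the
widest EF limits of agreement of the three methods, and all methods
underestimate EF relative to the reference — the qualitative ranking
reported in patient studies. The acceptance suite asserts the ranking
over 10 replicate 10-subject cohorts at a heavy arrhythmia burden
(p = 0.3, scale 2.5).

## What the simulation does and does not show

The generator reproduces the *statistical structure* that makes gating
methods differ: beat-length irregularity with realistic mechanisms, a
fixed-duration systole, Poisson counting noise, exposure imbalance and
count loss. It does **not** reproduce attenuation/scatter physics,
reconstruction resolution effects, respiratory motion, papillary muscles,
inter-observer segmentation variability, or true inter-modality effects
(the reference here is the same phantom sampled densely, not an
independently segmented MR image). Consequently absolute agreement in
this package is *better* than clinical PET-vs-MR tables — limits of
agreement here reflect gating and noise alone — and passing tests
validate directions, mechanisms and orderings, not clinical effect sizes.

## Numerical choices and degenerate inputs

* Half-open segments `[start, end)`; boundary events belong to the later
  segment; gate indices are 0-based throughout.
* FW residual tails are discarded (full-width segments only) to preserve
  phase purity; whether a scanner gates rejected beats at all is
  undocumented, so FW extracts from **all** beats here (the window only
  defines the width), consistent with its robustness rationale.
* The acceptance window is closed: a beat exactly on a bound is accepted.
* `rr_ms ≤ t_sys_ms` compresses systole into the short beat (guarded
  degenerate case); delineation of a structureless image raises a
  catchable `petgate_delineation_failure`; an all-rejecting window raises
  `petgate_empty_schedule`.
* Poisson sampling and R-peak generation restore the caller's RNG state.
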