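# petgate

ECG cardiac gating methods for list-mode PET, and their effect on
left-ventricular function assessment, studied on a synthetic beating-heart
phantom.

## The problem

Retrospectively gated cardiac PET bins list-mode events into cardiac
phases using the R peaks detected by the scanner's ECG. From the gated
images, end-diastolic volume (EDV), end-systolic volume (ESV) and ejection
fraction

> EF = 100 · (EDV − ESV) / EDV

are measured. R-peak detection inside a PET/MR bore is noisy, and
arrhythmic or artefactually merged beats corrupt the phase definition —
how strongly depends on the gating scheme. `petgate` implements the three
schemes used on clinical consoles:

| Method | Definition |
|---|---|
| **STD** | every R-R interval divided into exactly *n* (default 8) equal gates |
| **STD-BR** | STD restricted to beats inside an R-R acceptance window (abnormal beats rejected, their time discarded) |
| **FW** | one fixed gate width = mean accepted R-R / *n*, applied from every R peak; up to *n* full-width gates per beat, residual tail unassigned |

and everything needed to compare them end to end without patient data: a
dynamic ellipsoidal-shell LV phantom with a fixed-duration systole,
Poisson-sampled gated count images, an uptake-threshold geometric LV
delineation with automatic ED/ES phase detection, a noise-free 25-phase
volumetric reference (CINE-MR-like), and the agreement statistics used in
method-comparison studies: Pearson correlation, Deming errors-in-variables
regression, relative Bland-Altman bias / limits of agreement, and the
exact paired Wilcoxon signed-rank test.

The package is aimed at researchers in quantitative cardiac PET who want
to study gating strategies, beat-rejection policies or gate counts under
controlled, repeatable conditions.

## Worked example

A six-minute exam with a heavy arrhythmia burden (30% of beats stretched
2.5×), gated three ways and compared with the 25-phase reference:

```r
library(petgate)

rpeaks <- simulate_rpeaks(duration_ms = 6 * 60 * 1000, mean_rr_ms = 960,
                          hrv_sd_ms = 40, p_arrhythmia = 0.3,
                          arrhythmia_scale = 2.5, seed = 42)
rpeaks
#> R-peak train: 247 peaks over 360.0 s (mean RR 1462 ms)
#>   intervals: arrhythmic_long=86, normal=160

window <- fit_acceptance_window(rr_intervals(rpeaks))
abnormal_stats(rpeaks, window)
#> $abnormal_beat_fraction
#> [1] 0.35
#> $rejected_time_fraction
#> [1] 0.573

phantom <- phantom_spec()      # 64^3 @ 2 mm, EDV 160 mL, ESV 82 mL
model   <- volume_model()      # cosine systole (300 ms) + linear refill
reference_function_params(phantom, model, rr_ms = 960)   # 25 phases
#> EDV 160.0 mL, ESV 82.9 mL, EF 48.2%

axis <- phantom_long_axis(phantom)
for (sch in list(schedule_std(rpeaks, 8),
                 schedule_std_br(rpeaks, window, 8),
                 schedule_fw(rpeaks, window, 8))) {
  gis <- integrate_gated_counts(rpeaks, sch, phantom, model,
                                total_expected_counts = 2e6, seed = 1)
  fp <- function_params(volume_curve(gis, axis))
  cat(sprintf("%-7s EDV %5.1f  ESV %5.1f  EF %4.1f%%\n",
              sch$method, fp$edv_ml, fp$esv_ml, fp$ef_pct))
}
#> STD     EDV 159.2  ESV  99.1  EF 37.8%
#> STD_BR  EDV 158.5  ESV  90.6  EF 42.8%
#> FW      EDV 155.8  ESV  89.8  EF 42.3%
```

Reading the numbers: 35% of the beats are abnormal but they carry 57% of
the acquisition time — long beats cost disproportionate time under beat
rejection. STD, which keeps those beats, smears dissimilar cardiac phases
into each gate: its ESV is inflated (99 vs 83 mL) and its EF depressed
(37.8 vs 48.2%). STD-BR and FW stay markedly closer to the reference, at
the price of discarded time (STD-BR) or unassigned beat tails (FW). The
residual ~5-point EF gap of all methods against the reference is the
8-gate temporal undersampling bias.

Whole-cohort experiments (30 subjects, three methods, agreement tables)
run through `experiment_config()` / `run_experiment()`, or from a shell
via `inst/scripts/run_experiment.R`.

## Package layout

* `R/rpeaks.R`, `R/phantom.R`, `R/gated_counts.R` — synthetic cohort:
  R-peak trains, beating LV phantom, gated Poisson count images (NIfTI +
  JSON sidecar IO).
* `R/gating.R` — acceptance windows, the STD / STD-BR / FW schedules,
  event-to-gate assignment, abnormal-beat statistics.
* `R/assessment.R` — exposure normalisation, uptake-threshold LV
  delineation, volume curves, ED/ES detection, EDV/ESV/EF.
* `R/agreement.R` — Pearson, Deming, relative Bland-Altman, exact
  Wilcoxon signed-rank.
* `R/experiment.R` — cohort simulation and method-vs-reference agreement
  tables.
* `vignettes/gating-methods.Rmd` — models, assumptions, design choices
  and limitations.
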