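#' Configuration of an in-silico gating-comparison experiment
#'
#' Bundles every parameter of the cohort simulation: per-subject R-peak
#' train statistics, phantom heterogeneity, counts budget, gating settings
#' and the multi-phase reference.  Subject-level arrhythmia burden is drawn
#' from a two-component mixture so that a minority of subjects carries a
#' heavy arrhythmia load while the rest are nearly regular, mirroring
#' cohorts where roughly a quarter of subjects show > 10% abnormal beats.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer master seed; every random draw derives from it.
#' @param duration_ms Acquisition length per subject (ms).
#' @param mean_rr_range_ms Uniform range for the subject mean R-R (ms).
#' @param hrv_sd_ms Normal-beat R-R standard deviation (ms).
#' @param p_arrhythmia_low_range,p_arrhythmia_high_range Uniform ranges of
#'   the per-beat arrhythmia probability in the low- and high-burden
#'   mixture components.
#' @param prop_high_arrhythmia Probability that a subject belongs to the
#'   high-burden component.
#' @param arrhythmia_scale Stretch factor of arrhythmic intervals.
#' @param p_missed_peak Per-peak missed-detection probability.
#' @param edv_range_ml,ef_range_pct Uniform ranges of subject EDV (mL) and
#'   EF (%); ESV is derived.
#' @param total_counts Expected total counts over the full acquisition; a
#'   schedule that uses only part of the acquisition collects
#'   proportionally fewer counts.
#' @param noiseless If `TRUE`, skip Poisson sampling.
#' @param n_gates Gates per beat / maximum gates (default 8).
#' @param window_halfwidth Relative half-width of the automatic acceptance
#'   window.
#' @param threshold_fraction Uptake threshold for LV delineation.
#' @param grid_shape,voxel_size_mm Phantom grid used for the cohort.
#' @param wall_thickness_mm Myocardial wall thickness (mm).
#' @param t_sys_ms Systole duration (ms).
#' @param dt_ms Quadrature step for count integration (ms).
#' @param n_phases_reference Phases of the noise-free reference modality.
#' @return An object of class `experiment_config` (a validated list).
#' @export
experiment_config <- function(n_subjects = 30, seed = 1,
                              duration_ms = 42 * 60 * 1000,
                              mean_rr_range_ms = c(850, 1100),
                              hrv_sd_ms = 40,
                              p_arrhythmia_low_range = c(0, 0.05),
                              p_arrhythmia_high_range = c(0.12, 0.4),
                              prop_high_arrhythmia = 0.27,
                              arrhythmia_scale = 2.5,
                              p_missed_peak = 0.01,
                              edv_range_ml = c(100, 230),
                              ef_range_pct = c(25, 70),
                              total_counts = 1e6,
                              noiseless = FALSE,
                              n_gates = 8,
                              window_halfwidth = 0.2,
                              threshold_fraction = 0.5,
                              grid_shape = c(48, 48, 48),
                              voxel_size_mm = c(2.5, 2.5, 2.5),
                              wall_thickness_mm = 9,
                              t_sys_ms = 300,
                              dt_ms = 10,
                              n_phases_reference = 25) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              duration_ms = duration_ms,
              mean_rr_range_ms = as.numeric(mean_rr_range_ms),
              hrv_sd_ms = hrv_sd_ms,
              p_arrhythmia_low_range = as.numeric(p_arrhythmia_low_range),
              p_arrhythmia_high_range = as.numeric(p_arrhythmia_high_range),
              prop_high_arrhythmia = prop_high_arrhythmia,
              arrhythmia_scale = arrhythmia_scale,
              p_missed_peak = p_missed_peak,
              edv_range_ml = as.numeric(edv_range_ml),
              ef_range_pct = as.numeric(ef_range_pct),
              total_counts = total_counts,
              noiseless = isTRUE(noiseless),
              n_gates = as.integer(n_gates),
              window_halfwidth = window_halfwidth,
              threshold_fraction = threshold_fraction,
              grid_shape = as.integer(if (length(grid_shape) == 1L)
                rep(grid_shape, 3) else grid_shape),
              voxel_size_mm = as.numeric(if (length(voxel_size_mm) == 1L)
                rep(voxel_size_mm, 3) else voxel_size_mm),
              wall_thickness_mm = wall_thickness_mm,
              t_sys_ms = t_sys_ms,
              dt_ms = dt_ms,
              n_phases_reference = as.integer(n_phases_reference))
  validate_experiment_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_experiment_config <- function(cfg) {
  check_scalar_number(cfg$n_subjects, "n_subjects", lower = 1)
  check_scalar_number(cfg$duration_ms, "duration_ms",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$total_counts, "total_counts",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$prop_high_arrhythmia, "prop_high_arrhythmia",
                      lower = 0, upper = 1)
  for (nm in c("mean_rr_range_ms", "p_arrhythmia_low_range",
               "p_arrhythmia_high_range", "edv_range_ml", "ef_range_pct")) {
    rng <- cfg[[nm]]
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] > rng[2])
      pg_stop("petgate_invalid_parameter",
              sprintf("`%s` must be a finite ordered range", nm))
  }
  invisible(cfg)
}

#' Read or write an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `read_experiment_config` returns an `experiment_config`;
#'   `write_experiment_config` invisibly returns `path`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}

#' Run the full in-silico gating-comparison experiment
#'
#' For every subject: simulate an R-peak train and an LV phantom, build the
#' STD, STD-BR and FW schedules, integrate gated counts once per schedule
#' (with a counts budget proportional to the schedule's used acquisition
#' time), assess EDV/ESV/EF with the uptake-threshold model, and compute
#' the noise-free multi-phase reference.  Then, per gating method and
#' parameter, compare against the reference with Pearson correlation,
#' Deming regression, relative Bland-Altman agreement and the paired
#' Wilcoxon signed-rank test.  Subject-level failures (e.g., an acceptance
#' window that rejects every beat) are recorded as missing with a warning
#' and excluded from the summaries.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-subject progress.
#' @return An object of class `petgate_experiment`: list with `cohort`
#'   (one row per subject x modality), `agreement` (one row per method x
#'   parameter) and `config`.  Deterministic given `config$seed`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_subjects

  subj <- with_rng_seed(config$seed, {
    high <- stats::runif(n) < config$prop_high_arrhythmia
    p_lo <- stats::runif(n, config$p_arrhythmia_low_range[1],
                         config$p_arrhythmia_low_range[2])
    p_hi <- stats::runif(n, config$p_arrhythmia_high_range[1],
                         config$p_arrhythmia_high_range[2])
    data.frame(
      subject = seq_len(n),
      mean_rr_ms = stats::runif(n, config$mean_rr_range_ms[1],
                                config$mean_rr_range_ms[2]),
      p_arrhythmia = ifelse(high, p_hi, p_lo),
      edv_ml = stats::runif(n, config$edv_range_ml[1], config$edv_range_ml[2]),
      ef_pct = stats::runif(n, config$ef_range_pct[1], config$ef_range_pct[2]))
  })

  methods <- c("STD", "STD_BR", "FW")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("subject %d/%d", i, n))
    rows[[i]] <- simulate_subject(subj[i, ], config)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  agreement <- list()
  params <- c("edv_ml", "esv_ml", "ef_pct")
  ref <- cohort[cohort$modality == "reference", ]
  for (m in methods) {
    mtab <- cohort[cohort$modality == m, ]
    ok <- !is.na(mtab$ef_pct)
    for (p in params) {
      x <- ref[[p]][ok]
      y <- mtab[[p]][ok]
      if (sum(ok) < 3L) next
      ba <- bland_altman_relative(x, y)
      dem <- deming_fit(x, y)
      agreement[[length(agreement) + 1L]] <- data.frame(
        method = m, parameter = sub("_ml$|_pct$", "", p),
        n_pairs = sum(ok),
        pearson_r = pearson_r(x, y),
        deming_slope = dem$slope,
        deming_intercept = dem$intercept,
        bias_pct = ba$bias_pct,
        loa_lower_pct = ba$loa_lower_pct,
        loa_upper_pct = ba$loa_upper_pct,
        loa_amplitude_pct = ba$loa_amplitude_pct,
        wilcoxon_p = wilcoxon_signed_rank(x, y))
    }
  }
  agreement <- do.call(rbind, agreement)

  structure(list(cohort = cohort, agreement = agreement, config = config),
            class = "petgate_experiment")
}

simulate_subject <- function(s, config) {
  esv <- s$edv_ml * (1 - s$ef_pct / 100)
  phantom <- phantom_spec(grid_shape = config$grid_shape,
                          voxel_size_mm = config$voxel_size_mm,
                          edv_ml = s$edv_ml, esv_ml = esv,
                          wall_thickness_mm = config$wall_thickness_mm,
                          t_sys_ms = config$t_sys_ms)
  model <- volume_model(t_sys_ms = config$t_sys_ms)
  seed_i <- derive_seed(config$seed, s$subject)

  rpeaks <- simulate_rpeaks(config$duration_ms, s$mean_rr_ms,
                            config$hrv_sd_ms, s$p_arrhythmia,
                            config$arrhythmia_scale, config$p_missed_peak,
                            seed = seed_i)
  rr <- rr_intervals(rpeaks)
  window <- fit_acceptance_window(rr, config$window_halfwidth)
  acc <- rr >= window$lower_ms & rr <= window$upper_ms
  astat <- abnormal_stats(rpeaks, window)
  span <- diff(range(rpeaks$timestamps_ms))
  axis <- phantom_long_axis(phantom)

  ref <- reference_function_params(phantom, model,
                                   rr_ms = if (any(acc)) mean(rr[acc])
                                           else mean(rr),
                                   n_phases = config$n_phases_reference)

  one_row <- function(modality, fp) {
    data.frame(subject = s$subject, modality = modality,
               edv_ml = if (is.null(fp)) NA_real_ else fp$edv_ml,
               esv_ml = if (is.null(fp)) NA_real_ else fp$esv_ml,
               ef_pct = if (is.null(fp)) NA_real_ else fp$ef_pct,
               abnormal_beat_fraction = astat$abnormal_beat_fraction,
               rejected_time_fraction = astat$rejected_time_fraction)
  }

  assess <- function(schedule, sub_seed) {
    counts <- config$total_counts * sum(gate_exposure(schedule)) / span
    gis <- integrate_gated_counts(rpeaks, schedule, phantom, model,
                                  total_expected_counts = counts,
                                  dt_ms = config$dt_ms,
                                  noiseless = config$noiseless,
                                  seed = sub_seed)
    vc <- volume_curve(gis, axis, config$threshold_fraction)
    function_params(vc)
  }

  try_method <- function(builder, k) {
    tryCatch(assess(builder(), derive_seed(seed_i, k)),
             petgate_error = function(e) {
               warning(sprintf("subject %d: %s", s$subject,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }

  fps <- list(
    STD = try_method(function() schedule_std(rpeaks, config$n_gates), 1L),
    STD_BR = try_method(function()
      schedule_std_br(rpeaks, window, config$n_gates), 2L),
    FW = try_method(function()
      schedule_fw(rpeaks, window, config$n_gates), 3L))

  rbind(one_row("reference", ref),
        one_row("STD", fps$STD),
        one_row("STD_BR", fps$STD_BR),
        one_row("FW", fps$FW))
}

#' Count subjects whose abnormal-beat burden exceeds a threshold
#'
#' @param cohort_table The `cohort` data frame of a [run_experiment()]
#'   result (or the result itself).
#' @param threshold_fraction Abnormal-beat fraction cut-off (default 0.1).
#' @return Integer count of subjects with
#'   `abnormal_beat_fraction > threshold_fraction`.
#' @export
summarize_abnormal <- function(cohort_table, threshold_fraction = 0.1) {
  if (inherits(cohort_table, "petgate_experiment"))
    cohort_table <- cohort_table$cohort
  check_scalar_number(threshold_fraction, "threshold_fraction", lower = 0)
  per_subject <- tapply(cohort_table$abnormal_beat_fraction,
                        cohort_table$subject, function(v) v[1])
  sum(per_subject > threshold_fraction)
}

#' @export
print.petgate_experiment <- function(x, ...) {
  cat(sprintf("Gating experiment: %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  cat(sprintf("  subjects with > 10%% abnormal beats: %d\n",
              summarize_abnormal(x)))
  print(x$agreement[, c("method", "parameter", "pearson_r", "deming_slope",
                        "bias_pct", "loa_amplitude_pct", "wilcoxon_p")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
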