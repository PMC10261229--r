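#' Acceptance window on R-R interval durations
#'
#' Beats whose R-R interval falls inside `[lower_ms, upper_ms]` are
#' considered normal; beats outside are treated as abnormal (arrhythmia or
#' R-peak detection artefact) and rejected by beat-rejection gating.
#'
#' @param lower_ms,upper_ms Window bounds in ms, `0 < lower < upper`.
#' @return An object of class `acceptance_window`.
#' @export
acceptance_window <- function(lower_ms, upper_ms) {
  check_scalar_number(lower_ms, "lower_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(upper_ms, "upper_ms", lower = 0, strict_lower = TRUE)
  if (lower_ms >= upper_ms)
    pg_stop("petgate_invalid_parameter", "lower_ms must be < upper_ms")
  structure(list(lower_ms = lower_ms, upper_ms = upper_ms),
            class = "acceptance_window")
}

#' Fit an acceptance window from the R-R distribution
#'
#' Automated surrogate for the manual per-patient window definition used on
#' clinical consoles: the window is centred on the median R-R interval with
#' a relative half-width, `[median * (1 - f), median * (1 + f)]`.  The
#' median is robust to a minority of long arrhythmic intervals, but the
#' surrogate fails on strongly bimodal R-R distributions (both modes may
#' fall outside the window); supply an explicit [acceptance_window()] in
#' that case.
#'
#' @param rr_list Numeric vector of R-R interval durations (ms).
#' @param relative_halfwidth Fractional half-width `f`, `0 < f < 1`;
#'   default 0.2.
#' @return An [acceptance_window()].
#' @export
fit_acceptance_window <- function(rr_list, relative_halfwidth = 0.2) {
  if (length(rr_list) == 0L)
    pg_stop("petgate_insufficient_data", "rr_list is empty")
  check_scalar_number(relative_halfwidth, "relative_halfwidth",
                      lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  m <- stats::median(rr_list)
  acceptance_window(m * (1 - relative_halfwidth),
                    m * (1 + relative_halfwidth))
}

new_gate_schedule <- function(method, n_gates, segments, timestamps_ms,
                              gate_width_ms = NA_real_) {
  o <- order(segments$t_start_ms)
  structure(list(method = method, n_gates = as.integer(n_gates),
                 segments = segments[o, , drop = FALSE],
                 gate_width_ms = gate_width_ms,
                 timestamps_ms = timestamps_ms),
            class = "gate_schedule")
}

#' @export
print.gate_schedule <- function(x, ...) {
  cat(sprintf("%s gate schedule: %d gates, %d segments over %d beats",
              x$method, x$n_gates, nrow(x$segments),
              length(unique(x$segments$beat_index))))
  if (is.finite(x$gate_width_ms))
    cat(sprintf(", gate width %.1f ms", x$gate_width_ms))
  cat("\n")
  invisible(x)
}

#' Standard gating: fixed number of gates per beat
#'
#' Divides every R-R interval into exactly `n_gates` contiguous equal-width
#' gates, so gate width varies from beat to beat.  Segments are half-open
#' `[t_start, t_end)` absolute time intervals; gate indices are 0-based.
#'
#' @param rpeaks An `rpeak_train` or numeric timestamp vector.
#' @param n_gates Number of gates per beat (default 8).
#' @return A `gate_schedule` with one segment per (beat, gate).
#' @export
schedule_std <- function(rpeaks, n_gates = 8) {
  ts <- rpeak_timestamps(rpeaks)
  if (length(ts) < 2L)
    pg_stop("petgate_insufficient_data", "need at least two R peaks")
  check_scalar_number(n_gates, "n_gates", lower = 1)
  n_gates <- as.integer(n_gates)
  nb <- length(ts) - 1L
  rr <- diff(ts)
  beat <- rep(seq_len(nb), each = n_gates)
  gate <- rep(seq_len(n_gates) - 1L, times = nb)
  start <- ts[beat] + gate * rr[beat] / n_gates
  end <- ts[beat] + (gate + 1L) * rr[beat] / n_gates
  end[gate == n_gates - 1L] <- ts[beat[gate == n_gates - 1L] + 1L]
  segs <- data.frame(beat_index = beat, gate_index = gate,
                     t_start_ms = start, t_end_ms = end)
  new_gate_schedule("STD", n_gates, segs, ts)
}

#' Beat-rejection gating: standard gating on accepted beats only
#'
#' Identical to [schedule_std()] but beats whose R-R interval lies outside
#' the acceptance window contribute no segments at all: their acquisition
#' time is discarded.
#'
#' @inheritParams schedule_std
#' @param window An [acceptance_window()].
#' @return A `gate_schedule`; raises a catchable
#'   `petgate_empty_schedule` error if every beat is rejected.
#' @export
schedule_std_br <- function(rpeaks, window, n_gates = 8) {
  stopifnot(inherits(window, "acceptance_window"))
  std <- schedule_std(rpeaks, n_gates)
  ts <- std$timestamps_ms
  rr <- diff(ts)
  ok_beat <- rr >= window$lower_ms & rr <= window$upper_ms
  if (!any(ok_beat))
    pg_stop("petgate_empty_schedule",
            "acceptance window rejects every beat")
  segs <- std$segments[ok_beat[std$segments$beat_index], , drop = FALSE]
  rownames(segs) <- NULL
  new_gate_schedule("STD_BR", n_gates, segs, ts)
}

#' Fixed-width gating: a single gate duration for the whole acquisition
#'
#' The gate width is defined as `1/n_gates` of the mean R-R interval after
#' abnormal-beat rejection.  From every beat (accepted or not) up to
#' `n_gates` full-width segments are extracted starting at the R peak;
#' residual time at the end of the beat is left unassigned.  Early cardiac
#' phases are thereby preserved even on long arrhythmic beats, exploiting
#' the constancy of the systolic phase.
#'
#' @inheritParams schedule_std_br
#' @return A `gate_schedule` with `gate_width_ms` set.
#' @export
schedule_fw <- function(rpeaks, window, n_gates = 8) {
  stopifnot(inherits(window, "acceptance_window"))
  ts <- rpeak_timestamps(rpeaks)
  if (length(ts) < 2L)
    pg_stop("petgate_insufficient_data", "need at least two R peaks")
  check_scalar_number(n_gates, "n_gates", lower = 1)
  n_gates <- as.integer(n_gates)
  rr <- diff(ts)
  acc <- rr >= window$lower_ms & rr <= window$upper_ms
  if (!any(acc))
    pg_stop("petgate_empty_schedule",
            "no accepted beats to define the fixed gate width")
  width <- mean(rr[acc]) / n_gates
  n_seg <- pmin(n_gates, floor(rr / width + 1e-9))
  beat <- rep.int(seq_along(rr), n_seg)
  gate <- sequence(n_seg) - 1L
  start <- ts[beat] + gate * width
  segs <- data.frame(beat_index = beat, gate_index = gate,
                     t_start_ms = start, t_end_ms = start + width)
  new_gate_schedule("FW", n_gates, segs, ts, gate_width_ms = width)
}

#' Per-gate accumulated exposure
#'
#' @param schedule A `gate_schedule`.
#' @return Numeric vector of length `n_gates`: total acquisition time (ms)
#'   assigned to each gate (0-based gate order).
#' @export
gate_exposure <- function(schedule) {
  stopifnot(inherits(schedule, "gate_schedule"))
  segs <- schedule$segments
  dur <- segs$t_end_ms - segs$t_start_ms
  as.numeric(tapply(dur, factor(segs$gate_index,
                                levels = 0:(schedule$n_gates - 1L)),
                    sum, default = 0))
}

#' Assign event timestamps to gates
#'
#' Binary search over the schedule's half-open segments: an event at a
#' segment boundary belongs to the later segment.  Events falling in
#' rejected beats, fixed-width residual tails, or outside the schedule
#' altogether are unassigned.
#'
#' @param t_ms Numeric vector of list-mode event times (ms).
#' @param schedule A `gate_schedule`.
#' @return Integer vector of 0-based gate indices, `NA` where unassigned.
#' @export
assign_event <- function(t_ms, schedule) {
  stopifnot(inherits(schedule, "gate_schedule"))
  segs <- schedule$segments
  idx <- findInterval(t_ms, segs$t_start_ms)
  gate <- rep(NA_integer_, length(t_ms))
  hit <- idx >= 1L
  hit[hit] <- t_ms[hit] < segs$t_end_ms[idx[hit]]
  gate[hit] <- as.integer(segs$gate_index[idx[hit]])
  gate
}

#' Abnormal-beat and rejected-time fractions
#'
#' @param rpeaks An `rpeak_train` or timestamp vector.
#' @param window An [acceptance_window()].
#' @return A list with `abnormal_beat_fraction` (share of R-R intervals
#'   outside the window) and `rejected_time_fraction` (share of total R-R
#'   time carried by those intervals).  Because abnormal intervals are
#'   typically long, the time fraction exceeds the beat fraction.
#' @export
abnormal_stats <- function(rpeaks, window) {
  stopifnot(inherits(window, "acceptance_window"))
  rr <- rr_intervals(rpeaks)
  abn <- rr < window$lower_ms | rr > window$upper_ms
  list(abnormal_beat_fraction = mean(abn),
       rejected_time_fraction = sum(rr[abn]) / sum(rr))
}
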