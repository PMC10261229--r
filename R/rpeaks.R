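#' Simulate an R-peak timestamp train
#'
#' Generates the train of ECG R-peak detection times that drives list-mode
#' cardiac gating.  Normal R-R intervals are drawn from a truncated normal
#' distribution; with probability `p_arrhythmia` an interval is stretched by
#' `arrhythmia_scale` (an arrhythmic long beat); with probability
#' `p_missed_peak` an R peak is dropped, so that two consecutive intervals
#' merge into one long interval, emulating R-peak detection artefacts on
#' PET/MR systems.
#'
#' @param duration_ms Total acquisition length in milliseconds.
#' @param mean_rr_ms Mean normal R-R interval (ms).
#' @param hrv_sd_ms Standard deviation of normal R-R intervals (ms).
#' @param p_arrhythmia Per-beat probability of an arrhythmic long interval.
#' @param arrhythmia_scale Multiplicative stretch applied to arrhythmic
#'   intervals; must exceed 1.
#' @param p_missed_peak Per-peak probability that an interior R peak is
#'   missed, merging its two adjacent intervals.  A peak immediately
#'   following a missed one is never dropped as well, so merged intervals
#'   span exactly two underlying beats.
#' @param seed Optional integer seed; the train is reproducible given the
#'   seed and the caller's RNG stream is left untouched.
#' @param rr_floor_ms Lower truncation for drawn intervals (ms); defaults to
#'   40% of `mean_rr_ms`.
#'
#' @return An object of class `rpeak_train`: a list with `timestamps_ms`
#'   (strictly increasing, starting at 0), `labels` (one per R-R interval:
#'   `"normal"`, `"arrhythmic_long"` or `"merged_missed_peak"`) and
#'   `duration_ms`.
#' @export
simulate_rpeaks <- function(duration_ms, mean_rr_ms = 960, hrv_sd_ms = 40,
                            p_arrhythmia = 0, arrhythmia_scale = 2.5,
                            p_missed_peak = 0, seed = NULL,
                            rr_floor_ms = 0.4 * mean_rr_ms) {
  check_scalar_number(duration_ms, "duration_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(mean_rr_ms, "mean_rr_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(hrv_sd_ms, "hrv_sd_ms", lower = 0)
  check_scalar_number(p_arrhythmia, "p_arrhythmia", lower = 0, upper = 1)
  check_scalar_number(p_missed_peak, "p_missed_peak", lower = 0, upper = 1)
  check_scalar_number(arrhythmia_scale, "arrhythmia_scale",
                      lower = 1, strict_lower = TRUE)
  check_scalar_number(rr_floor_ms, "rr_floor_ms", lower = 0)

  with_rng_seed(seed, {
    n_guess <- ceiling(duration_ms / mean_rr_ms) + 10L
    rr <- numeric(0)
    lab <- character(0)
    total <- 0
    while (total < duration_ms) {
      d <- stats::rnorm(n_guess, mean_rr_ms, hrv_sd_ms)
      d <- pmax(d, rr_floor_ms)
      arr <- stats::runif(n_guess) < p_arrhythmia
      d[arr] <- d[arr] * arrhythmia_scale
      rr <- c(rr, d)
      lab <- c(lab, ifelse(arr, "arrhythmic_long", "normal"))
      total <- sum(rr)
    }
    ts <- c(0, cumsum(rr))
    keep <- ts <= duration_ms
    ts <- ts[keep]
    lab <- lab[seq_len(max(length(ts) - 1L, 0L))]

    # Missed-peak artefact: drop interior peaks; never two in a row, so a
    # merged interval always spans exactly two underlying beats.
    if (p_missed_peak > 0 && length(ts) >= 3L) {
      drop <- rep(FALSE, length(ts))
      u <- stats::runif(length(ts))
      i <- 2L
      while (i <= length(ts) - 1L) {
        if (u[i] < p_missed_peak) {
          drop[i] <- TRUE
          i <- i + 2L
        } else {
          i <- i + 1L
        }
      }
      if (any(drop)) {
        new_lab <- character(0)
        j <- 1L
        while (j <= length(lab)) {
          # interval j ends at peak j+1; if that peak is dropped, intervals
          # j and j+1 merge
          if (j + 1L <= length(ts) && drop[j + 1L]) {
            new_lab <- c(new_lab, "merged_missed_peak")
            j <- j + 2L
          } else {
            new_lab <- c(new_lab, lab[j])
            j <- j + 1L
          }
        }
        ts <- ts[!drop]
        lab <- new_lab
      }
    }

    structure(list(timestamps_ms = ts, labels = lab,
                   duration_ms = duration_ms),
              class = "rpeak_train")
  })
}

#' R-R intervals of an R-peak train
#'
#' @param rpeaks An `rpeak_train` object or a numeric vector of strictly
#'   increasing R-peak timestamps (ms).
#' @return Numeric vector of consecutive R-R interval durations (ms), in
#'   acquisition order.
#' @export
rr_intervals <- function(rpeaks) {
  ts <- rpeak_timestamps(rpeaks)
  if (length(ts) < 2L)
    pg_stop("petgate_insufficient_data",
            "at least two R-peak timestamps are required")
  diff(ts)
}

rpeak_timestamps <- function(rpeaks) {
  if (inherits(rpeaks, "rpeak_train")) return(rpeaks$timestamps_ms)
  if (is.numeric(rpeaks)) {
    if (is.unsorted(rpeaks, strictly = TRUE))
      pg_stop("petgate_invalid_parameter",
              "R-peak timestamps must be strictly increasing")
    return(as.numeric(rpeaks))
  }
  pg_stop("petgate_invalid_parameter",
          "`rpeaks` must be an rpeak_train or a numeric timestamp vector")
}

#' @export
print.rpeak_train <- function(x, ...) {
  rr <- diff(x$timestamps_ms)
  cat(sprintf("R-peak train: %d peaks over %.1f s (mean RR %.0f ms)\n",
              length(x$timestamps_ms), x$duration_ms / 1000,
              if (length(rr)) mean(rr) else NA_real_))
  if (length(x$labels)) {
    tab <- table(x$labels)
    cat("  intervals:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read or write an R-peak train as CSV
#'
#' The on-disk format has one row per R peak with columns `timestamp_ms`
#' and `label`, where `label` is the class of the R-R interval that starts
#' at that peak (empty for the final peak).
#'
#' @param rpeaks An `rpeak_train`.
#' @param path File path.
#' @param duration_ms Total acquisition length when reading; defaults to
#'   the last timestamp.
#' @return `read_rpeaks` returns an `rpeak_train`; `write_rpeaks`
#'   invisibly returns `path`.
#' @export
write_rpeaks <- function(rpeaks, path) {
  stopifnot(inherits(rpeaks, "rpeak_train"))
  df <- data.frame(timestamp_ms = rpeaks$timestamps_ms,
                   label = c(rpeaks$labels, ""))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpeaks
#' @export
read_rpeaks <- function(path, duration_ms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp_ms", "label") %in% names(df)))
    pg_stop("petgate_invalid_parameter",
            "R-peak CSV must have columns timestamp_ms and label")
  ts <- as.numeric(df$timestamp_ms)
  if (is.unsorted(ts, strictly = TRUE))
    pg_stop("petgate_invalid_parameter",
            "timestamps in R-peak CSV must be strictly increasing")
  lab <- as.character(df$label[-length(ts)])
  structure(list(timestamps_ms = ts, labels = lab,
                 duration_ms = if (is.null(duration_ms)) ts[length(ts)]
                               else duration_ms),
            class = "rpeak_train")
}
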