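test_that("acceptance window from the median ignores a single long outlier", {
  win <- fit_acceptance_window(c(rep(800, 9), 1600), 0.2)
  expect_equal(win$lower_ms, 640)
  expect_equal(win$upper_ms, 960)
  # the outlier is excluded, the normal beats accepted
  expect_true(1600 > win$upper_ms)
  expect_true(all(rep(800, 9) >= win$lower_ms & rep(800, 9) <= win$upper_ms))
})

test_that("all equal intervals are all accepted", {
  win <- fit_acceptance_window(rep(900, 20), 0.2)
  expect_true(900 >= win$lower_ms && 900 <= win$upper_ms)
})

test_that("the median surrogate fails on a balanced bimodal distribution", {
  # the window centres between the modes, where no beat lives
  win <- fit_acceptance_window(c(rep(800, 5), rep(1200, 5)), 0.2)
  expect_equal((win$lower_ms + win$upper_ms) / 2, 1000)
  # modes separated by more than the window width are both rejected
  rrs <- c(rep(750, 5), rep(1250, 5))
  win2 <- fit_acceptance_window(rrs, 0.2)
  expect_true(all(rrs < win2$lower_ms | rrs > win2$upper_ms))
})

test_that("window constructor and fitter reject invalid input", {
  expect_error(fit_acceptance_window(numeric(0)),
               class = "petgate_insufficient_data")
  expect_error(acceptance_window(900, 700),
               class = "petgate_invalid_parameter")
  expect_error(fit_acceptance_window(c(800, 900), 1.5),
               class = "petgate_invalid_parameter")
})

test_that("STD divides one beat into equal half-open gates", {
  sch <- schedule_std(c(0, 800), n_gates = 8)
  segs <- sch$segments
  expect_equal(nrow(segs), 8)
  expect_equal(segs$t_end_ms - segs$t_start_ms, rep(100, 8))
  expect_equal(segs$t_start_ms[1], 0)
  expect_equal(segs$t_end_ms[1], 100)
  expect_equal(segs$gate_index, 0:7)
})

test_that("STD exposure accumulates across beats and mixes dissimilar cycles", {
  expect_equal(gate_exposure(schedule_std(c(0, 800, 1600), 8)), rep(200, 8))
  # irregular beats: gate 0 holds 100 ms of the short and 200 ms of the
  # long cycle, i.e. dissimilar cardiac phases
  expo <- gate_exposure(schedule_std(c(0, 800, 2400), 8))
  expect_equal(expo[1], 300)
  expect_equal(sum(expo), 2400)
})

test_that("STD schedules tile each beat exactly", {
  for (seed in 1:5) {
    rp <- simulate_rpeaks(3 * 60 * 1000, 900, 80, 0.3, 2.2, 0.1, seed = seed)
    sch <- schedule_std(rp, 8)
    rr <- rr_intervals(rp)
    width_by_beat <- tapply(sch$segments$t_end_ms - sch$segments$t_start_ms,
                            sch$segments$beat_index, sum)
    expect_equal(as.numeric(width_by_beat), rr)
    # segments within each beat are contiguous and ordered
    segs <- sch$segments[order(sch$segments$beat_index,
                               sch$segments$gate_index), ]
    by_beat <- split(segs, segs$beat_index)
    for (b in by_beat)
      expect_equal(b$t_start_ms[-1], b$t_end_ms[-nrow(b)])
  }
})

test_that("beat rejection drops abnormal beats and only those", {
  win <- acceptance_window(640, 960)
  sch <- schedule_std_br(c(0, 800, 2400), win, 8)
  expect_equal(unique(sch$segments$beat_index), 1L)
  expect_equal(sum(sch$segments$t_end_ms - sch$segments$t_start_ms), 800)
  # a window covering everything reproduces plain STD
  all_win <- acceptance_window(1, 1e6)
  expect_equal(schedule_std_br(c(0, 800, 2400), all_win, 8)$segments,
               schedule_std(c(0, 800, 2400), 8)$segments)
  expect_error(schedule_std_br(c(0, 800, 2400), acceptance_window(1, 2), 8),
               class = "petgate_empty_schedule")
})

test_that("with 40% long beats the scheduled time fraction drops below 60%", {
  rp <- simulate_rpeaks(20 * 60 * 1000, 960, 30, p_arrhythmia = 0.4,
                        arrhythmia_scale = 2.5, seed = 8)
  rr <- rr_intervals(rp)
  win <- fit_acceptance_window(rr, 0.2)
  sch <- schedule_std_br(rp, win, 8)
  kept <- sum(gate_exposure(sch)) / sum(rr)
  expect_lt(kept, 0.6)
})

test_that("FW gate width is 1/8 of the mean accepted R-R interval", {
  rp <- regular_train(100, rr_ms = 960)
  win <- fit_acceptance_window(rr_intervals(rp), 0.2)
  sch <- schedule_fw(rp, win, 8)
  expect_identical(sch$gate_width_ms, 120)
})

test_that("FW extracts full-width segments, capped at n_gates", {
  # 10 accepted 960 ms beats fix the width at 120 ms; then a short and a
  # very long beat are appended outside the window
  ts <- c((0:10) * 960, 10 * 960 + 700, 10 * 960 + 700 + 2000)
  win <- acceptance_window(864, 1056)
  sch <- schedule_fw(ts, win, 8)
  segs <- sch$segments
  expect_equal(sch$gate_width_ms, 120)
  expect_true(all(abs(segs$t_end_ms - segs$t_start_ms - 120) < 1e-9))
  short <- segs[segs$beat_index == 11, ]
  expect_equal(nrow(short), 5)   # floor(700 / 120)
  expect_equal(short$gate_index, 0:4)
  long <- segs[segs$beat_index == 12, ]
  expect_equal(nrow(long), 8)    # capped at n_gates despite floor(2000/120)=16
  expect_equal(max(long$t_end_ms) - min(long$t_start_ms), 960)
})

test_that("FW exposure fills early gates first and never exceeds the span", {
  ts <- c((0:10) * 960, 10 * 960 + 700)
  win <- acceptance_window(864, 1056)
  expo <- gate_exposure(schedule_fw(ts, win, 8))
  expect_equal(expo, 10 * 120 + c(rep(120, 5), 0, 0, 0))
  expect_lte(sum(expo), max(ts) - min(ts))
  expect_error(schedule_fw(ts, acceptance_window(1, 2), 8),
               class = "petgate_empty_schedule")
})

test_that("regular trains make the three gating methods coincide", {
  rp <- regular_train(50, rr_ms = 960)
  win <- fit_acceptance_window(rr_intervals(rp), 0.2)
  s_std <- schedule_std(rp, 8)
  s_br <- schedule_std_br(rp, win, 8)
  s_fw <- schedule_fw(rp, win, 8)
  expect_equal(s_br$segments, s_std$segments)
  expect_equal(s_fw$segments[, c("beat_index", "gate_index")],
               s_std$segments[, c("beat_index", "gate_index")])
  expect_equal(s_fw$segments$t_start_ms, s_std$segments$t_start_ms)
  expect_equal(s_fw$segments$t_end_ms, s_std$segments$t_end_ms)
})

test_that("events map to gates by half-open membership", {
  sch <- schedule_std(c(0, 800), 8)
  expect_identical(assign_event(150, sch), 1L)   # 150 in [100, 200)
  expect_identical(assign_event(100, sch), 1L)   # boundary -> later segment
  expect_identical(assign_event(c(0, 799.9), sch), c(0L, 7L))
  ts <- c((0:10) * 960, 10 * 960 + 700)
  win <- acceptance_window(864, 1056)
  fw <- schedule_fw(ts, win, 8)
  expect_identical(assign_event(10 * 960 + 650, fw), NA_integer_)  # tail
})

test_that("STD assignment partitions the acquisition", {
  rp <- simulate_rpeaks(60 * 1000, 900, 60, 0.2, 2, 0, seed = 4)
  sch <- schedule_std(rp, 8)
  span <- range(rp$timestamps_ms)
  t <- seq(span[1], span[2] - 0.01, length.out = 5000)
  expect_false(anyNA(assign_event(t, sch)))
})

test_that("uniform events land in gates proportionally to exposure", {
  set.seed(31)
  rp <- simulate_rpeaks(5 * 60 * 1000, 900, 70, 0.25, 2.5, 0.05, seed = 31)
  win <- fit_acceptance_window(rr_intervals(rp), 0.2)
  sch <- schedule_fw(rp, win, 8)
  span <- range(rp$timestamps_ms)
  n_ev <- 40000
  t <- runif(n_ev, span[1], span[2])
  g <- assign_event(t, sch)
  expo <- gate_exposure(sch)
  p <- expo / diff(span)
  obs <- tabulate(g + 1L, nbins = 8) / n_ev
  tol <- 4 * sqrt(p * (1 - p) / n_ev)
  expect_true(all(abs(obs - p) <= tol + 1e-12))
})

test_that("abnormal-beat statistics count beats and time separately", {
  win <- acceptance_window(640, 960)
  st <- abnormal_stats(c(0, 800, 1600, 3200), win)
  expect_equal(st$abnormal_beat_fraction, 1 / 3)
  expect_equal(st$rejected_time_fraction, 0.5)
  st0 <- abnormal_stats(c(0, 800, 1600), win)
  expect_equal(st0$abnormal_beat_fraction, 0)
  expect_equal(st0$rejected_time_fraction, 0)
})

test_that("uniformly longer abnormal beats inflate the time fraction", {
  set.seed(17)
  for (i in 1:20) {
    n_norm <- sample(5:20, 1)
    n_long <- sample(1:5, 1)
    rr <- sample(c(runif(n_norm, 700, 900), runif(n_long, 1500, 3000)))
    ts <- c(0, cumsum(rr))
    win <- acceptance_window(650, 1000)
    st <- abnormal_stats(ts, win)
    expect_gt(st$rejected_time_fraction, st$abnormal_beat_fraction)
  }
})
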