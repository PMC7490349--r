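test_that("constant R-R intervals map to constant bpm", {
  expect_equal(unique(round(instantaneous_rate(const_beats(0.8))$bpm, 9)), 75)
  expect_equal(unique(round(instantaneous_rate(const_beats(0.5))$bpm, 9)), 120)
  expect_error(instantaneous_rate(beat_series(c(0, 1))), "3 beats")
})

test_that("rate interpolation is linear between interval midpoints", {
  b <- beat_series(c(0, 1, 1.5))
  r <- instantaneous_rate(b, grid_rate = 1000)
  # midpoints (0.5, 60 bpm) and (1.25, 120 bpm); halfway -> 90 bpm
  expect_equal(stats::approx(r$time, r$bpm, xout = 0.875)$y, 90)
  expect_equal(r$time[1], 0.5)
  expect_equal(r$time[length(r$time)], 1.25)
})

test_that("rate is exact at midpoints and linear in between", {
  set.seed(4)
  for (i in 1:5) {
    # intervals on the 0.2 s lattice: midpoints land on the 10 Hz grid
    beats <- beat_series(cumsum(c(0, sample(c(0.6, 0.8, 1.0, 1.2), 40,
                                            replace = TRUE))))
    mids <- (beats$beat_times[-1] + beats$beat_times[-41]) / 2
    r <- instantaneous_rate(beats, grid_rate = 10)
    on_grid <- round(mids * 10) == mids * 10
    got <- r$bpm[match(round(mids[on_grid], 6), round(r$time, 6))]
    expect_equal(got, 60 / beats$rr[on_grid], tolerance = 1e-12)
    # every grid value lies on the hand-interpolated midpoint polyline
    oracle <- stats::approx(mids, 60 / beats$rr, xout = r$time)$y
    expect_equal(r$bpm, oracle, tolerance = 1e-12)
  }
})

test_that("artifact screening flags out-of-range and jumpy intervals", {
  clean <- const_beats(0.8, 80)
  expect_equal(attr(reject_artifacts(clean), "artifacts")$n_flagged, 0)
  times <- cumsum(c(0, rep(0.8, 40)))
  times <- sort(c(times, times[20] + 0.1))  # one 0.1 s interval inserted
  flagged <- attr(reject_artifacts(beat_series(times)), "artifacts")$flag
  expect_gte(sum(flagged), 1)
  expect_true(flagged[which.min(diff(times))])
  # alternating 0.4/1.2: every interval deviates >25% from the local median
  alt <- beat_series(cumsum(c(0, rep(c(0.4, 1.2), 30))))
  expect_warning(reject_artifacts(alt, reject_frac = 1), "flagged")
  expect_error(reject_artifacts(alt), "rejected")
})

test_that("flagged intervals are bridged over in the rate curve", {
  times <- cumsum(c(0, rep(0.8, 30)))
  times <- sort(c(times, times[15] + 0.05))
  b <- reject_artifacts(beat_series(times))
  r <- instantaneous_rate(b, 10)
  expect_true(all(abs(r$bpm - 75) < 16))  # 0.05 s interval would be 1200 bpm
})

test_that("epochs are baseline-referenced under both policies", {
  ev <- tiny_events(c(12, 25))
  flat <- rate_series_from(function(t) rep(75, length(t)))
  ep <- epoch_cardiac(flat, ev, participant = "P1")
  expect_true(all(ep$epochs == 0))
  expect_equal(dim(ep$epochs), c(2, 100))
  step <- rate_series_from(function(t) {
    75 - 2 * ((t - 12) >= 2 & (t - 12) < 5 | (t - 25) >= 2 & (t - 25) < 5)
  })
  ep2 <- epoch_cardiac(step, ev)
  rel <- ep2$time
  expect_equal(unique(ep2$epochs[1, rel >= 2 & rel < 5]), -2)
  expect_equal(unique(ep2$epochs[1, rel < 2 | rel >= 5]), 0)
  # prewindow policy: reference = mean of r over onset + [-1, 0), so for a
  # linear rate the epoch is 0.5 * tau + 0.5 * 0.55 (mean lag of the grid)
  slope <- rate_series_from(function(t) 60 + 0.5 * t)
  ep3 <- epoch_cardiac(slope, ev, baseline_policy = "prewindow")
  expect_equal(ep3$epochs[1, ] - 0.5 * ep3$time,
               rep(0.5 * 0.55, ncol(ep3$epochs)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("events outside the rate support are rejected, all-out errors", {
  ev <- tiny_events(c(2, 12))  # first epoch starts before the support
  r <- rate_series_from(function(t) rep(70, length(t)), from = 5, to = 30)
  ep <- epoch_cardiac(r, ev)
  expect_equal(ep$items$rejected, c(TRUE, FALSE))
  ev_out <- tiny_events(c(100, 150))
  expect_error(epoch_cardiac(r, ev_out), "all items rejected")
})

test_that("evoked averaging is idempotent and cancels opposites", {
  ev <- tiny_events(c(12, 25))
  flat <- rate_series_from(function(t) rep(75, length(t)))
  ep <- epoch_cardiac(flat, ev, participant = "P1")
  ep$epochs[1, ] <- 1
  ep$epochs[2, ] <- 1
  avg <- average_evoked(ep, by = "emotion")
  expect_true(all(avg$cells$neutral == 1))
  ep$epochs[2, ] <- -1
  avg2 <- average_evoked(ep, by = "emotion")
  expect_true(all(avg2$cells$neutral == 0))
  # rejected items never enter the mean
  ep$items$rejected[2] <- TRUE
  avg3 <- average_evoked(ep, by = "emotion")
  expect_true(all(avg3$cells$neutral == 1))
})

test_that("peak deflection reports extremum with earliest-tie rule", {
  tt <- seq(0, 9.9, by = 0.1)
  curve <- -sin(pi * tt / 10)
  pk <- peak_deflection(curve, tt)
  expect_equal(pk$amplitude, -1)
  expect_equal(pk$latency, 5)
  flat <- rep(0, length(tt))
  pk0 <- peak_deflection(flat, tt, window = c(1, 8))
  expect_equal(pk0$amplitude, 0)
  expect_equal(pk0$latency, 1)
  two <- rep(0, length(tt)); two[tt %in% c(3, 7)] <- -2
  expect_equal(peak_deflection(two, tt)$latency, 3)
})

test_that("the published deceleration kernel is recovered end to end", {
  ev <- schedule_events("pre", n_items = 12,
                        emotions = c("disgust", "neutral"),
                        conditions = "baseline")
  p <- cardiac_sim_params(noise_sd = 0, rsa_amp = 0, session_drift_bpm = 0)
  ce <- participant_evoked(ev, p, baseline_bpm = 78, seed = 8,
                           participant = "P1")
  avg <- average_evoked(ce, by = "emotion")
  pk <- peak_deflection(avg$grand$disgust, avg$time)
  expect_lt(abs(pk$amplitude - (-2.34)), 0.15)
  expect_lt(abs(pk$latency - 3.48), 0.25)
})

test_that("tidy long export matches the cell matrices", {
  ev <- tiny_events(c(12, 25))
  flat <- rate_series_from(function(t) rep(75, length(t)))
  eps <- lapply(c("P1", "P2"), function(id)
    epoch_cardiac(flat, ev, participant = id))
  avg <- average_evoked(eps, by = "emotion")
  long <- evoked_long(avg)
  expect_equal(nrow(long), 2 * length(avg$time))
  expect_setequal(unique(long$participant), c("P1", "P2"))
})
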