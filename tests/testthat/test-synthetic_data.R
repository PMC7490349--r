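test_that("constant-rate limit of the integrate-and-fire generator", {
  ev <- tiny_events(30)
  p <- quiet_cardiac(amplitude = 0)
  b60 <- simulate_beats(ev, p, baseline_bpm = 60, span = 60)
  expect_true(abs(length(b60$beat_times) - 60) <= 1)
  expect_equal(unique(round(b60$rr, 9)), 1.0)
  b120 <- simulate_beats(ev, p, baseline_bpm = 120, span = 60)
  expect_equal(unique(round(b120$rr, 9)), 0.5)
})

test_that("beat count matches the integrated intensity for piecewise rates", {
  ev <- tiny_events(c(20, 40, 60))
  p <- quiet_cardiac(amplitude = -8, latency = 3, width = 1.5)
  for (bpm in c(55, 72, 95)) {
    b <- simulate_beats(ev, p, baseline_bpm = bpm, span = 80)
    r <- attr(b, "rate")
    dt <- r$time[2] - r$time[1]
    expected <- sum((r$bpm[-1] + r$bpm[-length(r$bpm)]) / 2) * dt / 60
    expect_true(abs(length(b$beat_times) - expected) <= 1)
  }
})

test_that("a single kernel is recovered from the realized beats", {
  ev <- event_table(30, 10, "pre", "baseline", "neutral", "k1")
  p <- quiet_cardiac(amplitude = -10, latency = 3, width = 1.5)
  b <- simulate_beats(ev, p, baseline_bpm = 70, span = 60)
  # oracle: direct numerical evaluation of the generator's rate function
  oracle <- attr(b, "rate")
  i_true <- which.min(oracle$bpm)
  expect_equal(oracle$time[i_true] - 30, 3, tolerance = 0.02)
  expect_equal(min(oracle$bpm) - 70, -10, tolerance = 0.01)
  # recovery through the cardiac module
  r <- instantaneous_rate(b, 10)
  sel <- r$time > 30 & r$time < 40
  i <- which.min(r$bpm[sel])
  expect_lt(abs((r$time[sel][i] - 30) - 3), 0.25)
  expect_lt(abs((r$bpm[sel][i] - 70) - (-10)), 1)
})

test_that("non-positive rates are refused", {
  ev <- tiny_events(10)
  p <- quiet_cardiac(amplitude = -80, latency = 3)
  expect_error(simulate_beats(ev, p, baseline_bpm = 60, span = 30),
               "non-positive")
})

test_that("blocked and randomized schedules present the same items", {
  blocked <- schedule_events("pre", n_items = 4, design = "blocked")
  randomized <- schedule_events("pre", n_items = 4, design = "randomized",
                                seed = 9)
  expect_setequal(blocked$item_id, randomized$item_id)
  expect_equal(nrow(blocked), nrow(randomized))
  expect_false(identical(blocked$item_id, randomized$item_id))
  # identical cell composition, different presentation order
  count_cells <- function(ev) table(ev$condition, ev$emotion)
  expect_equal(count_cells(blocked), count_cells(randomized))
  # scenes last 10 s with a 500 ms gap within a sub-block
  gaps <- diff(blocked$onset)
  expect_true(all(abs(gaps - 10.5) < 1e-9 | gaps > 10.5))
})

test_that("cohort simulation is deterministic and complete on disk", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cardiac <- cardiac_sim_params(n_participants = 2, n_items = 3)
  eeg <- eeg_sim_params(n_channels = 4, rate = 100, window = c(-0.5, 1.0),
                        n_trials = 2)
  for (d in c(dir_a, dir_b)) {
    simulate_cohort(d, cardiac, eeg, behavior_sim_params(),
                    emotions = c("disgust", "neutral"), seed = 7L)
  }
  files <- sort(list.files(dir_a))
  expect_equal(sort(list.files(dir_b)), files)
  expect_equal(sum(grepl("^beats_", files)), 4)  # 2 participants x 2 phases
  for (f in files) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)),
                     label = sprintf("file %s", f))
  }
  manifest <- jsonlite::read_json(file.path(dir_a, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(length(manifest$participants$participant), 2)
  expect_true(all(c("inhibition", "theta_decrease") %in%
                    names(manifest$participants)))
  # files written by the cohort re-load through the io layer
  beats <- read_beats(file.path(dir_a, "beats_P01_pre.tsv"))
  expect_gt(length(beats$beat_times), 100)
  ep <- read_epochs(file.path(dir_a, "eeg_P01.txt"),
                    file.path(dir_a, "eeg_P01.json"))
  expect_equal(dim(ep$data), c(4, 4, 150))
})

test_that("behavioral contingencies match their generating probabilities", {
  design <- toy_behavior(n_items = 200)
  params <- behavior_sim_params(
    recall_p = c(think = 0.95, nothink = 0.7, baseline = 0.9),
    criterion_fail_p = 0)
  beh <- simulate_behavior(design, params, seed = 21)
  expect_equal(attr(criterion_exclude(beh), "exclusions")$n_excluded, 0)
  sc <- recall_scores(beh)
  supp <- sc$suppression$score_pp
  # binomial oracle: diff of two proportions, n = 200 each, ~3 SE band
  se <- 100 * sqrt(0.7 * 0.3 / 200 + 0.9 * 0.1 / 200)
  expect_true(all(abs(supp - (-20)) < 3 * se))
  # saturated intrusions
  beh2 <- simulate_behavior(toy_behavior(20),
                            behavior_sim_params(
                              intrusion_p1 = c(disgust = 1, sad = 1,
                                               neutral = 1),
                              intrusion_decay = 1),
                            seed = 3)
  tc <- intrusion_timecourse(beh2)
  expect_true(all(tc$proportion == 1))
})

test_that("intrusion decay follows the per-block geometric schedule", {
  design <- do.call(rbind, replicate(40, toy_behavior(6), simplify = FALSE))
  params <- behavior_sim_params(intrusion_p1 = c(disgust = 0.6, sad = 0.6,
                                                 neutral = 0.6),
                                intrusion_decay = 0.8)
  beh <- simulate_behavior(design, params, seed = 5)
  tc <- intrusion_timecourse(beh, emotion = "disgust")
  n_rep <- sum(beh$condition == "nothink" & beh$emotion == "disgust")
  for (b in c(1, 4, 8)) {
    p_true <- 0.6 * 0.8^(b - 1)
    obs <- mean(tc$proportion[tc$block == b])
    expect_lt(abs(obs - p_true), 3 * sqrt(p_true * (1 - p_true) / n_rep))
  }
})

test_that("eeg epochs have the requested geometry and injected band effect", {
  p <- eeg_sim_params(n_channels = 102, rate = 100, window = c(-0.2, 0.3),
                      n_trials = 1)
  ep <- simulate_eeg_epochs(c("think", "nothink"), p, seed = 1)
  expect_equal(dim(ep$data), c(2, 102, 50))
  # analytic power-of-sinusoid oracle: amplitude halved -> power quartered
  p2 <- eeg_sim_params(n_channels = 2, rate = 100, window = c(-1, 3),
                       pink_sd = 0,
                       nt_scales = c(theta = NA, alpha = 1, low_beta = 1,
                                     high_beta = 1))
  ep2 <- simulate_eeg_epochs(rep(c("think", "nothink"), 3), p2,
                             theta_scale = 0.5, seed = 2)
  tfr <- multitaper_tfr(ep2$data, rate = 100, time = ep2$time, freqs = 5.5,
                        average = FALSE)
  sel <- tfr$time > 1 & tfr$time < 2.5
  pw <- apply(tfr$power[, , 1, sel], 1, mean)
  ratio <- mean(pw[ep2$conditions == "nothink"]) /
    mean(pw[ep2$conditions == "think"])
  expect_equal(ratio, 0.25, tolerance = 0.05)
})

test_that("latent inhibition effects are recovered with unit slope", {
  cardiac <- cardiac_sim_params(n_participants = 28)
  inh <- cohort_inhibition_scores(cardiac, seed = 11,
                                  emotions = "disgust",
                                  conditions = c("nothink", "baseline"))
  fit <- stats::lm(score ~ true_inhibition, data = inh$scores)
  expect_gt(stats::coef(fit)[2], 0.7)
  expect_lt(stats::coef(fit)[2], 1.3)
})

test_that("the disc montage is symmetric and covers every channel", {
  m <- disc_montage(102)
  expect_equal(length(m$channels), 102)
  expect_true(all(m$adjacency$channels == m$channels))
  deg <- table(factor(m$adjacency$pairs[, 1], levels = m$channels))
  expect_true(all(deg >= 1))
})
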