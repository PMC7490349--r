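# Cohort-level convenience wrappers: simulate a cohort in memory and push it
# through the cardiac, evoked-statistics and EEG stages. These are the same
# steps a user would run on real exported recordings, with the generator
# standing in for the acquisition system.

#' Evoked cardiac epochs for one simulated participant
#'
#' Simulates a beat series for the given events, screens artifacts,
#' estimates the instantaneous rate and cuts baseline-referenced epochs.
#'
#' @param events An [event_table()].
#' @param cardiac A [cardiac_sim_params()].
#' @param baseline_bpm,inhibition,phase,rsa_phase,seed Passed to
#'   [simulate_beats()].
#' @param grid_rate Rate-grid rate (Hz).
#' @param window Epoch window (s).
#' @param baseline_policy Epoch reference policy.
#' @param participant Participant id.
#' @return A `cardiac_epochs` object.
#' @export
participant_evoked <- function(events, cardiac = cardiac_sim_params(),
                               baseline_bpm = cardiac$baseline_bpm_mean,
                               inhibition = cardiac$inhib_mean,
                               phase = "pre", rsa_phase = 0, seed = NULL,
                               grid_rate = 10, window = c(0, 10),
                               baseline_policy = "onset",
                               participant = NA_character_) {
  beats <- simulate_beats(events, cardiac, baseline_bpm = baseline_bpm,
                          inhibition = inhibition, phase = phase,
                          rsa_phase = rsa_phase, seed = seed)
  beats <- reject_artifacts(beats)
  rate <- instantaneous_rate(beats, grid_rate)
  epoch_cardiac(rate, events, window = window,
                baseline_policy = baseline_policy, participant = participant)
}

#' Simulate a cohort of cardiac epochs in memory
#'
#' @param cardiac A [cardiac_sim_params()].
#' @param eeg An [eeg_sim_params()] (supplies the coupling for the latent
#'   draws).
#' @param phase `"pre"` or `"post"`.
#' @param emotions,conditions Design cells.
#' @param design Schedule design.
#' @param seed Base seed.
#' @param grid_rate Rate-grid rate (Hz).
#' @return A list with `epochs` (list of `cardiac_epochs`) and `truth`
#'   (the [draw_participants()] tibble).
#' @export
simulate_cohort_epochs <- function(cardiac = cardiac_sim_params(),
                                   eeg = eeg_sim_params(),
                                   phase = "pre",
                                   emotions = c("disgust", "neutral"),
                                   conditions = c("think", "nothink",
                                                  "baseline"),
                                   design = "blocked", seed = 1L,
                                   grid_rate = 10) {
  set.seed(seed)
  truth <- draw_participants(cardiac$n_participants, cardiac, eeg)
  drift <- cardiac$session_drift_bpm / 2
  epochs <- lapply(seq_len(cardiac$n_participants), function(p) {
    ev <- schedule_events(phase, n_items = cardiac$n_items,
                          emotions = emotions, conditions = conditions,
                          design = design,
                          seed = .stream_seed(seed, p, 1L))
    participant_evoked(
      ev, cardiac,
      baseline_bpm = truth$baseline_bpm[p] +
        if (phase == "pre") drift else -drift,
      inhibition = truth$inhibition[p], phase = phase,
      rsa_phase = truth$rsa_phase[p],
      seed = .stream_seed(seed, p, 3L), grid_rate = grid_rate,
      participant = truth$participant[p])
  })
  list(epochs = epochs, truth = truth)
}

#' Pre-assessment emotional contrast
#'
#' Pools items by emotion, contrasts the negative-emotion curves (mean of
#' disgust and, when present, sad) against the neutral curves with a
#' pointwise paired t test (two-tailed) under FDR correction, and reports
#' the emotional time of interest and the peak deflection of the
#' grand-mean negative curve.
#'
#' @param epochs List of `cardiac_epochs` (one per participant).
#' @param q FDR level.
#' @return A list with `test` (`pointwise_test`), `toi` (`time_window` or
#'   NULL when no point survives), `peak` (grand-mean negative-curve peak),
#'   `evoked` (the by-emotion `evoked_set`).
#' @export
pre_assessment_contrast <- function(epochs, q = 0.05) {
  ev <- average_evoked(epochs, by = "emotion")
  negatives <- intersect(c("disgust", "sad"), names(ev$cells))
  stopifnot(length(negatives) >= 1, "neutral" %in% names(ev$cells))
  emo <- Reduce(`+`, ev$cells[negatives]) / length(negatives)
  test <- pointwise_paired_t(emo, ev$cells$neutral, time = ev$time,
                             tail = "two", q = q)
  toi <- tryCatch(extract_toi(test), error = function(e) NULL)
  grand_neg <- colMeans(emo)
  peak <- peak_deflection(grand_neg, ev$time, direction = "min")
  list(test = test, toi = toi, peak = peak, evoked = ev)
}

#' Cardiac inhibition scores for a simulated post-TNT cohort
#'
#' Simulates the post-TNT assessment, builds the No-Think and Baseline
#' evoked curves for the target emotion, and scores every participant over
#' the intersection of the emotional and suppression windows.
#'
#' @param cardiac,eeg Parameter objects.
#' @param emotion Emotion carrying the inhibition effect.
#' @param seed Base seed.
#' @param emotional_toi,suppression_toi Score windows (s).
#' @param grid_rate Rate-grid rate (Hz).
#' @return A list with `scores` (tibble with truth columns joined) and
#'   `truth`.
#' @export
cohort_inhibition_scores <- function(cardiac = cardiac_sim_params(),
                                     eeg = eeg_sim_params(),
                                     emotion = "disgust", seed = 1L,
                                     emotional_toi = c(1.89, 5.03),
                                     suppression_toi = c(2.41, 10),
                                     grid_rate = 10,
                                     emotions = c(emotion, "neutral"),
                                     conditions = c("think", "nothink",
                                                    "baseline")) {
  sim <- simulate_cohort_epochs(cardiac, eeg, phase = "post",
                                emotions = emotions,
                                conditions = conditions,
                                seed = seed, grid_rate = grid_rate)
  ev <- average_evoked(sim$epochs, by = c("condition", "emotion"))
  nt <- ev$cells[[paste0("nothink.", emotion)]]
  bl <- ev$cells[[paste0("baseline.", emotion)]]
  stopifnot(identical(rownames(nt), rownames(bl)))
  scores <- inhibition_score(nt, bl, ev$time, emotional_toi, suppression_toi)
  m <- match(scores$participant, sim$truth$participant)
  scores$true_inhibition <- sim$truth$inhibition[m]
  scores$true_theta_decrease <- sim$truth$theta_decrease[m]
  list(scores = scores, truth = sim$truth)
}

#' Per-participant theta No-Think power decrease
#'
#' Simulates one participant's EEG epochs, computes trial-averaged
#' multitaper TFRs per condition, percent-baselines, downsamples, contrasts
#' No-Think against Think and averages over a band and window.
#'
#' @param eeg An [eeg_sim_params()].
#' @param theta_scale The participant's No-Think theta amplitude scale.
#' @param seed Seed.
#' @param band,window Band (Hz) and time window (s) of the summary scalar.
#' @param freqs TFR frequency axis; defaults to the canonical 27 bins
#'   restricted to the band (what the summary uses).
#' @param crop,baseline Percent-change windows (s).
#' @param bin Downsampling bin (s).
#' @return The band-average scalar (percent change difference).
#' @export
participant_theta_decrease <- function(eeg = eeg_sim_params(),
                                       theta_scale = 1, seed = NULL,
                                       band = c(3, 8), window = c(1.0, 2.5),
                                       freqs = NULL,
                                       crop = c(-0.5, 3.0),
                                       baseline = c(-0.5, 0), bin = 0.02) {
  if (is.null(freqs)) {
    full <- seq(3, 30, length.out = 27)
    freqs <- full[full >= band[1] & full <= band[2]]
  }
  ep <- simulate_eeg_epochs(rep(c("think", "nothink"), each = eeg$n_trials),
                            eeg, theta_scale = theta_scale, seed = seed)
  # one decomposition for all trials, then per-condition trial means
  tfr_all <- multitaper_tfr(ep$data, rate = ep$rate, time = ep$time,
                            freqs = freqs, channels = ep$channels,
                            average = FALSE)
  one <- function(cond) {
    sel <- ep$conditions == cond
    tfr <- tfr_all
    tfr$power <- array(colMeans(tfr_all$power[sel, , , , drop = FALSE]),
                       dim = dim(tfr_all$power)[-1])
    tfr$n_trials <- sum(sel)
    downsample_time(crop_and_baseline(tfr, crop, baseline), bin)
  }
  contrast <- condition_tfr_contrast(list(one("nothink")), list(one("think")),
                                     min_trials = min(eeg$n_trials, 5))
  band_average(contrast$diffs[[1]], band = band, window = window)
}

#' Median-split theta contrast for one simulated cohort
#'
#' The full chain linking memory-suppression EEG to cardiac inhibition:
#' cardiac inhibition scores recovered from the simulated post-TNT
#' assessment, a median split of participants, per-participant theta
#' No-Think power decreases from the simulated EEG, and a one-sided
#' Mann-Whitney test that the high-inhibition group shows the larger theta
#' decrease.
#'
#' @param cardiac,eeg Parameter objects.
#' @param seed Base seed.
#' @param band,window Band (Hz) and window (s) of the theta summary.
#' @return A list with `test` (`rank_test`), `scores`, `theta` (per
#'   participant scalars), `split`.
#' @export
cohort_theta_split <- function(cardiac = cardiac_sim_params(),
                               eeg = eeg_sim_params(), seed = 1L,
                               band = c(3, 8), window = c(1.0, 2.5)) {
  # only the no-think and baseline disgust cells enter the score
  inh <- cohort_inhibition_scores(cardiac, eeg, seed = seed,
                                  emotions = "disgust",
                                  conditions = c("nothink", "baseline"))
  theta <- vapply(seq_len(nrow(inh$truth)), function(p) {
    participant_theta_decrease(
      eeg, theta_scale = 1 - inh$truth$theta_decrease[p],
      seed = .stream_seed(seed, p, 5L), band = band, window = window)
  }, numeric(1))
  split <- median_split(inh$scores)
  hi <- theta[split$label == "high_inhibition"]
  lo <- theta[split$label == "low_inhibition"]
  test <- mann_whitney(hi, lo, tail = "less")
  list(test = test, scores = inh$scores, theta = theta, split = split)
}
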