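# Synthetic cohorts with known ground truth: heartbeat point processes from a
# stated instantaneous-rate model, oscillatory EEG epochs, and TNT behavioral
# contingencies. Every latent parameter is recorded in the cohort manifest so
# downstream estimators can be validated by recovery.

#' Default evoked heart-rate kernel table
#'
#' One gamma-shaped deceleration kernel per design cell, parameterized by
#' peak amplitude (bpm, negative = deceleration), peak latency (s after
#' stimulus onset) and width (s). Condition `"any"` matches every condition
#' (used in the pre-TNT assessment, where conditions are not yet
#' distinguishable in the cardiac response). Cells with `inhibition = TRUE`
#' receive the participant's inhibition effect: the kernel amplitude is
#' shifted toward zero by the participant's true inhibition (bpm), emulating
#' the blunted deceleration of suppressed material.
#'
#' @param phase `"pre"` or `"post"`.
#' @return A data frame with columns `condition`, `emotion`, `amplitude`,
#'   `latency`, `width`, `inhibition`.
#' @export
default_kernel_table <- function(phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (phase == "pre") {
    data.frame(
      condition = "any",
      emotion = c("disgust", "sad", "neutral"),
      amplitude = c(-2.34, -2.24, -0.60),
      latency = c(3.48, 3.36, 3.50),
      width = 1.5,
      inhibition = FALSE
    )
  } else {
    data.frame(
      condition = c("think", "nothink", "baseline",
                    "think", "nothink", "baseline",
                    "think", "nothink", "baseline"),
      emotion = rep(c("disgust", "sad", "neutral"), each = 3),
      amplitude = c(-2.70, -2.68, -2.68,
                    -2.69, -4.05, -2.68,
                    -1.80, -2.44, -2.73),
      latency = c(4.70, 4.16, 4.16,
                  5.33, 4.48, 4.16,
                  5.57, 5.99, 5.68),
      width = 1.5,
      inhibition = c(FALSE, TRUE, FALSE,
                     FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE)
    )
  }
}

#' Cardiac simulation parameters
#'
#' Defaults emulate the observed conditions of TNT emotion-assessment
#' sessions: session-mean heart rates near 80 bpm before and 70 bpm after
#' the task (participant SD ~10.5 bpm), a disgust deceleration kernel
#' peaking at -2.34 bpm around 3.48 s, respiratory sinus arrhythmia of
#' 1.5 bpm at 0.25 Hz, and a 1-bpm mean blunting of the No-Think
#' deceleration with 0.6 bpm between-participant spread.
#'
#' @param baseline_bpm_mean,baseline_bpm_sd Across-participant distribution
#'   of session-mean heart rate (bpm).
#' @param session_drift_bpm Pre-minus-post difference in session-mean heart
#'   rate (bpm); the pre session runs `drift/2` above the participant mean
#'   and the post session `drift/2` below. Set 0 to disable.
#' @param kernel_pre,kernel_post Kernel tables (see [default_kernel_table()]).
#' @param inhib_mean,inhib_sd Mean and SD (bpm) of the per-participant true
#'   inhibition effect added to `inhibition = TRUE` kernel amplitudes.
#' @param rsa_amp,rsa_freq Respiratory sinus arrhythmia amplitude (bpm) and
#'   frequency (Hz).
#' @param noise_sd,noise_tau Smooth within-recording rate noise: SD in bpm
#'   and Gaussian smoothing kernel SD in seconds.
#' @param n_participants,n_items Cohort size and items per
#'   condition-by-emotion cell.
#' @param dt Integration step (s) of the rate model.
#' @param seed Base seed for cohort generation.
#' @return A list of class `cardiac_sim_params`.
#' @export
cardiac_sim_params <- function(baseline_bpm_mean = 75.7,
                               baseline_bpm_sd = 10.5,
                               session_drift_bpm = 9.8,
                               kernel_pre = default_kernel_table("pre"),
                               kernel_post = default_kernel_table("post"),
                               inhib_mean = 1.0,
                               inhib_sd = 0.6,
                               rsa_amp = 1.5,
                               rsa_freq = 0.25,
                               noise_sd = 0.5,
                               noise_tau = 2.0,
                               n_participants = 28,
                               n_items = 12,
                               dt = 0.01,
                               seed = 1L) {
  stopifnot(baseline_bpm_mean > 0, n_items > 0, n_participants > 0, dt > 0)
  structure(as.list(environment()), class = "cardiac_sim_params")
}

#' EEG simulation parameters
#'
#' Defaults emulate condition-dependent band power in dense-array epochs:
#' 102 channels, epochs spanning [-1.5, 4.0) s around cue onset, ongoing
#' band-limited oscillations whose post-onset amplitude is scaled by
#' condition, on top of spatially correlated pink noise. The per-participant
#' theta No-Think decrease is drawn jointly with the cardiac inhibition
#' effect at correlation `coupling` (default 0.6), which makes the
#' median-split analysis of theta power against cardiac inhibition
#' recoverable from synthetic cohorts.
#'
#' @param n_channels Number of channels (disc montage).
#' @param window Epoch window in seconds relative to cue onset, half-open.
#' @param rate Sampling rate (Hz).
#' @param band_amps Named amplitudes (a.u.) of the ongoing oscillation in
#'   each band.
#' @param band_freqs Named list of component frequencies (Hz) per band;
#'   each band's oscillation is a sum of equal-amplitude sinusoids with
#'   independent random phases per trial, spreading power across the band
#'   as in broadband cortical rhythms.
#' @param nt_scales Fixed post-onset amplitude scaling of No-Think trials
#'   per band; the theta entry is replaced by the participant's own
#'   `1 - theta decrease`.
#' @param theta_decrease_mean,theta_decrease_sd Distribution of the
#'   per-participant fractional theta amplitude decrease on No-Think trials.
#' @param coupling Correlation between the theta decrease and the cardiac
#'   inhibition effect across participants.
#' @param pink_sd Pink-noise SD (a.u.).
#' @param spatial_mix Fraction of noise variance shared across channels.
#' @param effect_onset,effect_ramp Time (s) after onset at which the
#'   condition scaling engages, and ramp duration (s).
#' @param n_trials Trials per condition.
#' @param seed Base seed.
#' @return A list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(n_channels = 102,
                           window = c(-1.5, 4.0),
                           rate = 250,
                           band_amps = c(theta = 1.0, alpha = 1.2,
                                         low_beta = 0.7, high_beta = 0.4),
                           band_freqs = list(theta = c(3.8, 5.5, 7.2),
                                             alpha = c(8.8, 10, 11.2),
                                             low_beta = c(14, 16.5, 19),
                                             high_beta = c(21, 25, 29)),
                           nt_scales = c(theta = NA, alpha = 0.9,
                                         low_beta = 0.9, high_beta = 1.0),
                           theta_decrease_mean = 0.3,
                           theta_decrease_sd = 0.15,
                           coupling = 0.6,
                           pink_sd = 1.0,
                           spatial_mix = 0.3,
                           effect_onset = 0.5,
                           effect_ramp = 0.2,
                           n_trials = 24,
                           seed = 1L) {
  stopifnot(n_channels >= 1, all(band_amps >= 0), window[1] < window[2],
            rate > 0)
  structure(as.list(environment()), class = "eeg_sim_params")
}

#' Behavioral simulation parameters
#'
#' Defaults emulate TNT behavioral contingencies: intrusion proportions
#' starting near 0.5 and decaying geometrically across the eight blocks,
#' final recall higher for baseline than suppressed items, and a ~1.2%
#' criterion-test failure rate.
#'
#' @param intrusion_p1 Named per-emotion intrusion probability in block 1.
#' @param intrusion_decay Multiplicative decay of the intrusion probability
#'   per block.
#' @param n_blocks Number of TNT blocks.
#' @param recall_p Named per-condition final recall probability.
#' @param criterion_fail_p Probability that an item fails the pre-TNT
#'   criterion test.
#' @param valence_pre_mean Named per-emotion mean pre-TNT valence rating
#'   (1-9 scale).
#' @param valence_sd Rating noise SD.
#' @param valence_shift Named per-condition true shift of post-TNT ratings.
#' @param seed Base seed.
#' @return A list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(intrusion_p1 = c(disgust = 0.45, sad = 0.55,
                                                 neutral = 0.50),
                                intrusion_decay = 0.85,
                                n_blocks = 8,
                                recall_p = c(think = 0.95, nothink = 0.80,
                                             baseline = 0.90),
                                criterion_fail_p = 0.012,
                                valence_pre_mean = c(disgust = 3.0, sad = 3.0,
                                                     neutral = 5.8),
                                valence_sd = 1.0,
                                valence_shift = c(think = 0, nothink = 0,
                                                  baseline = 0),
                                seed = 1L) {
  stopifnot(all(intrusion_p1 >= 0 & intrusion_p1 <= 1),
            intrusion_decay >= 0 & intrusion_decay <= 1,
            all(recall_p >= 0 & recall_p <= 1),
            criterion_fail_p >= 0 & criterion_fail_p <= 1)
  structure(as.list(environment()), class = "behavior_sim_params")
}

# gamma-shaped bump normalized so k(latency) = amplitude; width w maps to the
# dimensionless shape s = (latency / w)^2, so larger w means a broader bump
.rate_kernel <- function(t, amplitude, latency, width) {
  s <- (latency / width)^2
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / latency
  out[pos] <- amplitude * (x * exp(1 - x))^s
  out
}

.match_kernels <- function(events, table) {
  idx <- integer(nrow(events))
  key_exact <- paste(table$condition, table$emotion)
  key_any <- paste("any", table$emotion)
  for (i in seq_len(nrow(events))) {
    j <- match(paste(events$condition[i], events$emotion[i]), key_exact)
    if (is.na(j)) j <- match(paste("any", events$emotion[i]), key_any)
    if (is.na(j)) {
      stop(sprintf("no kernel for cell (%s, %s)", events$condition[i],
                   events$emotion[i]), call. = FALSE)
    }
    idx[i] <- j
  }
  idx
}

# smooth Gaussian-correlated noise, unit SD before scaling; FFT convolution
# at a power-of-2 length (prime-length FFTs are pathologically slow)
.smooth_noise <- function(n, dt, tau) {
  if (n < 3) return(numeric(n))
  half <- ceiling(3 * tau / dt)
  m <- 2 * half + 1
  kern <- stats::dnorm(seq(-half, half) * dt, sd = tau)
  kern <- kern / sum(kern)
  w <- stats::rnorm(n + 2 * half)
  nfft <- 2^ceiling(log2(length(w) + m - 1))
  conv <- Re(stats::fft(stats::fft(c(w, numeric(nfft - length(w)))) *
                          stats::fft(c(kern, numeric(nfft - m))),
                        inverse = TRUE)) / nfft
  sm <- conv[m:(m + n - 1)]
  sm / stats::sd(sm)
}

#' Evaluate the latent instantaneous-rate model
#'
#' The ground-truth rate (bpm) underlying [simulate_beats()]:
#' baseline + sum of event kernels + RSA sine + smooth noise.
#'
#' @param time Times (s) at which to evaluate.
#' @param events An [event_table()].
#' @param kernels Kernel table rows matched to `events` (columns
#'   `amplitude`, `latency`, `width`; one row per event).
#' @param baseline_bpm Baseline rate (bpm).
#' @param rsa_amp,rsa_freq,rsa_phase RSA sine parameters.
#' @param noise Optional precomputed noise vector (bpm) aligned with `time`.
#' @return Numeric vector of rates (bpm).
#' @export
rate_model <- function(time, events, kernels, baseline_bpm,
                       rsa_amp = 0, rsa_freq = 0.25, rsa_phase = 0,
                       noise = NULL) {
  r <- rep(baseline_bpm, length(time))
  uniform <- length(time) > 1 && diff(range(diff(time))) < 1e-9
  for (i in seq_len(nrow(events))) {
    if (uniform) {
      # the bump is negligible beyond ~6 peak latencies; restrict support
      dt <- time[2] - time[1]
      i1 <- max(1L, floor((events$onset[i] - time[1]) / dt) + 1L)
      i2 <- min(length(time),
                ceiling((events$onset[i] + 6 * kernels$latency[i] -
                           time[1]) / dt) + 1L)
      sel <- i1:i2
    } else {
      sel <- seq_along(time)
    }
    r[sel] <- r[sel] + .rate_kernel(time[sel] - events$onset[i],
                                    kernels$amplitude[i],
                                    kernels$latency[i], kernels$width[i])
  }
  if (rsa_amp != 0) r <- r + rsa_amp * sin(2 * pi * rsa_freq * time + rsa_phase)
  if (!is.null(noise)) r <- r + noise
  r
}

#' Simulate a beat series from events by time rescaling
#'
#' Realizes an inhomogeneous point process from the instantaneous-rate model
#' r(t) = baseline + event kernels + RSA sine + smooth noise: the k-th beat
#' occurs when the integral of r(t)/60 since the previous beat reaches 1
#' (integrate-and-fire by time rescaling). With constant r the generated
#' intervals are exactly 60/r seconds.
#'
#' @param events An [event_table()] for one recording; events must lie
#'   within the simulated span.
#' @param params A [cardiac_sim_params()].
#' @param baseline_bpm This recording's baseline rate (bpm); defaults to the
#'   population mean.
#' @param inhibition True inhibition effect (bpm) added to kernels flagged
#'   `inhibition = TRUE`.
#' @param phase `"pre"` or `"post"`: selects the kernel table.
#' @param rsa_phase RSA phase offset (rad).
#' @param span Recording length (s); defaults to last event offset + 5 s.
#' @param seed Optional seed for the noise draw.
#' @return A [beat_series()] with attribute `rate` (list `time`, `bpm`): the
#'   realized ground-truth rate curve.
#' @export
simulate_beats <- function(events, params = cardiac_sim_params(),
                           baseline_bpm = params$baseline_bpm_mean,
                           inhibition = params$inhib_mean,
                           phase = c("pre", "post"),
                           rsa_phase = 0, span = NULL, seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  table <- if (phase == "pre") params$kernel_pre else params$kernel_post
  kern <- table[.match_kernels(events, table), , drop = FALSE]
  kern$amplitude <- kern$amplitude + ifelse(kern$inhibition, inhibition, 0)
  if (is.null(span)) span <- max(events$onset + events$duration) + 5
  if (any(events$onset < 0) || any(events$onset + events$duration > span)) {
    stop("events must lie within the simulated recording span", call. = FALSE)
  }
  time <- seq(0, span, by = params$dt)
  noise <- if (params$noise_sd > 0) {
    params$noise_sd * .smooth_noise(length(time), params$dt, params$noise_tau)
  } else NULL
  r <- rate_model(time, events, kern, baseline_bpm,
                  rsa_amp = params$rsa_amp, rsa_freq = params$rsa_freq,
                  rsa_phase = rsa_phase, noise = noise)
  if (any(r <= 0)) {
    stop("rate model is non-positive somewhere; lower noise/kernel amplitudes",
         call. = FALSE)
  }
  # cumulative intensity by trapezoid; beats at integer crossings
  lam <- c(0, cumsum((r[-1] + r[-length(r)]) / 2) * params$dt / 60)
  n_beats <- floor(lam[length(lam)])
  if (n_beats < 3) stop("recording too short: fewer than 3 beats", call. = FALSE)
  beats <- stats::approx(lam, time, xout = seq_len(n_beats), ties = "ordered")$y
  out <- beat_series(beats)
  attr(out, "rate") <- list(time = time, bpm = r)
  out
}

#' Build a TNT session event schedule
#'
#' Emulates the emotion-assessment schedule: 10-s scene presentations with a
#' 500-ms interstimulus interval, grouped into a neutral and a negative
#' block separated by a rest. In the `"blocked"` design each valence block
#' is divided into condition sub-blocks (think / no-think / baseline); in
#' the `"randomized"` design conditions are shuffled within each valence
#' block. Both designs present exactly the same items.
#'
#' @param phase `"pre"` or `"post"`.
#' @param n_items Items per condition-by-emotion cell.
#' @param emotions Emotions included (negative emotions share the negative
#'   block).
#' @param conditions Conditions included.
#' @param design `"blocked"` or `"randomized"`.
#' @param duration Scene duration (s).
#' @param isi Interstimulus interval (s).
#' @param rest Rest between sub-blocks (s).
#' @param lead Initial rest (s).
#' @param seed Seed for the randomized ordering.
#' @return An [event_table()].
#' @export
schedule_events <- function(phase = "pre", n_items = 12,
                            emotions = c("disgust", "sad", "neutral"),
                            conditions = c("think", "nothink", "baseline"),
                            design = c("blocked", "randomized"),
                            duration = 10, isi = 0.5, rest = 30, lead = 10,
                            seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  items <- expand.grid(condition = conditions, emotion = emotions,
                       idx = seq_len(n_items), stringsAsFactors = FALSE)
  items$item_id <- sprintf("%s_%s_%02d", items$emotion, items$condition,
                           items$idx)
  items$valence <- ifelse(items$emotion == "neutral", "neutral", "negative")
  ordered <- NULL
  for (v in c("neutral", "negative")) {
    blk <- items[items$valence == v, , drop = FALSE]
    if (!nrow(blk)) next
    if (design == "blocked") {
      blk <- blk[order(match(blk$emotion, emotions),
                       match(blk$condition, conditions), blk$idx), ,
                 drop = FALSE]
      blk$subblock <- paste(blk$emotion, blk$condition)
    } else {
      # conditions intermixed within each emotion's presentation block
      blk <- blk[order(match(blk$emotion, emotions)), , drop = FALSE]
      for (e in unique(blk$emotion)) {
        sel <- which(blk$emotion == e)
        blk[sel, ] <- blk[sel[sample(length(sel))], ]
      }
      blk$subblock <- blk$emotion
    }
    ordered <- rbind(ordered, blk)
  }
  onset <- numeric(nrow(ordered))
  t <- lead
  prev_block <- ordered$subblock[1]
  for (i in seq_len(nrow(ordered))) {
    if (ordered$subblock[i] != prev_block) {
      t <- t + rest
      prev_block <- ordered$subblock[i]
    }
    onset[i] <- t
    t <- t + duration + isi
  }
  event_table(onset, duration, phase, ordered$condition, ordered$emotion,
              ordered$item_id)
}

#' Regular disc montage with neighbor adjacency
#'
#' Places `n` channels on a sunflower (golden-angle) layout over the unit
#' disc and connects each channel to its spatial neighbors (pairs closer
#' than 1.6 times the median nearest-neighbor distance). The real sensor-net
#' geometry is not needed to exercise spatial clustering logic.
#'
#' @param n Number of channels.
#' @return A list with `channels`, `xy` (n x 2 coordinates) and `adjacency`
#'   (an `adjacency_list`).
#' @export
disc_montage <- function(n) {
  k <- seq_len(n)
  radius <- sqrt((k - 0.5) / n)
  theta <- pi * (3 - sqrt(5)) * k
  xy <- cbind(radius * cos(theta), radius * sin(theta))
  channels <- sprintf("CH%03d", k)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  cutoff <- 1.6 * stats::median(nn)
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) == 0 && n > 1) idx <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
  adj <- adjacency_list(cbind(channels[idx[, 1]], channels[idx[, 2]]),
                        channels = channels)
  list(channels = channels, xy = xy, adjacency = adj)
}

# columns of 1/f-amplitude noise, unit SD; computed at a power-of-2 length
# and truncated (FFTs at awkward lengths are slow)
.pink_noise_mat <- function(n, n_col) {
  nfft <- 2^ceiling(log2(n))
  spec <- stats::mvfft(matrix(stats::rnorm(nfft * n_col), nfft, n_col))
  f <- c(1, seq_len(nfft - 1))
  f <- pmin(f, nfft - f + 1)  # mirrored frequencies
  x <- Re(stats::mvfft(spec / sqrt(f), inverse = TRUE))[seq_len(n), ,
                                                        drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate oscillatory EEG epochs
#'
#' Each epoch is spatially correlated pink noise plus ongoing band-limited
#' sinusoidal oscillations whose amplitude, from `effect_onset` seconds
#' after the cue, is scaled per condition. On No-Think trials the theta
#' amplitude is scaled by `theta_scale` (the participant's effect); alpha
#' and low-beta carry the fixed decreases in `params$nt_scales`.
#'
#' @param conditions Character vector of per-trial condition labels
#'   (`"think"` / `"nothink"`).
#' @param params An [eeg_sim_params()].
#' @param theta_scale Post-onset theta amplitude multiplier on No-Think
#'   trials (1 = no decrease).
#' @param seed Optional seed.
#' @return A list with `data` (trial x channel x time array), `channels`,
#'   `time`, `rate`, `conditions`.
#' @export
simulate_eeg_epochs <- function(conditions, params = eeg_sim_params(),
                                theta_scale = 1 - params$theta_decrease_mean,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- .canon_label(conditions, .canonical_conditions, "condition")
  n_trial <- length(conditions)
  time <- seq(params$window[1], params$window[2] - 1 / params$rate,
              by = 1 / params$rate)
  nt <- length(time)
  nch <- params$n_channels
  ramp <- pmin(pmax((time - params$effect_onset) / params$effect_ramp, 0), 1)
  bands <- names(params$band_amps)
  # noise: one shared pink component per trial plus channel-specific pink
  pink <- .pink_noise_mat(nt, n_trial * (nch + 1))
  shared <- pink[, seq_len(n_trial), drop = FALSE]            # nt x trial
  own <- array(pink[, -seq_len(n_trial)], dim = c(nt, nch, n_trial))
  data <- array(0, dim = c(nt, nch, n_trial))
  for (tr in seq_len(n_trial)) {
    epoch <- params$pink_sd *
      (sqrt(params$spatial_mix) * shared[, tr] +
         sqrt(1 - params$spatial_mix) * own[, , tr])
    sig <- numeric(nt)
    for (b in bands) {
      scale_post <- if (conditions[tr] == "nothink") {
        if (b == "theta") theta_scale else params$nt_scales[[b]]
      } else 1
      comps <- params$band_freqs[[b]]
      amp_t <- params$band_amps[[b]] / sqrt(length(comps)) *
        (1 + (scale_post - 1) * ramp)
      carrier <- rowSums(sin(outer(time, 2 * pi * comps) +
                               rep(stats::runif(length(comps), 0, 2 * pi),
                                   each = nt)))
      sig <- sig + amp_t * carrier
    }
    data[, , tr] <- epoch + sig
  }
  data <- aperm(data, c(3, 2, 1))
  list(data = data, channels = sprintf("CH%03d", seq_len(nch)), time = time,
       rate = params$rate, conditions = conditions)
}

#' Simulate TNT behavioral records
#'
#' Bernoulli intrusion reports with a geometrically decaying per-block
#' probability (No-Think items only), criterion-test outcomes, final recall
#' outcomes per condition, and pre/post valence ratings.
#'
#' @param design Data frame with one row per item: columns `condition`,
#'   `emotion`, `item_id`.
#' @param params A [behavior_sim_params()].
#' @param participant Participant id recorded in the output.
#' @param seed Optional seed.
#' @return A tibble, one row per item, with columns `participant`,
#'   `item_id`, `condition`, `emotion`, `criterion`, `recall`,
#'   `valence_pre`, `valence_post` and `intr_b1` ... `intr_b<n_blocks>`.
#' @export
simulate_behavior <- function(design, params = behavior_sim_params(),
                              participant = "P01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  nb <- params$n_blocks
  criterion <- stats::rbinom(n, 1, 1 - params$criterion_fail_p)
  recall <- stats::rbinom(n, 1, params$recall_p[design$condition])
  vpre <- round(pmin(pmax(
    stats::rnorm(n, params$valence_pre_mean[design$emotion],
                 params$valence_sd), 1), 9))
  vpost <- round(pmin(pmax(
    vpre + params$valence_shift[design$condition] +
      stats::rnorm(n, 0, params$valence_sd / 2), 1), 9))
  intr <- matrix(NA_integer_, n, nb)
  nt_rows <- which(design$condition == "nothink")
  for (b in seq_len(nb)) {
    p_b <- params$intrusion_p1[design$emotion[nt_rows]] *
      params$intrusion_decay^(b - 1)
    intr[nt_rows, b] <- stats::rbinom(length(nt_rows), 1, p_b)
  }
  colnames(intr) <- sprintf("intr_b%d", seq_len(nb))
  tibble::as_tibble(cbind(
    tibble::tibble(participant = participant,
                   item_id = design$item_id,
                   condition = design$condition,
                   emotion = design$emotion,
                   criterion = criterion,
                   recall = recall,
                   valence_pre = vpre,
                   valence_post = vpost),
    tibble::as_tibble(intr)))
}

.stream_seed <- function(base, participant, stream) {
  (as.integer(base) + 7919L * as.integer(participant) + as.integer(stream)) %%
    .Machine$integer.max
}

#' Draw per-participant latent effects
#'
#' The cardiac inhibition effect and the theta No-Think decrease are drawn
#' from a bivariate normal with correlation `eeg$coupling`, so that
#' participants whose suppressed-item deceleration is most blunted also tend
#' to show the largest theta power decrease.
#'
#' @param n Number of participants.
#' @param cardiac A [cardiac_sim_params()].
#' @param eeg An [eeg_sim_params()].
#' @return A tibble with `participant`, `baseline_bpm`, `inhibition`
#'   (bpm), `theta_decrease` (fraction, clamped to [0, 0.95]) and
#'   `rsa_phase`.
#' @export
draw_participants <- function(n, cardiac = cardiac_sim_params(),
                              eeg = eeg_sim_params()) {
  z1 <- stats::rnorm(n)
  z2 <- eeg$coupling * z1 + sqrt(1 - eeg$coupling^2) * stats::rnorm(n)
  tibble::tibble(
    participant = sprintf("P%02d", seq_len(n)),
    # truncated to the physiological resting range of healthy adults
    baseline_bpm = pmin(pmax(stats::rnorm(n, cardiac$baseline_bpm_mean,
                                          cardiac$baseline_bpm_sd), 45), 120),
    inhibition = cardiac$inhib_mean + cardiac$inhib_sd * z1,
    theta_decrease = pmin(pmax(eeg$theta_decrease_mean +
                                 eeg$theta_decrease_sd * z2, 0), 0.95),
    rsa_phase = stats::runif(n, 0, 2 * pi)
  )
}

#' Simulate a full cohort to disk
#'
#' Writes, per participant, pre- and post-TNT beats and events files, an EEG
#' epoch tensor with sidecar, plus a cohort behavior table, the channel
#' adjacency, and a JSON manifest recording every latent parameter (true
#' kernel amplitudes, per-participant inhibition and theta effects). Given
#' the same seed the output is byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param cardiac,eeg,behavior Parameter objects.
#' @param emotions Emotions included in the design.
#' @param design `"blocked"` or `"randomized"` schedule.
#' @param seed Integer base seed.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_cohort <- function(outdir,
                            cardiac = cardiac_sim_params(),
                            eeg = eeg_sim_params(),
                            behavior = behavior_sim_params(),
                            emotions = c("disgust", "sad", "neutral"),
                            design = c("blocked", "randomized"),
                            seed = 1L) {
  design <- match.arg(design)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- cardiac$n_participants
  truth <- draw_participants(n, cardiac, eeg)
  montage <- disc_montage(eeg$n_channels)
  write_adjacency(montage$adjacency, file.path(outdir, "adjacency.tsv"))
  drift <- cardiac$session_drift_bpm / 2
  behavior_rows <- vector("list", n)
  for (p in seq_len(n)) {
    pid <- truth$participant[p]
    for (ph in c("pre", "post")) {
      ev <- schedule_events(ph, n_items = cardiac$n_items,
                            emotions = emotions, design = design,
                            seed = .stream_seed(seed, p,
                                                if (ph == "pre") 1L else 2L))
      beats <- simulate_beats(
        ev, cardiac,
        baseline_bpm = truth$baseline_bpm[p] + if (ph == "pre") drift else -drift,
        inhibition = truth$inhibition[p], phase = ph,
        rsa_phase = truth$rsa_phase[p],
        seed = .stream_seed(seed, p, if (ph == "pre") 3L else 4L))
      write_events(ev, file.path(outdir, sprintf("events_%s_%s.tsv", pid, ph)))
      write_beats(beats, file.path(outdir, sprintf("beats_%s_%s.tsv", pid, ph)))
    }
    conditions <- rep(c("think", "nothink"), each = eeg$n_trials)
    ep <- simulate_eeg_epochs(conditions, eeg,
                              theta_scale = 1 - truth$theta_decrease[p],
                              seed = .stream_seed(seed, p, 5L))
    write_epochs(ep$data, ep$channels, ep$rate, ep$time[1],
                 file.path(outdir, sprintf("eeg_%s.txt", pid)),
                 file.path(outdir, sprintf("eeg_%s.json", pid)))
    writeLines(conditions, file.path(outdir, sprintf("eeg_%s_trials.tsv", pid)))
    item_design <- schedule_events("post", n_items = cardiac$n_items,
                                   emotions = emotions, design = "blocked")
    behavior_rows[[p]] <- simulate_behavior(item_design, behavior,
                                            participant = pid,
                                            seed = .stream_seed(seed, p, 6L))
  }
  beh <- do.call(rbind, behavior_rows)
  utils::write.table(beh, file.path(outdir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = seed, design = design, emotions = emotions,
    n_participants = n, n_items = cardiac$n_items,
    kernel_pre = cardiac$kernel_pre, kernel_post = cardiac$kernel_post,
    coupling = eeg$coupling,
    participants = as.data.frame(truth)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}
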