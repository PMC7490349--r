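# Multitaper time-frequency estimation with percent-change baselining,
# temporal downsampling, condition contrasts and band averages.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with half-bandwidth
#' parameter `nw`, via the classical symmetric tridiagonal eigenproblem
#' whose eigenvectors are the Slepian sequences. Tapers are unit-energy and
#' returned in decreasing order of spectral concentration.
#'
#' @param n Taper length (samples).
#' @param nw Time half-bandwidth product.
#' @param k Number of tapers.
#' @return An n x k matrix of tapers.
#' @export
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, k < n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- i[-1] * (n - i[-1]) / 2
  m <- diag(diag_main)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  e <- eigen(m, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # fix sign so the largest-magnitude element is positive (power is
  # sign-invariant; this only makes the basis deterministic)
  for (j in seq_len(k)) {
    if (tapers[which.max(abs(tapers[, j])), j] < 0) tapers[, j] <- -tapers[, j]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

# smallest 5-smooth integer >= n (fast FFT length)
.next_fast_len <- function(n) {
  best <- 2^ceiling(log2(n))
  for (a in 0:ceiling(log2(n))) {
    for (b in 0:ceiling(log(n, 3))) {
      v <- 2^a * 3^b
      if (v > best) break
      while (v < n) v <- v * 5
      if (v >= n && v < best) best <- v
    }
  }
  best
}

#' Multitaper time-frequency decomposition
#'
#' Sliding-window multitaper power estimation with a frequency-dependent
#' window: at each frequency f the window spans `n_cycles / f` seconds and
#' carries `floor(time_bandwidth) - 1` DPSS tapers with time half-bandwidth
#' `time_bandwidth / 2`. Power at each (channel, frequency, time) point is
#' the taper-averaged squared magnitude of the complex demodulate, with
#' unit-energy tapers, so a unit-variance white-noise input has expected
#' power 1 at every point.
#'
#' @param data Epoch data: trial x channel x time array, or a channel x
#'   time matrix for a single trial.
#' @param rate Sampling rate (Hz).
#' @param time Time axis (s, relative to stimulus onset); defaults to
#'   samples starting at 0.
#' @param freqs Frequencies (Hz); default 27 linear bins over [3, 30].
#' @param n_cycles Cycles per frequency determining the window length.
#' @param time_bandwidth Time-bandwidth product (window duration times full
#'   bandwidth); controls taper count.
#' @param channels Channel labels.
#' @param average Average power across trials (default); otherwise the
#'   power array keeps a leading trial dimension.
#' @return A list of class `tfr`: `power` (channel x freq x time, or trial x
#'   channel x freq x time), `channels`, `freqs`, `time`, `rate`, `units`
#'   (`"power"`), `n_trials`, `params`.
#' @export
multitaper_tfr <- function(data, rate, time = NULL,
                           freqs = seq(3, 30, length.out = 27),
                           n_cycles = 3.5, time_bandwidth = 4,
                           channels = NULL, average = TRUE) {
  if (is.matrix(data)) data <- array(data, dim = c(1, dim(data)))
  stopifnot(length(dim(data)) == 3)
  n_trial <- dim(data)[1]; n_ch <- dim(data)[2]; n_time <- dim(data)[3]
  if (is.null(time)) time <- (seq_len(n_time) - 1) / rate
  if (is.null(channels)) channels <- sprintf("CH%03d", seq_len(n_ch))
  win_len <- round(n_cycles / freqs * rate)
  win_len <- win_len + (win_len + 1) %% 2  # odd lengths, symmetric center
  if (any(win_len > n_time)) {
    f_bad <- freqs[which.max(win_len)]
    stop(sprintf("epoch too short for the %.3g Hz analysis window (%d > %d samples)",
                 f_bad, max(win_len), n_time), call. = FALSE)
  }
  n_tapers <- max(1, floor(time_bandwidth) - 1)
  nw <- time_bandwidth / 2
  nfft <- .next_fast_len(n_time + max(win_len))
  # one forward FFT per signal, reused across frequencies and tapers
  sig <- matrix(0, nfft, n_trial * n_ch)
  sig[seq_len(n_time), ] <- t(matrix(data, n_trial * n_ch, n_time))
  sig_f <- stats::mvfft(sig)
  power <- array(0, dim = c(n_trial, n_ch, length(freqs), n_time))
  for (fi in seq_along(freqs)) {
    m <- win_len[fi]
    centre <- (m + 1) %/% 2
    tapers <- dpss_tapers(m, nw, n_tapers)
    s_rel <- seq_len(m) - centre
    demod <- exp(-2i * pi * freqs[fi] * s_rel / rate)
    acc <- matrix(0, n_time, n_trial * n_ch)
    for (k in seq_len(n_tapers)) {
      kern <- rev(tapers[, k] * demod)   # reversed: convolution = correlation
      kern_f <- stats::fft(c(kern, rep(0, nfft - m)))
      conv <- stats::mvfft(sig_f * kern_f, inverse = TRUE) / nfft
      acc <- acc + Mod(conv[centre:(centre + n_time - 1), , drop = FALSE])^2
    }
    power[, , fi, ] <- aperm(array(acc / n_tapers,
                                   dim = c(n_time, n_trial, n_ch)),
                             c(2, 3, 1))
  }
  if (average) {
    power <- array(colMeans(power), dim = dim(power)[-1])
  }
  structure(list(power = power, channels = channels, freqs = freqs,
                 time = time, rate = rate, units = "power",
                 n_trials = n_trial,
                 params = list(n_cycles = n_cycles,
                               time_bandwidth = time_bandwidth)),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d channel(s) x %d freq(s) [%g-%g Hz] x %d timepoint(s) [%g, %g] s; units: %s; %d trial(s)\n",
              length(x$channels), length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$time), x$time[1], x$time[length(x$time)], x$units,
              x$n_trials))
  invisible(x)
}

.tfr_power_dims <- function(tfr) {
  d <- dim(tfr$power)
  if (length(d) == 4) list(per_trial = TRUE, d = d) else
    list(per_trial = FALSE, d = d)
}

#' Percent-change baseline correction and cropping
#'
#' Converts power to percent change from the mean over a pre-onset baseline
#' window, per channel and frequency: 100 * (P(t) - mean_baseline) /
#' mean_baseline, then crops the epoch (both windows half-open). Bins with
#' zero baseline power are set to NA, flagged, and excluded pairwise from
#' downstream statistics.
#'
#' @param tfr A `tfr` in raw power units.
#' @param crop Retained window (s), default [-0.5, 3.0).
#' @param baseline Baseline window (s), default [-0.5, 0).
#' @return A `tfr` with `units = "percent"` and attribute `n_undefined`
#'   (count of zero-baseline bins).
#' @export
crop_and_baseline <- function(tfr, crop = c(-0.5, 3.0),
                              baseline = c(-0.5, 0)) {
  stopifnot(inherits(tfr, "tfr"), tfr$units == "power")
  bsel <- tfr$time >= baseline[1] & tfr$time < baseline[2]
  if (!any(bsel)) stop("baseline window lies outside the epoch", call. = FALSE)
  info <- .tfr_power_dims(tfr)
  p <- tfr$power
  if (!info$per_trial) p <- array(p, dim = c(1, dim(p)))
  d <- dim(p)
  mu <- rowMeans(matrix(p[, , , bsel, drop = FALSE], prod(d[1:3])))
  mu_arr <- array(mu, dim = d)  # recycles over time (last dim)
  out <- 100 * (p - mu_arr) / mu_arr
  n_undef <- sum(mu == 0)
  if (n_undef > 0) out[array(mu == 0, dim = d)] <- NA_real_
  csel <- tfr$time >= crop[1] & tfr$time < crop[2]
  out <- out[, , , csel, drop = FALSE]
  if (!info$per_trial) out <- array(out, dim = dim(out)[-1])
  res <- tfr
  res$power <- out
  res$time <- tfr$time[csel]
  res$units <- "percent"
  attr(res, "n_undefined") <- n_undef
  res
}

#' Downsample a TFR in time
#'
#' Non-overlapping bin means (default 20-ms bins); a trailing partial bin
#' is dropped. The new time axis holds the bin centers.
#'
#' @param tfr A `tfr`.
#' @param bin Bin width in seconds.
#' @return The downsampled `tfr`.
#' @export
downsample_time <- function(tfr, bin = 0.02) {
  dt <- tfr$time[2] - tfr$time[1]
  k <- round(bin / dt)
  if (k < 1) stop("bin is smaller than the native time step", call. = FALSE)
  n_time <- length(tfr$time)
  n_bins <- n_time %/% k
  if (n_bins < 1) stop("epoch shorter than one bin", call. = FALSE)
  idx <- rep(seq_len(n_bins), each = k)
  info <- .tfr_power_dims(tfr)
  p <- tfr$power
  if (!info$per_trial) p <- array(p, dim = c(1, dim(p)))
  d <- dim(p)
  p <- p[, , , seq_len(n_bins * k), drop = FALSE]
  # bin means along time: accumulate the k within-bin slices
  acc <- array(0, dim = c(d[1:3], n_bins))
  for (j in seq_len(k)) {
    acc <- acc + p[, , , seq(j, n_bins * k, by = k), drop = FALSE]
  }
  out <- acc / k
  if (!info$per_trial) out <- array(out, dim = dim(out)[-1])
  res <- tfr
  res$power <- out
  res$time <- tfr$time[seq(1, n_bins * k, by = k)] + (k - 1) * dt / 2
  res
}

#' Per-participant condition difference TFRs
#'
#' Computes, for each participant, the trial-averaged TFR difference
#' (A - B). Participants with fewer than `min_trials` trials in either
#' condition are excluded (a small-trial mean is unreliable) and reported.
#'
#' @param tfrs_a,tfrs_b Lists of trial-averaged `tfr` objects (one per
#'   participant, matched order); each must carry `n_trials`.
#' @param min_trials Minimal trial count per condition.
#' @param participants Optional participant ids.
#' @return A list with `diffs` (list of difference `tfr`s of retained
#'   participants), `participants` (retained ids) and `excluded` (ids).
#' @export
condition_tfr_contrast <- function(tfrs_a, tfrs_b, min_trials = 5,
                                   participants = NULL) {
  stopifnot(length(tfrs_a) == length(tfrs_b))
  n <- length(tfrs_a)
  if (is.null(participants)) participants <- sprintf("P%02d", seq_len(n))
  keep <- vapply(seq_len(n), function(i) {
    tfrs_a[[i]]$n_trials >= min_trials && tfrs_b[[i]]$n_trials >= min_trials
  }, logical(1))
  diffs <- lapply(which(keep), function(i) {
    a <- tfrs_a[[i]]; b <- tfrs_b[[i]]
    stopifnot(identical(dim(a$power), dim(b$power)),
              identical(a$units, b$units))
    d <- a
    d$power <- a$power - b$power
    d$units <- paste0(a$units, " difference")
    d$n_trials <- min(a$n_trials, b$n_trials)
    d
  })
  list(diffs = diffs, participants = participants[keep],
       excluded = participants[!keep])
}

#' Average a TFR over a band, window and channel set
#'
#' Mean power over the channels, the frequencies inside the band (band
#' edges inclusive) and the timepoints inside the half-open window.
#' NA bins (undefined percent change) are excluded.
#'
#' @param tfr A trial-averaged `tfr`.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param window Time window `c(start, end)` in s, half-open.
#' @param channels Channel labels to include (default all).
#' @return A scalar.
#' @export
band_average <- function(tfr, band = c(3, 8), window = c(1.0, 2.5),
                         channels = NULL) {
  info <- .tfr_power_dims(tfr)
  stopifnot(!info$per_trial)
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  tsel <- tfr$time >= window[1] & tfr$time < window[2]
  csel <- if (is.null(channels)) rep(TRUE, length(tfr$channels)) else
    tfr$channels %in% channels
  if (!any(fsel)) stop("no frequency bins inside the band", call. = FALSE)
  if (!any(tsel)) stop("no timepoints inside the window", call. = FALSE)
  mean(tfr$power[csel, fsel, tsel, drop = FALSE], na.rm = TRUE)
}
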