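# Shared fixtures: tiny event tables, quiet parameter sets, temp writers.

tiny_events <- function(onsets = c(10, 20.5), condition = "baseline",
                        emotion = "neutral", phase = "pre") {
  event_table(onsets, 10, phase,
              rep_len(condition, length(onsets)),
              rep_len(emotion, length(onsets)),
              sprintf("it%02d", seq_along(onsets)))
}

# deterministic, noise-free cardiac parameters with a single kernel cell
quiet_cardiac <- function(amplitude = -2.34, latency = 3.48, width = 1.5,
                          emotion = "neutral", ...) {
  cardiac_sim_params(
    noise_sd = 0, rsa_amp = 0, session_drift_bpm = 0,
    kernel_pre = data.frame(condition = "any", emotion = emotion,
                            amplitude = amplitude, latency = latency,
                            width = width, inhibition = FALSE),
    ...)
}

# constant-rate beat series helper
const_beats <- function(rr = 0.8, n = 100, t0 = 0) {
  beat_series(t0 + rr * (0:(n - 1)))
}

# a rate_series built directly from a function of time
rate_series_from <- function(f, from = 0, to = 40, grid_rate = 10) {
  tt <- seq(from, to, by = 1 / grid_rate)
  structure(list(time = tt, bpm = f(tt), grid_rate = grid_rate),
            class = "rate_series")
}

# small behavior table with known structure
toy_behavior <- function(n_items = 12, recall_p = c(think = 1, nothink = 0.75,
                                                    baseline = 11 / 12)) {
  design <- expand.grid(condition = c("think", "nothink", "baseline"),
                        emotion = c("disgust", "neutral"),
                        idx = seq_len(n_items), stringsAsFactors = FALSE)
  design$item_id <- sprintf("%s_%s_%02d", design$emotion, design$condition,
                            design$idx)
  design
}
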