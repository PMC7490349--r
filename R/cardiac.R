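# Evoked heart-rate analysis: beat series -> instantaneous rate ->
# baseline-referenced epochs -> per-participant evoked timecourses.

#' Flag artifactual R-R intervals
#'
#' Intervals outside [0.3, 2.0] s, or deviating more than 25% from the
#' running median of 11 intervals, are flagged as artifacts. Flagged
#' intervals are excluded from the interpolation support of
#' [instantaneous_rate()]. Thresholds are configurable; every rejection is
#' reported.
#'
#' @param beats A [beat_series()].
#' @param rr_bounds Physiological R-R bounds in seconds.
#' @param median_window Window (intervals) of the running median.
#' @param max_dev Maximal fractional deviation from the running median.
#' @param warn_frac Flag fraction above which a recording-level warning is
#'   emitted.
#' @param reject_frac Flag fraction above which the recording is rejected
#'   (error).
#' @return `beats` with attribute `artifacts`: a list with logical `flag`
#'   (per interval), `n_flagged` and `fraction`.
#' @export
reject_artifacts <- function(beats, rr_bounds = c(0.3, 2.0),
                             median_window = 11, max_dev = 0.25,
                             warn_frac = 0.25, reject_frac = 0.5) {
  rr <- beats$rr
  flag <- rr < rr_bounds[1] | rr > rr_bounds[2]
  if (length(rr) >= median_window) {
    med <- stats::runmed(rr, median_window, endrule = "median")
    flag <- flag | abs(rr - med) / med > max_dev
  }
  fraction <- mean(flag)
  if (fraction > reject_frac) {
    stop(sprintf("recording rejected: %.0f%% of R-R intervals flagged as artifacts",
                 100 * fraction), call. = FALSE)
  }
  if (fraction > warn_frac) {
    warning(sprintf("%.0f%% of R-R intervals flagged as artifacts",
                    100 * fraction), call. = FALSE)
  }
  attr(beats, "artifacts") <- list(flag = flag, n_flagged = sum(flag),
                                   fraction = fraction)
  beats
}

#' Instantaneous heart rate on a uniform grid
#'
#' Assigns the rate 60/RR (bpm) of each R-R interval to the interval's
#' midpoint and interpolates linearly onto a uniform grid, clipped to the
#' span of the midpoints. Intervals flagged by [reject_artifacts()] are
#' removed from the interpolation support, so the rate bridges over them.
#'
#' @param beats A [beat_series()], optionally carrying an `artifacts`
#'   attribute.
#' @param grid_rate Grid rate in Hz (default 10).
#' @return A list of class `rate_series` with `time` (s), `bpm` and
#'   `grid_rate`.
#' @export
instantaneous_rate <- function(beats, grid_rate = 10) {
  if (length(beats$beat_times) < 3) {
    stop("at least 3 beats are needed to estimate a rate curve",
         call. = FALSE)
  }
  mid <- (beats$beat_times[-1] + beats$beat_times[-length(beats$beat_times)]) / 2
  val <- 60 / beats$rr
  art <- attr(beats, "artifacts")
  if (!is.null(art)) {
    mid <- mid[!art$flag]
    val <- val[!art$flag]
    if (length(mid) < 2) stop("fewer than 2 clean R-R intervals", call. = FALSE)
  }
  dt <- 1 / grid_rate
  t0 <- ceiling(mid[1] / dt) * dt
  grid <- seq(t0, mid[length(mid)], by = dt)
  bpm <- stats::approx(mid, val, xout = grid, ties = "ordered")$y
  structure(list(time = grid, bpm = bpm, grid_rate = grid_rate),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d samples at %g Hz, %.3f-%.3f s, mean %.1f bpm\n",
              length(x$time), x$grid_rate, x$time[1], x$time[length(x$time)],
              mean(x$bpm)))
  invisible(x)
}

#' Epoch a rate series around stimulus onsets
#'
#' Cuts the rate curve into per-item epochs over `window` seconds relative
#' to onset (half-open) and references each epoch so that the baseline maps
#' to 0 bpm change: either the rate value at onset (default, matching
#' curves drawn with image onset as 0) or the mean rate over a pre-onset
#' window. Items whose epoch (or baseline) window is not fully covered by
#' the rate-curve support are rejected and reported.
#'
#' @param rate A `rate_series`.
#' @param events An [event_table()].
#' @param window Epoch window, seconds relative to onset, half-open.
#' @param baseline_policy `"onset"` or `"prewindow"`.
#' @param baseline_window Pre-onset window for the `"prewindow"` policy.
#' @param participant Participant id stored with the epochs.
#' @return A list of class `cardiac_epochs`: `participant`, `items` (tibble
#'   with `item_id`, `condition`, `emotion`, `phase`, `rejected`), `time`
#'   (epoch-relative, s), and `epochs` (item x time matrix of bpm change;
#'   rejected items hold NA).
#' @export
epoch_cardiac <- function(rate, events, window = c(0, 10),
                          baseline_policy = c("onset", "prewindow"),
                          baseline_window = c(-1, 0),
                          participant = NA_character_) {
  baseline_policy <- match.arg(baseline_policy)
  dt <- 1 / rate$grid_rate
  rel_time <- seq(window[1], window[2] - dt / 2, by = dt)
  n_ev <- nrow(events)
  epochs <- matrix(NA_real_, n_ev, length(rel_time))
  rejected <- logical(n_ev)
  support <- range(rate$time)
  for (i in seq_len(n_ev)) {
    on <- events$onset[i]
    need_lo <- on + if (baseline_policy == "prewindow") {
      min(window[1], baseline_window[1])
    } else min(window[1], 0)
    need_hi <- on + window[2] - dt / 2
    if (need_lo < support[1] || need_hi > support[2]) {
      rejected[i] <- TRUE
      next
    }
    vals <- stats::approx(rate$time, rate$bpm, xout = on + rel_time,
                          ties = "ordered")$y
    ref <- if (baseline_policy == "onset") {
      stats::approx(rate$time, rate$bpm, xout = on, ties = "ordered")$y
    } else {
      bl_t <- seq(baseline_window[1], baseline_window[2] - dt / 2, by = dt)
      mean(stats::approx(rate$time, rate$bpm, xout = on + bl_t,
                         ties = "ordered")$y)
    }
    epochs[i, ] <- vals - ref
  }
  if (all(rejected)) {
    stop("all items rejected: no epoch lies inside the rate-curve support",
         call. = FALSE)
  }
  items <- tibble::tibble(item_id = events$item_id,
                          condition = events$condition,
                          emotion = events$emotion,
                          phase = events$phase,
                          rejected = rejected)
  structure(list(participant = participant, items = items, time = rel_time,
                 epochs = epochs),
            class = "cardiac_epochs")
}

#' @export
print.cardiac_epochs <- function(x, ...) {
  cat(sprintf("<cardiac_epochs> participant %s: %d items (%d rejected), [%g, %g) s\n",
              x$participant, nrow(x$items), sum(x$items$rejected),
              x$time[1], x$time[length(x$time)] + diff(x$time[1:2])))
  invisible(x)
}

#' Average epochs into per-participant evoked timecourses
#'
#' Within each participant and each design cell (grouping labels),
#' unrejected item epochs are averaged into one curve; participant-level
#' curves are retained for statistics, and the grand mean across
#' participants is provided for display.
#'
#' @param epoch_list A list of `cardiac_epochs` (one per participant), or a
#'   single `cardiac_epochs`.
#' @param by Grouping labels among `"condition"`, `"emotion"`, `"phase"`.
#' @return A list of class `evoked_set`: `time`, and `cells`, a named list
#'   (one entry per observed label combination, named
#'   `"<condition>.<emotion>"` style) of participant x time matrices with
#'   participant ids as rownames; plus `grand`, the matching grand-mean
#'   curves.
#' @export
average_evoked <- function(epoch_list, by = c("condition", "emotion")) {
  if (inherits(epoch_list, "cardiac_epochs")) epoch_list <- list(epoch_list)
  stopifnot(length(epoch_list) > 0)
  time <- epoch_list[[1]]$time
  cells <- list()
  for (ep in epoch_list) {
    stopifnot(isTRUE(all.equal(ep$time, time)))
    keep <- !ep$items$rejected
    labels <- do.call(paste, c(ep$items[by], sep = "."))
    for (lab in unique(labels[keep])) {
      rows <- which(keep & labels == lab)
      curve <- colMeans(ep$epochs[rows, , drop = FALSE])
      m <- cells[[lab]]
      cells[[lab]] <- rbind(m, curve)
      rownames(cells[[lab]])[nrow(cells[[lab]])] <- as.character(ep$participant)
    }
  }
  grand <- lapply(cells, colMeans)
  structure(list(time = time, cells = cells, grand = grand, by = by),
            class = "evoked_set")
}

#' @export
print.evoked_set <- function(x, ...) {
  cat(sprintf("<evoked_set> %d cell(s) over [%g, %g) s:\n", length(x$cells),
              x$time[1], x$time[length(x$time)] + diff(x$time[1:2])))
  for (lab in names(x$cells)) {
    cat(sprintf("  %-24s n = %d\n", lab, nrow(x$cells[[lab]])))
  }
  invisible(x)
}

#' Tidy long-format view of an evoked set
#'
#' @param evoked An `evoked_set`.
#' @return A tibble with columns `participant`, `cell`, `time`,
#'   `bpm_change`.
#' @export
evoked_long <- function(evoked) {
  out <- lapply(names(evoked$cells), function(lab) {
    m <- evoked$cells[[lab]]
    tibble::tibble(participant = rep(rownames(m), each = ncol(m)),
                   cell = lab,
                   time = rep(evoked$time, nrow(m)),
                   bpm_change = as.vector(t(m)))
  })
  do.call(rbind, out)
}

#' Peak deflection of an evoked curve
#'
#' Returns the most extreme value in a search window and its latency.
#' Ties are resolved to the earliest timepoint.
#'
#' @param curve Numeric evoked curve (bpm change).
#' @param time Matching time axis (s).
#' @param window Search window, half-open; defaults to the full span.
#' @param direction `"min"` (deceleration peak) or `"max"`.
#' @return A list with `amplitude` (bpm) and `latency` (s).
#' @export
peak_deflection <- function(curve, time, window = NULL,
                            direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (is.null(window)) window <- c(time[1], time[length(time)] + Inf)
  sel <- which(time >= window[1] & time < window[2])
  if (!length(sel)) stop("empty search window", call. = FALSE)
  v <- curve[sel]
  i <- if (direction == "min") which.min(v) else which.max(v)
  list(amplitude = v[i], latency = time[sel[i]])
}
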