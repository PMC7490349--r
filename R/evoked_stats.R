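# Pointwise timecourse contrasts with FDR control, time-of-interest
# extraction, neutral-deceleration correction, and the per-participant
# cardiac inhibition score.

.tail_p <- function(t, df, tail) {
  switch(tail,
         two = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df))
}

#' Paired t test at every timepoint
#'
#' Runs a paired t test (A vs B) at each timepoint of two matched
#' participant x time matrices, then adjusts the per-timepoint p values with
#' the Benjamini-Hochberg step-up. Timepoints where the paired differences
#' have zero variance are flagged and assigned p = 1 rather than an
#' undefined statistic.
#'
#' @param a,b Participant x time matrices, rows matched by participant.
#' @param time Time axis (s).
#' @param tail `"two"`, `"greater"` (A > B) or `"less"`.
#' @param q FDR level.
#' @return A list of class `pointwise_test`: `time`, `t`, `p`, `p_fdr`,
#'   `mask_raw` (p <= q), `mask` (p_fdr <= q), `degenerate` (zero-variance
#'   flags), `tail`, `q`, `n`.
#' @export
pointwise_paired_t <- function(a, b, time = NULL,
                               tail = c("two", "greater", "less"),
                               q = 0.05) {
  tail <- match.arg(tail)
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a)
  if (n < 3) stop("paired pointwise test needs at least 3 participants",
                  call. = FALSE)
  if (is.null(time)) time <- seq_len(ncol(a))
  d <- a - b
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  # zero variance up to floating fuzz relative to the mean difference
  degenerate <- s <= .Machine$double.eps^0.75 * pmax(abs(m), 1)
  tstat <- ifelse(degenerate, 0, m / (s / sqrt(n)))
  p <- .tail_p(tstat, n - 1, tail)
  p[degenerate] <- 1
  adj <- fdr_bh(p, q)
  structure(list(time = time, t = tstat, p = p, p_fdr = adj$p_adj,
                 mask_raw = p <= q, mask = adj$mask, degenerate = degenerate,
                 tail = tail, q = q, n = n),
            class = "pointwise_test")
}

#' @export
print.pointwise_test <- function(x, ...) {
  cat(sprintf("<pointwise_test> %d timepoints, n = %d, tail = %s: %d significant after FDR (q = %g)\n",
              length(x$t), x$n, x$tail, sum(x$mask), x$q))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p values and significance mask
#'
#' Step-up false discovery rate control across a family of p values.
#'
#' @param p Vector of p values in [0, 1].
#' @param q FDR level for the mask.
#' @return A list with `p_adj` (monotone BH-adjusted p values) and `mask`
#'   (`p_adj <= q`).
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, mask = !is.na(p_adj) & p_adj <= q)
}

#' Extract the time of interest from a pointwise test
#'
#' The TOI is the longest contiguous run of significant timepoints (ties
#' resolved to the earliest run), reported as the half-open window from the
#' first to the last significant sample of that run. An alternative rule,
#' the span from first to last significant point overall, is available.
#'
#' @param result A `pointwise_test`.
#' @param which_mask `"fdr"` (default) or `"raw"`: boundary timepoints can
#'   be judged on either the corrected or the uncorrected mask, so both are
#'   available.
#' @param rule `"longest_run"` or `"span"`.
#' @return A numeric window `c(start, end)` in seconds, class
#'   `time_window`.
#' @export
extract_toi <- function(result, which_mask = c("fdr", "raw"),
                        rule = c("longest_run", "span")) {
  which_mask <- match.arg(which_mask)
  rule <- match.arg(rule)
  mask <- if (which_mask == "fdr") result$mask else result$mask_raw
  if (!any(mask)) {
    stop("no significant timepoints: cannot extract a time of interest",
         call. = FALSE)
  }
  if (rule == "span") {
    sel <- range(which(mask))
  } else {
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    cand <- which(runs$values)
    best <- cand[which.max(runs$lengths[cand])]  # which.max takes earliest tie
    sel <- c(starts[best], ends[best])
  }
  structure(c(result$time[sel[1]], result$time[sel[2]]),
            class = "time_window")
}

#' Subtract the mean neutral deceleration
#'
#' Per participant and timepoint, subtracts the mean of the neutral-scene
#' curves (averaged across think, no-think and baseline conditions) from
#' each emotional-condition curve, isolating the emotion-specific response
#' from the shared stimulus-processing deceleration.
#'
#' @param emotional Named list of participant x time matrices (one per
#'   condition), matched rows.
#' @param neutral Named list of participant x time matrices of the neutral
#'   conditions.
#' @return Named list of corrected matrices, same shape as `emotional`.
#' @export
neutral_correct <- function(emotional, neutral) {
  stopifnot(length(neutral) >= 1)
  ref <- Reduce(`+`, neutral) / length(neutral)
  lapply(emotional, function(m) {
    stopifnot(identical(dim(m), dim(ref)))
    m - ref
  })
}

#' Window-mean contrast between two conditions
#'
#' Averages each participant's curve over a time of interest and contrasts
#' the two conditions with a paired t test and Cohen's d
#' (mean difference / SD of differences, so that d = t / sqrt(n)).
#'
#' @param a,b Participant x time matrices, rows matched.
#' @param time Time axis (s).
#' @param toi Time window `c(start, end)`, half-open.
#' @param tail Test tail.
#' @return A list with `per_participant` (tibble of window means and
#'   differences), `t`, `df`, `p`, `d`, `degenerate`.
#' @export
toi_contrast <- function(a, b, time, toi, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  sel <- time >= toi[1] & time < toi[2]
  if (!any(sel)) stop("time of interest lies outside the epoch span",
                      call. = FALSE)
  ma <- rowMeans(a[, sel, drop = FALSE])
  mb <- rowMeans(b[, sel, drop = FALSE])
  d_i <- ma - mb
  n <- length(d_i)
  s <- stats::sd(d_i)
  degenerate <- is.na(s) || s == 0
  tstat <- if (degenerate) 0 else mean(d_i) / (s / sqrt(n))
  p <- if (degenerate) 1 else .tail_p(tstat, n - 1, tail)
  eff <- if (degenerate) 0 else mean(d_i) / s
  list(per_participant = tibble::tibble(participant = rownames(a) %||%
                                          as.character(seq_len(n)),
                                        mean_a = ma, mean_b = mb, diff = d_i),
       t = tstat, df = n - 1, p = p, d = eff, degenerate = degenerate)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Per-participant cardiac inhibition score
#'
#' The inhibition score is the mean bpm change difference (No-Think minus
#' Baseline) over the intersection of the emotional time of interest
#' (pre-TNT negative-vs-neutral window) and the suppression window
#' (post-TNT No-Think-vs-Baseline window). Positive scores indicate a
#' blunted deceleration for suppressed items.
#'
#' @param nt,bl Participant x time matrices (No-Think and Baseline curves),
#'   rows matched.
#' @param time Time axis (s).
#' @param emotional_toi,suppression_toi The two windows `c(start, end)`.
#' @return A tibble with `participant`, `score` (bpm), and the window used
#'   as attributes `window`.
#' @export
inhibition_score <- function(nt, bl, time, emotional_toi = c(1.89, 5.03),
                             suppression_toi = c(2.41, 10)) {
  lo <- max(emotional_toi[1], suppression_toi[1])
  hi <- min(emotional_toi[2], suppression_toi[2])
  if (lo >= hi) {
    stop(sprintf("emotional window [%g, %g) and suppression window [%g, %g) do not intersect",
                 emotional_toi[1], emotional_toi[2],
                 suppression_toi[1], suppression_toi[2]), call. = FALSE)
  }
  sel <- time >= lo & time < hi
  scores <- rowMeans(nt[, sel, drop = FALSE]) -
    rowMeans(bl[, sel, drop = FALSE])
  out <- tibble::tibble(participant = rownames(nt) %||%
                          as.character(seq_along(scores)),
                        score = unname(scores))
  attr(out, "window") <- c(lo, hi)
  out
}
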