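# TNT behavioral indices: criterion exclusion, intrusion timecourses,
# recall and suppression scores, valence change, and the participant group
# splits used to stratify cardiac effects.

.check_behavior <- function(records, cols) {
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop(sprintf("behavior table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

#' Exclude items that failed the pre-TNT criterion test
#'
#' Items not correctly recalled on the criterion test before the TNT phase
#' are removed from all downstream analyses.
#'
#' @param records Behavior tibble (one row per participant x item) with a
#'   0/1 `criterion` column.
#' @return The retained rows, with attribute `exclusions`: a list with
#'   `n_excluded` and `fraction`.
#' @export
criterion_exclude <- function(records) {
  .check_behavior(records, "criterion")
  keep <- records$criterion == 1
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- list(n_excluded = sum(!keep),
                                  fraction = mean(!keep))
  out
}

#' Intrusion proportion per TNT block
#'
#' For each participant, averages the binary per-trial intrusion reports of
#' No-Think items of the requested emotion within each block.
#'
#' @param records Behavior tibble with `intr_b1` ... block columns.
#' @param emotion Emotion to select (`NULL` for all).
#' @return A tibble with `participant`, `block`, `proportion`.
#' @export
intrusion_timecourse <- function(records, emotion = NULL) {
  block_cols <- grep("^intr_b\\d+$", names(records), value = TRUE)
  if (!length(block_cols)) stop("no intrusion report columns found",
                                call. = FALSE)
  block_cols <- block_cols[order(as.integer(sub("intr_b", "", block_cols)))]
  rows <- records$condition == "nothink"
  if (!is.null(emotion)) rows <- rows & records$emotion == emotion
  sub <- records[rows, , drop = FALSE]
  out <- lapply(split(sub, sub$participant), function(d) {
    tibble::tibble(participant = d$participant[1],
                   block = seq_along(block_cols),
                   proportion = vapply(block_cols,
                                       function(cl) mean(d[[cl]]),
                                       numeric(1), USE.NAMES = FALSE))
  })
  do.call(rbind, unname(out))
}

#' Recall percentages and suppression score
#'
#' Percent recalled per condition x emotion per participant, over retained
#' items, plus the suppression-induced forgetting score: No-Think minus
#' Baseline recall in percentage points (negative = forgetting induced by
#' suppression).
#'
#' @param records Behavior tibble with a 0/1 `recall` column (already
#'   criterion-filtered).
#' @return A list with `recall` (tibble participant x condition x emotion:
#'   `n_items`, `pct_recalled`) and `suppression` (tibble per participant x
#'   emotion: `score_pp`).
#' @export
recall_scores <- function(records) {
  .check_behavior(records, c("recall", "condition", "emotion"))
  grp <- interaction(records$participant, records$condition, records$emotion,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, grp), function(d) {
    tibble::tibble(participant = d$participant[1], condition = d$condition[1],
                   emotion = d$emotion[1], n_items = nrow(d),
                   pct_recalled = 100 * mean(d$recall))
  }))
  rownames(agg) <- NULL
  agg <- tibble::as_tibble(agg)
  nt <- agg[agg$condition == "nothink", ]
  bl <- agg[agg$condition == "baseline", ]
  key <- function(d) paste(d$participant, d$emotion)
  m <- match(key(nt), key(bl))
  supp <- tibble::tibble(participant = nt$participant, emotion = nt$emotion,
                         score_pp = nt$pct_recalled - bl$pct_recalled[m])
  list(recall = agg, suppression = supp)
}

#' Split participants by suppression-induced forgetting
#'
#' Participants who forgot at least one retained No-Think item of the given
#' emotion form the forgetting-present group; participants who recalled all
#' of them form the forgetting-absent group.
#'
#' @param records Behavior tibble (criterion-filtered).
#' @param emotion Emotion on which the split is based.
#' @param correct_by_baseline If `TRUE`, the forgotten No-Think count is
#'   first corrected by the participant's baseline forgetting (No-Think
#'   minus Baseline forgotten items); the group criterion then applies to
#'   the corrected count. This isolates suppression-induced forgetting
#'   from general forgetting, at the cost of smaller groups.
#' @return A tibble with `participant`, `n_forgotten`, `label`
#'   (`"forgetting_present"` / `"forgetting_absent"`).
#' @export
split_by_forgetting <- function(records, emotion = "disgust",
                                correct_by_baseline = FALSE) {
  sub <- records[records$condition == "nothink" &
                   records$emotion == emotion, , drop = FALSE]
  if (!nrow(sub)) stop("no no-think items of that emotion", call. = FALSE)
  bl <- records[records$condition == "baseline" &
                  records$emotion == emotion, , drop = FALSE]
  out <- do.call(rbind, lapply(split(sub, sub$participant), function(d) {
    nf <- sum(d$recall == 0)
    if (correct_by_baseline) {
      nf <- nf - sum(bl$recall[bl$participant == d$participant[1]] == 0)
    }
    tibble::tibble(participant = d$participant[1], n_forgotten = nf,
                   label = if (nf >= 1) "forgetting_present" else
                     "forgetting_absent")
  }))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Median split on cardiac inhibition scores
#'
#' Participants above the median score are labelled high inhibition, the
#' rest (including exact-median values: ties go to the low group, a
#' deterministic and conservative rule for the high-inhibition contrast)
#' low inhibition.
#'
#' @param scores Tibble with `participant` and `score` (see
#'   [inhibition_score()]), or a named numeric vector.
#' @param tie `"low"` (default) or `"high"`: group receiving exact-median
#'   values.
#' @return A tibble with `participant`, `score`, `label`
#'   (`"high_inhibition"` / `"low_inhibition"`).
#' @export
median_split <- function(scores, tie = c("low", "high")) {
  tie <- match.arg(tie)
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      participant = names(scores) %||% as.character(seq_along(scores)),
      score = unname(scores))
  }
  if (nrow(scores) < 2) stop("median split needs at least 2 participants",
                             call. = FALSE)
  med <- stats::median(scores$score)
  high <- if (tie == "low") scores$score > med else scores$score >= med
  tibble::tibble(participant = scores$participant, score = scores$score,
                 label = ifelse(high, "high_inhibition", "low_inhibition"))
}

#' Valence change per condition
#'
#' Post-TNT minus pre-TNT valence ratings, averaged within condition x
#' emotion per participant (item-level normalization by the pre rating).
#'
#' @param records Behavior tibble with `valence_pre` and `valence_post`.
#' @return A tibble with `participant`, `condition`, `emotion`,
#'   `mean_change`.
#' @export
valence_change <- function(records) {
  .check_behavior(records, c("valence_pre", "valence_post"))
  ok <- !is.na(records$valence_pre) & !is.na(records$valence_post)
  sub <- records[ok, , drop = FALSE]
  stopifnot(all(sub$valence_pre >= 1 & sub$valence_pre <= 9),
            all(sub$valence_post >= 1 & sub$valence_post <= 9))
  grp <- interaction(sub$participant, sub$condition, sub$emotion, drop = TRUE)
  out <- do.call(rbind, lapply(split(sub, grp), function(d) {
    tibble::tibble(participant = d$participant[1], condition = d$condition[1],
                   emotion = d$emotion[1],
                   mean_change = mean(d$valence_post - d$valence_pre))
  }))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
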