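#' @keywords internal
"_PACKAGE"

# Time conventions used throughout the package:
#  - all absolute times are seconds from recording start;
#  - epoch-relative times are seconds from stimulus onset (onset = 0);
#  - every time window is half-open [start, end).

.canonical_conditions <- c("think", "nothink", "baseline")
.canonical_emotions <- c("disgust", "sad", "neutral")
.canonical_phases <- c("pre", "post")

.canon_label <- function(x, allowed, what, strip = TRUE) {
  x <- tolower(as.character(x))
  if (strip) x <- gsub("[^a-z]", "", x)
  bad <- !(x %in% allowed)
  if (any(bad)) {
    stop(sprintf("invalid %s label(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Create a heartbeat series
#'
#' A beat series stores the times of successive heartbeats (R peaks) in
#' seconds from the start of the recording, together with the derived R-R
#' intervals.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @return An object of class `beat_series` with elements `beat_times` and
#'   `rr` (successive differences, in seconds; one fewer than the beats).
#' @export
beat_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) == 0) stop("beat series is empty", call. = FALSE)
  if (anyNA(beat_times)) stop("beat times contain NA", call. = FALSE)
  rr <- diff(beat_times)
  if (any(rr <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  structure(list(beat_times = beat_times, rr = rr), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats spanning %.3f-%.3f s (mean RR %.3f s)\n",
              length(x$beat_times), x$beat_times[1],
              x$beat_times[length(x$beat_times)],
              if (length(x$rr)) mean(x$rr) else NA_real_))
  invisible(x)
}

#' Create an event table
#'
#' Validates and canonicalizes a table of stimulus events. Labels are
#' case-insensitive on input and stored lower-case.
#'
#' @param onset Numeric onset times (s from recording start), non-decreasing.
#' @param duration Numeric durations in seconds (scene presentations last 10 s).
#' @param phase `"pre"` or `"post"` (relative to the TNT task).
#' @param condition `"think"`, `"nothink"` or `"baseline"`.
#' @param emotion `"disgust"`, `"sad"` or `"neutral"`.
#' @param item_id Character item identifiers; each item must map to a single
#'   (condition, emotion) pair.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(onset, duration, phase, condition, emotion, item_id) {
  onset <- as.numeric(onset)
  if (anyNA(onset)) stop("event onsets contain NA", call. = FALSE)
  if (is.unsorted(onset)) {
    stop("event onsets must be non-decreasing", call. = FALSE)
  }
  tbl <- tibble::tibble(
    onset = onset,
    duration = as.numeric(duration),
    phase = .canon_label(phase, .canonical_phases, "phase"),
    condition = .canon_label(condition, .canonical_conditions, "condition"),
    emotion = .canon_label(emotion, .canonical_emotions, "emotion"),
    item_id = as.character(item_id)
  )
  cell <- paste(tbl$condition, tbl$emotion)
  n_cells <- tapply(cell, tbl$item_id, function(z) length(unique(z)))
  if (any(n_cells > 1)) {
    stop(sprintf("item(s) mapped to more than one condition/emotion: %s",
                 paste(names(n_cells)[n_cells > 1], collapse = ", ")),
         call. = FALSE)
  }
  class(tbl) <- c("event_table", class(tbl))
  tbl
}

#' Read a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset`, `duration`,
#' `phase`, `condition`, `emotion`, `item_id`.
#'
#' @param path Path to the TSV file.
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  required <- c("onset", "duration", "phase", "condition", "emotion", "item_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("events file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  onset <- suppressWarnings(as.numeric(raw$onset))
  if (anyNA(onset)) {
    stop(sprintf("non-numeric onset at line %d of %s",
                 which(is.na(onset))[1] + 1L, path), call. = FALSE)
  }
  duration <- suppressWarnings(as.numeric(raw$duration))
  if (anyNA(duration)) {
    stop(sprintf("non-numeric duration at line %d of %s",
                 which(is.na(duration))[1] + 1L, path), call. = FALSE)
  }
  event_table(onset, duration, raw$phase, raw$condition, raw$emotion,
              raw$item_id)
}

#' Write an events table
#'
#' Times are written at microsecond precision, below any physiological
#' effect of interest, so a write/read round trip is value-exact.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    onset = sprintf("%.6f", events$onset),
    duration = sprintf("%.6f", events$duration),
    phase = events$phase,
    condition = events$condition,
    emotion = events$emotion,
    item_id = events$item_id
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beat-series file
#'
#' A beats file holds one value per line after a single header line, which is
#' either `times` (values are beat times in seconds) or `rr t0=<sec>`
#' (values are R-R intervals in seconds, reconstructed by cumulative sum from
#' the declared first-beat time). Acquisition exports differ in which of the
#' two they provide, so both are accepted.
#'
#' @param path Path to the file.
#' @return A [beat_series()].
#' @export
read_beats <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop(sprintf("beats file %s is empty", path),
                              call. = FALSE)
  header <- trimws(lines[1])
  values <- suppressWarnings(as.numeric(lines[-1]))
  if (anyNA(values)) {
    stop(sprintf("non-numeric value at line %d of %s",
                 which(is.na(values))[1] + 1L, path), call. = FALSE)
  }
  if (identical(header, "times")) {
    return(beat_series(values))
  }
  if (grepl("^rr\\s+t0=", header)) {
    t0 <- as.numeric(sub("^rr\\s+t0=", "", header))
    if (is.na(t0)) stop(sprintf("unparseable t0 in header of %s", path),
                        call. = FALSE)
    bad <- which(values <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive R-R interval at line %d of %s",
                   bad[1] + 1L, path), call. = FALSE)
    }
    return(beat_series(c(t0, t0 + cumsum(values))))
  }
  stop(sprintf("unrecognized beats header '%s' in %s (expected 'times' or 'rr t0=<sec>')",
               header, path), call. = FALSE)
}

#' Write a beat series
#'
#' @param beats A [beat_series()].
#' @param path Output path.
#' @param mode `"times"` to write beat times, `"rr"` to write R-R intervals
#'   with the first beat time declared in the header.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path, mode = c("times", "rr")) {
  mode <- match.arg(mode)
  if (mode == "times") {
    lines <- c("times", sprintf("%.6f", beats$beat_times))
  } else {
    lines <- c(sprintf("rr t0=%.6f", beats$beat_times[1]),
               sprintf("%.6f", beats$rr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an epoch tensor with its JSON sidecar
#'
#' Epoch tensors are stored as whitespace-separated plain text: one line per
#' (trial, channel) pair in trial-major order, each line holding `n_time`
#' samples. The JSON sidecar declares `dims` (trial, channel, time), the
#' sampling `rate` in Hz, the epoch start `t0` in seconds relative to
#' stimulus onset, and the channel labels.
#'
#' @param path Path to the text array file.
#' @param sidecar Path to the JSON sidecar.
#' @return A list with `data` (array trial x channel x time), `channels`,
#'   `time` (s, relative to onset) and `rate` (Hz).
#' @export
read_epochs <- function(path, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("dims", "rate", "t0")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("sidecar %s is missing field '%s'", sidecar, field),
           call. = FALSE)
    }
  }
  dims <- as.integer(meta$dims)
  if (length(dims) != 3) stop("sidecar dims must have length 3 (trial, channel, time)",
                              call. = FALSE)
  values <- scan(path, what = numeric(), quiet = TRUE)
  if (length(values) != prod(dims)) {
    stop(sprintf("epoch file %s holds %d values but sidecar declares dims %s (= %d values)",
                 path, length(values), paste(dims, collapse = "x"),
                 prod(dims)), call. = FALSE)
  }
  # file layout: line = (trial, channel), fastest axis on disk = time
  data <- aperm(array(values, dim = c(dims[3], dims[2], dims[1])), c(3, 2, 1))
  channels <- if (!is.null(meta$channels)) as.character(meta$channels) else
    sprintf("CH%03d", seq_len(dims[2]))
  time <- meta$t0 + (seq_len(dims[3]) - 1L) / meta$rate
  list(data = data, channels = channels, time = time, rate = meta$rate)
}

#' Write an epoch tensor with its JSON sidecar
#'
#' @param data Numeric array, trial x channel x time.
#' @param channels Channel labels.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to onset.
#' @param path,sidecar Output paths for the array and the JSON sidecar.
#' @param digits Significant digits written per sample.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(data, channels, rate, t0, path, sidecar,
                         digits = 6) {
  dims <- dim(data)
  stopifnot(length(dims) == 3, length(channels) == dims[2])
  flat <- aperm(data, c(3, 2, 1))  # time fastest on disk
  mat <- matrix(signif(flat, digits), nrow = dims[3])
  lines <- apply(mat, 2, paste, collapse = " ")
  writeLines(lines, path)
  jsonlite::write_json(
    list(dims = dims, rate = rate, t0 = t0, channels = channels),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel adjacency list
#'
#' Two-column TSV of channel label pairs declared spatial neighbors. The
#' relation is symmetrized on read; self-pairs are rejected.
#'
#' @param path Path to the TSV (columns `a`, `b`, header optional).
#' @param channels Optional full channel set; every label in the file must
#'   belong to it.
#' @return An object of class `adjacency_list`: a list with `channels` and a
#'   two-column character matrix `pairs`.
#' @export
read_adjacency <- function(path, channels = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (identical(tolower(raw[1, 1]), "a")) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 2) stop("adjacency file must have two columns", call. = FALSE)
  adjacency_list(as.matrix(raw[, 1:2]), channels = channels)
}

#' Construct an adjacency list from label pairs
#'
#' @param pairs Two-column character matrix of neighbor label pairs.
#' @param channels Optional full channel set.
#' @return An `adjacency_list` object.
#' @export
adjacency_list <- function(pairs, channels = NULL) {
  pairs <- matrix(as.character(pairs), ncol = 2)
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("adjacency list contains self-pairs", call. = FALSE)
  }
  labels <- unique(c(pairs))
  if (is.null(channels)) {
    channels <- sort(labels)
  } else if (!all(labels %in% channels)) {
    stop(sprintf("adjacency labels not in channel set: %s",
                 paste(setdiff(labels, channels), collapse = ", ")),
         call. = FALSE)
  }
  # symmetrize and deduplicate
  both <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  both <- both[!duplicated(paste(both[, 1], both[, 2])), , drop = FALSE]
  structure(list(channels = channels, pairs = both), class = "adjacency_list")
}

#' Write an adjacency list
#'
#' @param adj An `adjacency_list`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  keep <- adj$pairs[adj$pairs[, 1] < adj$pairs[, 2], , drop = FALSE]
  utils::write.table(data.frame(a = keep[, 1], b = keep[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable constants of the pipeline with their defaults: the
#' 10 Hz interpolation grid for instantaneous heart rate, the [0, 10) s
#' cardiac epoch, the onset-value baseline policy, FDR level q = 0.05, the
#' cluster-forming threshold 2.5, 1024 permutations, linear 27-bin frequency
#' axis over [3, 30] Hz and the four canonical frequency bands.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    grid_rate = 10,                 # Hz, instantaneous-rate grid
    epoch_window = c(0, 10),        # s relative to onset, half-open
    baseline_policy = "onset",      # "onset" or "prewindow"
    baseline_window = c(-1, 0),     # used by the "prewindow" policy
    fdr_q = 0.05,
    cluster_threshold = 2.5,
    n_perm = 1024L,
    seed = NULL,
    freqs = seq(3, 30, length.out = 27),
    bands = list(theta = c(3, 8), alpha = c(8, 12),
                 low_beta = c(13, 20), high_beta = c(20, 30)),
    n_cycles = 3.5,
    time_bandwidth = 4
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$grid_rate > 0,
            cfg$epoch_window[1] < cfg$epoch_window[2],
            length(cfg$bands) > 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a keyed text file
#'
#' Accepts a minimal INI-style file of `key = value` lines (`#` comments
#' allowed). Vector values are comma-separated; band definitions use keys
#' `band.<name> = lo, hi`.
#'
#' @param path Path to the config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  overrides <- list()
  bands <- list()
  for (ln in lines) {
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    if (anyNA(parsed)) parsed <- trimws(strsplit(val, ",")[[1]])
    if (startsWith(key, "band.")) {
      bands[[sub("^band\\.", "", key)]] <- parsed
    } else {
      overrides[[key]] <- parsed
    }
  }
  if (length(bands)) overrides$bands <- bands
  do.call(run_config, overrides)
}
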