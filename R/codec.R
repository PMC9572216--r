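#' One multiplexed insole sample
#'
#' A frame is one 40 Hz sample from one insole: a timestamp, the foot side
#' and the 24 multiplexed ADC counts (16 pressure channels followed by 8
#' temperature channels, in the canonical order declared by the sensor
#' layout; the codec never reorders channels).
#'
#' @param timestamp Seconds since trial start (non-negative).
#' @param foot `"L"` or `"R"`.
#' @param pressure_adc Integer vector of 16 pressure-channel ADC counts.
#' @param temperature_adc Integer vector of 8 temperature-channel ADC counts.
#' @param cfg Optional [divider_config()]; when given, counts are range
#'   checked against `[0, adc_max]`.
#' @return Object of class `insole_frame`.
#' @export
insole_frame <- function(timestamp, foot, pressure_adc, temperature_adc,
                         cfg = NULL) {
  stopifnot(is.numeric(timestamp), length(timestamp) == 1, timestamp >= 0)
  foot <- match.arg(foot, c("L", "R"))
  if (length(pressure_adc) != 16)
    stop("a frame carries exactly 16 pressure channels (got ",
         length(pressure_adc), ")")
  if (length(temperature_adc) != 8)
    stop("a frame carries exactly 8 temperature channels (got ",
         length(temperature_adc), ")")
  counts <- c(pressure_adc, temperature_adc)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop("ADC counts must be non-negative integers")
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "divider_config"))
    if (any(counts > cfg$adc_max))
      stop(sprintf("ADC count %d above full scale %d",
                   max(counts), cfg$adc_max))
  }
  structure(list(timestamp = as.numeric(timestamp), foot = foot,
                 pressure_adc = as.integer(pressure_adc),
                 temperature_adc = as.integer(temperature_adc)),
            class = "insole_frame")
}

#' A logged insole trial
#'
#' A time-ordered sequence of frames from one insole at a fixed sampling
#' rate, stored as a data frame with columns `timestamp`, `foot`,
#' `p01`..`p16` (pressure ADC counts) and `t01`..`t08` (temperature ADC
#' counts). Timestamps must be strictly increasing with spacing
#' `1/sampling_rate`.
#'
#' @param frames Data frame in the column layout above (may have 0 rows).
#' @param sampling_rate Sampling rate in Hz (default 40).
#' @param subject Optional [subject_profile()].
#' @param trial_id Trial identifier string.
#' @param foot `"L"` or `"R"` (must match the frames).
#' @return Object of class `insole_trial`.
#' @export
insole_trial <- function(frames, sampling_rate = 40, subject = NULL,
                         trial_id = "trial", foot = c("L", "R")) {
  foot <- match.arg(foot)
  cols <- trial_columns()
  stopifnot(is.data.frame(frames))
  if (!all(cols %in% names(frames)))
    stop("`frames` must have columns: ", paste(cols, collapse = ", "))
  frames <- frames[, cols]
  if (nrow(frames)) {
    if (!all(frames$foot == foot)) stop("frame foot tags disagree with `foot`")
    dt <- diff(frames$timestamp)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / sampling_rate) > 1e-6))
      stop("timestamp spacing must equal 1/sampling_rate")
  }
  structure(list(frames = frames, sampling_rate = sampling_rate,
                 subject = subject, trial_id = trial_id, foot = foot),
            class = "insole_trial")
}

trial_columns <- function() {
  c("timestamp", "foot", sprintf("p%02d", 1:16), sprintf("t%02d", 1:8))
}

#' @export
print.insole_trial <- function(x, ...) {
  cat(sprintf("<insole_trial> '%s' foot %s: %d frames @ %g Hz (%.2f s)\n",
              x$trial_id, x$foot, nrow(x$frames), x$sampling_rate,
              if (nrow(x$frames)) nrow(x$frames) / x$sampling_rate else 0))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial An [insole_trial()].
#' @return Integer frame count.
#' @export
n_frames <- function(trial) {
  stopifnot(inherits(trial, "insole_trial"))
  nrow(trial$frames)
}

# ---- frame line codec -------------------------------------------------------

# Serialized line: timestamp(3 dp),foot,16 pressure counts,8 temperature
# counts. Header metadata (schema version, server/characteristic identifiers)
# travels once per stream, never per line.

#' Encode one frame as a delimited line
#'
#' Serializes a frame to the single-string wire format used by the logger:
#' comma-separated `timestamp` (3 decimals), foot tag, 16 pressure counts,
#' then 8 temperature counts.
#'
#' @param frame An [insole_frame()].
#' @return A single character line (no trailing newline).
#' @examples
#' f <- insole_frame(0, "L", 1:16, 17:24)
#' encode_frame(f)
#' @export
encode_frame <- function(frame) {
  stopifnot(inherits(frame, "insole_frame"))
  paste(c(sprintf("%.3f", frame$timestamp), frame$foot,
          frame$pressure_adc, frame$temperature_adc), collapse = ",")
}

#' Decode one serialized frame line
#'
#' Parses a line of the wire format back into a validated frame. Malformed
#' lines are rejected with a message naming the problem: a wrong channel
#' count, a non-numeric field (with its position) or a count above the ADC
#' full scale.
#'
#' @param line One character line.
#' @param cfg A [divider_config()] used for range validation.
#' @return An [insole_frame()].
#' @export
decode_frame <- function(line, cfg = divider_config()) {
  stopifnot(is.character(line), length(line) == 1)
  fields <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
  n_chan <- length(fields) - 2L
  if (n_chan != 24L)
    stop(sprintf("malformed frame: expected 24 channel fields, got %d", n_chan))
  ts <- suppressWarnings(as.numeric(fields[1]))
  if (is.na(ts)) stop("parse error at field 1: timestamp is not numeric")
  foot <- fields[2]
  if (!foot %in% c("L", "R"))
    stop("parse error at field 2: foot tag must be 'L' or 'R'")
  counts <- suppressWarnings(as.numeric(fields[-(1:2)]))
  if (anyNA(counts))
    stop(sprintf("parse error at field %d: '%s' is not numeric",
                 which(is.na(counts))[1] + 2L,
                 fields[which(is.na(counts))[1] + 2L]))
  if (any(counts > cfg$adc_max))
    stop(sprintf("ADC count %g above full scale %d (field %d)",
                 max(counts), cfg$adc_max,
                 which.max(counts) + 2L))
  insole_frame(ts, foot, counts[1:16], counts[17:24], cfg = cfg)
}

# ---- trial log files --------------------------------------------------------

log_schema_version <- "insole-log/1"

#' Write a trial to a delimited log file
#'
#' Plain-text, UTF-8, comma-delimited log: `#`-prefixed header lines carry
#' the stream metadata (schema version, server and characteristic identifier
#' stand-ins, sampling rate, trial id, foot, subject), one CSV header line
#' names the columns, then one encoded frame per line. Counts are stored as
#' integers and timestamps at 3 decimals, so a read-back reproduces the
#' trial exactly.
#'
#' @param trial An [insole_trial()].
#' @param path Output file path.
#' @param server_id,characteristic_id Stream identifier strings carried once
#'   in the header (stand-ins for the radio service identifiers).
#' @return `path`, invisibly.
#' @export
write_log <- function(trial, path, server_id = "insole-peripheral",
                      characteristic_id = "frame-stream") {
  stopifnot(inherits(trial, "insole_trial"))
  header <- c(
    paste0("#schema ", log_schema_version),
    paste0("#server ", server_id),
    paste0("#characteristic ", characteristic_id),
    paste0("#sampling_rate ", format(trial$sampling_rate)),
    paste0("#trial_id ", trial$trial_id),
    paste0("#foot ", trial$foot)
  )
  if (!is.null(trial$subject))
    header <- c(header, paste0("#subject ", format_subject(trial$subject)))
  lines <- character(nrow(trial$frames))
  fr <- trial$frames
  if (nrow(fr)) {
    counts <- as.matrix(fr[, c(sprintf("p%02d", 1:16), sprintf("t%02d", 1:8))])
    lines <- paste(sprintf("%.3f", fr$timestamp), fr$foot,
                   apply(counts, 1, paste, collapse = ","), sep = ",")
  }
  writeLines(c(header, paste(trial_columns(), collapse = ","), lines), path)
  invisible(path)
}

#' Read a trial back from a log file
#'
#' Inverse of [write_log()]. A truncated final line (e.g. an interrupted
#' acquisition) is dropped with a warning rather than failing the whole
#' trial.
#'
#' @param path Log file path.
#' @param cfg A [divider_config()] used to range-check counts.
#' @return An [insole_trial()].
#' @export
read_log <- function(path, cfg = divider_config()) {
  if (!file.exists(path)) stop("log file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- function(key, default = NULL) {
    hit <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (!length(hit)) return(default)
    sub(paste0("^#", key, " "), "", hit[1])
  }
  if (!identical(meta("schema"), log_schema_version))
    stop("unrecognized log schema in ", path)
  rate <- as.numeric(meta("sampling_rate", "40"))
  trial_id <- meta("trial_id", "trial")
  foot <- meta("foot", "L")
  subject <- parse_subject(meta("subject"))
  if (!length(body)) stop("log file has no column header: ", path)
  if (body[1] != paste(trial_columns(), collapse = ","))
    stop("unexpected column header in ", path)
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  frames <- empty_frames()
  if (length(data_lines)) {
    # drop a truncated trailing record rather than rejecting the trial
    n_fields <- lengths(strsplit(data_lines, ",", fixed = TRUE))
    if (n_fields[length(n_fields)] != 26L) {
      warning("dropping truncated final frame in ", path)
      data_lines <- data_lines[-length(data_lines)]
    }
    if (length(data_lines)) {
      parsed <- lapply(data_lines, decode_frame, cfg = cfg)
      frames <- frames_to_df(parsed)
    }
  }
  insole_trial(frames, sampling_rate = rate, subject = subject,
               trial_id = trial_id, foot = foot)
}

empty_frames <- function() {
  df <- c(list(timestamp = numeric(0), foot = character(0)),
          stats::setNames(rep(list(integer(0)), 24),
                          c(sprintf("p%02d", 1:16), sprintf("t%02d", 1:8))))
  as.data.frame(df, stringsAsFactors = FALSE)
}

frames_to_df <- function(frames) {
  df <- data.frame(
    timestamp = vapply(frames, `[[`, numeric(1), "timestamp"),
    foot = vapply(frames, `[[`, character(1), "foot"),
    stringsAsFactors = FALSE
  )
  p <- t(vapply(frames, `[[`, integer(16), "pressure_adc"))
  tt <- t(vapply(frames, `[[`, integer(8), "temperature_adc"))
  colnames(p) <- sprintf("p%02d", 1:16)
  colnames(tt) <- sprintf("t%02d", 1:8)
  cbind(df, as.data.frame(p), as.data.frame(tt))
}

format_subject <- function(s) {
  sprintf("age=%g weight=%g height=%g bmi=%.2f sex=%s",
          s$age, s$weight, s$height, s$bmi, s$sex)
}

parse_subject <- function(txt) {
  if (is.null(txt)) return(NULL)
  kv <- strsplit(strsplit(txt, " ", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  subject_profile(age = as.numeric(vals[["age"]]),
                  weight = as.numeric(vals[["weight"]]),
                  height = as.numeric(vals[["height"]]),
                  sex = vals[["sex"]])
}

# ---- ground-truth sidecar ---------------------------------------------------

#' Write a simulator ground-truth sidecar file
#'
#' Simulated trials carry a `ground_truth` attribute: per-frame true total
#' vGRF (template and sensed, i.e. post-hysteresis), per-frame true site
#' temperatures and the true heel-strike frame indices. This writes it as a
#' CSV next to the log so downstream stages can be validated without the
#' simulator in memory.
#'
#' @param trial A simulated [insole_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(trial, path) {
  gt <- attr(trial, "ground_truth")
  if (is.null(gt)) stop("trial carries no ground-truth attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#schema insole-truth/1"),
               paste0("#heel_strikes ", paste(gt$heel_strikes, collapse = " "))),
             con)
  utils::write.csv(gt$per_frame, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar file
#' @param path Sidecar CSV path written by [write_ground_truth()].
#' @return List with `per_frame` (data frame) and `heel_strikes` (integer
#'   frame indices).
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hs_line <- lines[startsWith(lines, "#heel_strikes")]
  hs <- if (length(hs_line)) {
    txt <- trimws(sub("^#heel_strikes", "", hs_line[1]))
    if (nzchar(txt)) as.integer(strsplit(txt, " ")[[1]]) else integer(0)
  } else integer(0)
  body <- lines[!startsWith(lines, "#")]
  per_frame <- utils::read.csv(text = paste(body, collapse = "\n"))
  list(per_frame = per_frame, heel_strikes = hs)
}
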