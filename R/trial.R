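#' A single recorded attempt
#'
#' One attempt of one motor task by one subject: a set of synchronously
#' sampled channels plus the experimental labels (session, priming condition,
#' Pre/Post time point, task, limb) and, for stimulation sweeps, the stimulus
#' onset times and intensities.
#'
#' @param subject_id Subject identifier (text).
#' @param session Session number, 1..6.
#' @param condition `"scTS"`, `"sham"` or `"none"` (e.g. familiarization).
#' @param time `"Pre"` or `"Post"` (relative to the priming protocol).
#' @param task `"mvc"`, `"steadiness"`, `"explosive"` or `"recruitment"`.
#' @param limb `"left"`, `"right"` or `"bilateral"`.
#' @param channels Named list of [sampled_signal()] objects, all with the same
#'   rate and length.
#' @param stim_onsets_s Stimulus onset times in seconds, strictly increasing
#'   (empty for voluntary tasks).
#' @param stim_intensities_mA Stimulus intensities, aligned with
#'   `stim_onsets_s`.
#'
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, session, condition, time, task, limb,
                         channels, stim_onsets_s = numeric(0),
                         stim_intensities_mA = numeric(0)) {
  condition <- match.arg(condition, c("scTS", "sham", "none"))
  time <- match.arg(time, c("Pre", "Post"))
  task <- match.arg(task, c("mvc", "steadiness", "explosive", "recruitment"))
  limb <- match.arg(limb, c("left", "right", "bilateral"))
  session <- as.integer(session)
  if (is.na(session) || session < 1L || session > 6L) {
    stop("session must be an integer in 1..6", call. = FALSE)
  }
  if (!is.list(channels) || length(channels) < 1L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list", call. = FALSE)
  }
  ok <- vapply(channels, inherits, logical(1), "sampled_signal")
  if (!all(ok)) stop("all channels must be sampled_signal objects", call. = FALSE)
  rates <- vapply(channels, function(s) s$rate, numeric(1))
  lens <- vapply(channels, function(s) length(s$values), numeric(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L) {
    stop("all channels must share one rate and one length", call. = FALSE)
  }
  if (length(stim_onsets_s) != length(stim_intensities_mA)) {
    stop("stim onset and intensity sequences must have equal length", call. = FALSE)
  }
  if (length(stim_onsets_s) > 1L && any(diff(stim_onsets_s) <= 0)) {
    stop("stim onsets must be strictly increasing", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), session = session,
         condition = condition, time = time, task = task, limb = limb,
         channels = channels,
         stim_onsets_s = as.numeric(stim_onsets_s),
         stim_intensities_mA = as.numeric(stim_intensities_mA)),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s, session %d, %s/%s, task %s (%s)\n",
              x$subject_id, x$session, x$condition, x$time, x$task, x$limb))
  cat(sprintf("  channels: %s; %d samples @ %g Hz; %d stimuli\n",
              paste(names(x$channels), collapse = ", "),
              length(x$channels[[1]]$values), x$channels[[1]]$rate,
              length(x$stim_onsets_s)))
  invisible(x)
}

trial_rate <- function(trial) trial$channels[[1]]$rate

#' Write a trial to a TSV file
#'
#' The on-disk trial format is UTF-8 TSV: `#key<TAB>value` header lines for
#' the labels and rate, one `#unit<TAB>channel<TAB>units` line per channel,
#' one `#stim<TAB>onset_s<TAB>intensity_mA` line per stimulus, then a
#' column-titled data table with one row per sample. Numeric values are
#' written with 9 significant digits so that write-then-read reproduces all
#' fields to that precision.
#'
#' @param trial A [trial_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(
    sprintf("#subject_id\t%s", trial$subject_id),
    sprintf("#session\t%d", trial$session),
    sprintf("#condition\t%s", trial$condition),
    sprintf("#time\t%s", trial$time),
    sprintf("#task\t%s", trial$task),
    sprintf("#limb\t%s", trial$limb),
    sprintf("#rate_hz\t%s", sprintf("%.9g", trial_rate(trial)))
  )
  if (!is.null(trial$attempt)) {
    hdr <- c(hdr, sprintf("#attempt\t%d", as.integer(trial$attempt)))
  }
  writeLines(hdr, con)
  for (nm in names(trial$channels)) {
    writeLines(sprintf("#unit\t%s\t%s", nm, trial$channels[[nm]]$units), con)
  }
  if (length(trial$stim_onsets_s)) {
    writeLines(sprintf("#stim\t%.9g\t%.9g", trial$stim_onsets_s,
                       trial$stim_intensities_mA), con)
  }
  writeLines(paste(names(trial$channels), collapse = "\t"), con)
  mat <- vapply(trial$channels, function(s) s$values,
                numeric(length(trial$channels[[1]]$values)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  lines <- do.call(paste, c(lapply(seq_len(ncol(mat)),
                                   function(j) sprintf("%.9g", mat[, j])),
                            sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trial from a TSV file
#'
#' Inverse of [write_trial()]. Malformed files (missing header keys, ragged
#' rows, non-increasing stimulus onsets) raise an error naming the offending
#' line.
#'
#' @param path File path.
#' @return A [trial_record()].
#' @export
read_trial <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  nhdr <- 0L
  keys <- list(); units <- character(0)
  stim_on <- numeric(0); stim_int <- numeric(0)
  for (i in seq_along(lines)) {
    if (!startsWith(lines[i], "#")) break
    nhdr <- i
    parts <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    key <- parts[1]
    if (key == "stim") {
      if (length(parts) != 3L) {
        stop(sprintf("%s: malformed #stim line at line %d", path, i), call. = FALSE)
      }
      stim_on <- c(stim_on, as.numeric(parts[2]))
      stim_int <- c(stim_int, as.numeric(parts[3]))
    } else if (key == "unit") {
      if (length(parts) < 2L) {
        stop(sprintf("%s: malformed #unit line at line %d", path, i), call. = FALSE)
      }
      units[parts[2]] <- if (length(parts) >= 3L) parts[3] else ""
    } else {
      keys[[key]] <- if (length(parts) >= 2L) parts[2] else ""
    }
  }
  required <- c("subject_id", "session", "condition", "time", "task", "limb", "rate_hz")
  missing <- setdiff(required, names(keys))
  if (length(missing)) {
    stop(sprintf("%s: missing required header key(s): %s (header ends at line %d)",
                 path, paste(missing, collapse = ", "), nhdr), call. = FALSE)
  }
  if (length(stim_on) > 1L && any(diff(stim_on) <= 0)) {
    bad <- which(diff(stim_on) <= 0)[1]
    stop(sprintf("%s: stim onsets not strictly increasing at stim entry %d", path, bad + 1L),
         call. = FALSE)
  }
  if (nhdr + 1L > length(lines)) {
    stop(sprintf("%s: no data table after header (line %d)", path, nhdr), call. = FALSE)
  }
  cols <- strsplit(lines[nhdr + 1L], "\t", fixed = TRUE)[[1]]
  body <- lines[(nhdr + 2L):length(lines)]
  body <- body[nzchar(body)]
  split_rows <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(split_rows)
  if (any(widths != length(cols))) {
    bad <- which(widths != length(cols))[1]
    stop(sprintf("%s: ragged data row at line %d (%d fields, expected %d)",
                 path, nhdr + 1L + bad, widths[bad], length(cols)), call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(split_rows, use.names = FALSE)),
                ncol = length(cols), byrow = TRUE)
  if (anyNA(mat)) {
    stop(sprintf("%s: non-numeric value in data table", path), call. = FALSE)
  }
  rate <- as.numeric(keys$rate_hz)
  channels <- stats::setNames(lapply(seq_along(cols), function(j) {
    sampled_signal(mat[, j], rate, units = if (cols[j] %in% names(units)) units[[cols[j]]] else "",
                   label = cols[j])
  }), cols)
  tr <- trial_record(keys$subject_id, as.integer(keys$session), keys$condition,
                     keys$time, keys$task, keys$limb, channels,
                     stim_onsets_s = stim_on, stim_intensities_mA = stim_int)
  if (!is.null(keys$attempt)) tr$attempt <- as.integer(keys$attempt)
  tr
}
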