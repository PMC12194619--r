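#' Maximum torque by sliding window
#'
#' Finds the 1 s (by default) sliding window with the highest mean torque,
#' stepping one sample at a time. This defines "maximum torque" for MVC
#' attempts; the same window is reused for the EMG metrics. Ties are broken
#' by the earliest window start.
#'
#' @param torque A [sampled_signal()], low-pass filtered at 10 Hz upstream.
#' @param win_s Window duration in seconds (default 1).
#' @param edge_trim_s Exclude windows overlapping the first/last
#'   `edge_trim_s` seconds (default 0; the trial-level wrappers use 0.1 to
#'   stay clear of filter edges).
#' @return List with `value` (windowed mean torque) and `start_s`.
#' @export
max_torque_window <- function(torque, win_s = 1.0, edge_trim_s = 0) {
  stopifnot(inherits(torque, "sampled_signal"))
  stats <- sliding_window_stats(torque, win_s, edge_trim_s)
  i <- which.max(stats$mean)           # first index wins ties -> earliest
  list(value = stats$mean[i], start_s = stats$start_s[i])
}

#' Lowest-variability window: torque steadiness CV
#'
#' Slides a 10 s (by default) window over a submaximal torque hold and
#' returns the lowest coefficient of variation (sample SD / mean,
#' dimensionless) together with the window start. That window defines the
#' steadiness outcome and is reused for the EMG metrics.
#'
#' @param torque A [sampled_signal()], low-pass filtered at 10 Hz upstream.
#' @param win_s Window duration in seconds (default 10).
#' @param edge_trim_s As in [max_torque_window()].
#' @return List with `cv` (dimensionless) and `start_s`.
#' @export
steadiness_cv <- function(torque, win_s = 10.0, edge_trim_s = 0) {
  stopifnot(inherits(torque, "sampled_signal"))
  stats <- sliding_window_stats(torque, win_s, edge_trim_s)
  if (any(stats$mean <= 0)) {
    stop("undefined CV: nonpositive mean torque in a candidate window", call. = FALSE)
  }
  cv <- stats$sd / stats$mean
  i <- which.min(cv)
  list(cv = cv[i], start_s = stats$start_s[i])
}

# O(n) windowed mean/SD for every 1-sample-step placement, via cumulative
# sums; SD is the sample (n-1) standard deviation.
sliding_window_stats <- function(signal, win_s, edge_trim_s = 0) {
  x <- signal$values
  rate <- signal$rate
  n <- length(x)
  wn <- round_half_up(win_s * rate)
  if (wn < 2L) stop("window too short", call. = FALSE)
  trim <- round_half_up(edge_trim_s * rate)
  first <- 1L + trim
  last <- n - trim - wn + 1L
  if (last < first) {
    stop(sprintf("signal of %g s too short for a %g s window (trim %g s)",
                 n / rate, win_s, edge_trim_s), call. = FALSE)
  }
  xc <- x - mean(x)  # center for numerical stability of the variance sums
  c1 <- c(0, cumsum(xc))
  c2 <- c(0, cumsum(xc^2))
  starts <- first:last
  s1 <- c1[starts + wn] - c1[starts]
  s2 <- c2[starts + wn] - c2[starts]
  mu <- s1 / wn
  v <- pmax(0, (s2 - wn * mu^2) / (wn - 1))
  list(start_s = (starts - 1L) / rate, mean = mu + mean(x), sd = sqrt(v))
}

#' Peak rate of torque development
#'
#' Maximum slope of the torque trace during its rising phase. The rising
#' phase runs from contraction onset to the global torque maximum; onset is
#' the last sample before the maximum at which torque is below baseline + 5%
#' of (max - baseline), with baseline taken as the mean of the first 200 ms.
#' The slope is a central difference of the (10 Hz low-pass filtered) trace.
#'
#' @param torque A [sampled_signal()], low-pass filtered at 10 Hz upstream.
#' @return Peak slope in units/s (nonnegative). A trace with no rising phase
#'   returns 0 with a warning.
#' @export
peak_rtd <- function(torque) {
  stopifnot(inherits(torque, "sampled_signal"))
  x <- torque$values
  rate <- torque$rate
  n <- length(x)
  if (n < 3L) stop("signal too short for a derivative", call. = FALSE)
  imax <- which.max(x)
  nb <- max(1L, min(round_half_up(0.2 * rate), n))
  baseline <- mean(x[seq_len(nb)])
  if (imax <= 1L || x[imax] <= baseline) {
    warning("no rising phase detected; peak RTD set to 0")
    return(0)
  }
  thr <- baseline + 0.05 * (x[imax] - baseline)
  below <- which(x[seq_len(imax - 1L)] < thr)
  onset <- if (length(below)) max(below) else 1L
  d <- (x[pmin(n, (onset:imax) + 1L)] - x[pmax(1L, (onset:imax) - 1L)]) *
    rate / 2
  max(0, max(d))
}

#' MVC trial metrics
#'
#' Computes the maximal-voluntary-contraction outcomes from one MVC trial:
#' maximum torque (1 s sliding-window mean), peak rate of torque development,
#' and EMG amplitude (RMS, as %MVC) and median power frequency of VL and RF
#' inside the max-torque window, plus their knee-extensor (KE) average.
#' Torque is low-pass filtered at 10 Hz and EMG band-pass filtered at
#' 10-499 Hz internally.
#'
#' @param trial A [trial_record()] with `task = "mvc"` and channels `torque`,
#'   `VL`, `RF`.
#' @param emg_mvc_ref Named numeric, per-muscle session reference EMG RMS
#'   (same units as the channels) used for %MVC normalization.
#' @param win_s MVC window duration (default 1 s).
#' @param edge_trim_s Edge exclusion for the window search (default 0.1 s).
#' @return An object of class `mvc_metrics`.
#' @export
mvc_metrics <- function(trial, emg_mvc_ref, win_s = 1.0, edge_trim_s = 0.1) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$task != "mvc") stop("trial task must be 'mvc'", call. = FALSE)
  need <- c("torque", "VL", "RF")
  miss <- setdiff(need, names(trial$channels))
  if (length(miss)) {
    stop(sprintf("missing channel(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  torque <- apply_filter(trial$channels$torque, torque_filter())
  w <- max_torque_window(torque, win_s = win_s, edge_trim_s = edge_trim_s)
  rtd <- peak_rtd(torque)
  emg <- emg_window_metrics(trial, c("VL", "RF"), emg_mvc_ref,
                            start_s = w$start_s, dur_s = win_s)
  structure(
    list(max_torque = w$value, max_window_start_s = w$start_s, peak_rtd = rtd,
         emg_rms_pct_mvc = emg$pct, emg_mdf = emg$mdf,
         ke_emg_rms_pct_mvc = mean(emg$pct), ke_mdf = mean(emg$mdf)),
    class = c("mvc_metrics", "limb_metrics")
  )
}

#' Torque steadiness trial metrics
#'
#' Computes the steadiness outcomes from one 20%-MVC hold: lowest 10 s
#' sliding-window coefficient of variation of torque (reported in percent),
#' and EMG amplitude (%MVC) and median power frequency of VL and RF inside
#' that lowest-CV window, plus KE averages.
#'
#' @inheritParams mvc_metrics
#' @param trial A [trial_record()] with `task = "steadiness"`.
#' @param win_s CV window duration (default 10 s).
#' @return An object of class `steadiness_metrics`.
#' @export
steadiness_metrics <- function(trial, emg_mvc_ref, win_s = 10.0,
                               edge_trim_s = 0.1) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$task != "steadiness") stop("trial task must be 'steadiness'", call. = FALSE)
  need <- c("torque", "VL", "RF")
  miss <- setdiff(need, names(trial$channels))
  if (length(miss)) {
    stop(sprintf("missing channel(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  torque <- apply_filter(trial$channels$torque, torque_filter())
  w <- steadiness_cv(torque, win_s = win_s, edge_trim_s = edge_trim_s)
  emg <- emg_window_metrics(trial, c("VL", "RF"), emg_mvc_ref,
                            start_s = w$start_s, dur_s = win_s)
  structure(
    list(cv_pct = 100 * w$cv, window_start_s = w$start_s,
         emg_rms_pct_mvc = emg$pct, emg_mdf = emg$mdf,
         ke_emg_rms_pct_mvc = mean(emg$pct), ke_mdf = mean(emg$mdf)),
    class = c("steadiness_metrics", "limb_metrics")
  )
}

# shared EMG window metrics: band-pass filter, RMS -> %MVC, and MDF for a set
# of muscles over one window
emg_window_metrics <- function(trial, muscles, emg_mvc_ref, start_s, dur_s) {
  if (is.null(names(emg_mvc_ref)) || !all(muscles %in% names(emg_mvc_ref))) {
    stop(sprintf("emg_mvc_ref must be named and cover: %s",
                 paste(muscles, collapse = ", ")), call. = FALSE)
  }
  if (any(emg_mvc_ref[muscles] <= 0)) {
    stop("emg_mvc_ref values must be positive", call. = FALSE)
  }
  pct <- mdf <- stats::setNames(numeric(length(muscles)), muscles)
  for (m in muscles) {
    f <- apply_filter(trial$channels[[m]], emg_filter())
    pct[m] <- 100 * signal_rms(f, start_s, dur_s) / emg_mvc_ref[[m]]
    mdf[m] <- median_power_frequency(f, start_s, dur_s)
  }
  list(pct = pct, mdf = mdf)
}

#' Average metrics from the left and right limb
#'
#' Field-wise arithmetic mean of two metric objects of the same type, used to
#' collapse per-limb outcomes to one subject-level value.
#'
#' @param left,right Two metric objects of identical class (e.g. two
#'   `mvc_metrics`).
#' @return A metric object of the same class.
#' @export
average_limbs <- function(left, right) {
  if (!identical(class(left), class(right))) {
    stop("average_limbs: metric objects must have the same type", call. = FALSE)
  }
  if (!identical(names(left), names(right))) {
    stop("average_limbs: metric objects must have the same fields", call. = FALSE)
  }
  out <- left
  for (f in names(left)) {
    if (is.numeric(left[[f]])) out[[f]] <- (left[[f]] + right[[f]]) / 2
  }
  out
}
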