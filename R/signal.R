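#' Uniformly sampled signal
#'
#' The basic container for every analysed channel: a numeric vector of samples
#' taken at a constant rate, plus physical units and a label. All acquisition
#' in the supported protocol runs at 1000 samples/s, but any positive rate is
#' accepted (tests use lower rates for speed).
#'
#' @param values Numeric vector of samples; must be finite and of length >= 1.
#' @param rate Sampling rate in samples per second.
#' @param units Unit string, e.g. `"N.m"`, `"N"`, `"m/s"`, `"uV"`.
#' @param label Channel label, e.g. `"torque"`, `"VL"`.
#'
#' @return An object of class `sampled_signal`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000, "N.m", "torque")
#' signal_duration(s)
sampled_signal <- function(values, rate, units = "", label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("sampled_signal: 'values' must have length >= 1", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("sampled_signal: 'values' must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("sampled_signal: 'rate' must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, rate = as.numeric(rate),
         units = as.character(units), label = as.character(label)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s], %d samples @ %g Hz (%.3f s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$units, length(x$values), x$rate, signal_duration(x)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal A [sampled_signal()].
#' @return Duration in seconds (`length(values) / rate`).
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  length(signal$values) / signal$rate
}

# seconds -> sample index conversion: round half up, windows are half-open
# [start, start + dur). Returns integer indices (1-based) into values.
round_half_up <- function(x) floor(x + 0.5)

window_indices <- function(signal, start_s, dur_s) {
  n <- length(signal$values)
  i0 <- round_half_up(start_s * signal$rate) + 1L
  i1 <- round_half_up((start_s + dur_s) * signal$rate)
  if (dur_s <= 0) stop("window duration must be positive", call. = FALSE)
  if (i0 < 1L || i1 > n) {
    stop(sprintf("window [%g, %g) s outside signal of duration %g s",
                 start_s, start_s + dur_s, n / signal$rate), call. = FALSE)
  }
  i0:i1
}

#' Root mean square over a time window
#'
#' RMS amplitude of a signal over the half-open window `[start_s, start_s +
#' dur_s)`. Used for EMG amplitude quantification; it is invariant to
#' rectification (sign flips) by construction.
#'
#' @param signal A [sampled_signal()].
#' @param start_s Window start in seconds (default 0).
#' @param dur_s Window duration in seconds (default: to end of signal).
#' @return Nonnegative scalar in the signal's units.
#' @export
signal_rms <- function(signal, start_s = 0, dur_s = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (is.null(dur_s)) dur_s <- signal_duration(signal) - start_s
  idx <- window_indices(signal, start_s, dur_s)
  sqrt(mean(signal$values[idx]^2))
}

#' Median power frequency of an EMG window
#'
#' The frequency that splits the spectral power of the window in half within
#' `band_hz`. The spectrum is estimated by Welch's method (Hamming window,
#' 256 ms segments, 50% overlap, per-segment mean removal) and the half-power
#' crossing is linearly interpolated between spectral bins.
#'
#' @param signal A [sampled_signal()].
#' @param start_s,dur_s Analysis window (seconds); defaults to the whole signal.
#' @param band_hz Length-2 numeric, analysis band in Hz; default `c(10, 499)`
#'   matching the EMG band-pass.
#' @return Median power frequency in Hz.
#' @export
median_power_frequency <- function(signal, start_s = 0, dur_s = NULL,
                                   band_hz = c(10, 499)) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (is.null(dur_s)) dur_s <- signal_duration(signal) - start_s
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= signal$rate / 2 + 1e-9) {
    stop("band_hz must satisfy 0 < low < high <= rate/2", call. = FALSE)
  }
  idx <- window_indices(signal, start_s, dur_s)
  x <- signal$values[idx]
  sp <- welch_psd(x, signal$rate)
  keep <- sp$freq >= band_hz[1] & sp$freq <= band_hz[2]
  f <- sp$freq[keep]
  p <- sp$power[keep]
  tot <- sum(p)
  if (tot <= 0 || length(f) < 2L) {
    stop("degenerate spectrum: no power in the analysis band", call. = FALSE)
  }
  cum <- cumsum(p)
  half <- tot / 2
  k <- which(cum >= half)[1]
  if (k == 1L) return(f[1])
  # linear interpolation of the cumulative power crossing between bins k-1, k
  f0 <- f[k - 1L]; f1 <- f[k]
  c0 <- cum[k - 1L]; c1 <- cum[k]
  f0 + (half - c0) / (c1 - c0) * (f1 - f0)
}

# Welch power spectral density: Hamming window, 256 ms segments, 50% overlap.
# Falls back to a single full-length segment when the window is shorter than
# one segment. Returns power at frequencies 0..rate/2; absolute scaling is
# arbitrary (only ratios are used downstream).
welch_psd <- function(x, rate, seg_s = 0.256, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, max(8L, round_half_up(seg_s * rate)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1L) * rate / nseg, power = acc / length(starts))
}
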