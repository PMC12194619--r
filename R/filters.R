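#' Filter specification
#'
#' Describes one of the digital filters used by the pipeline. The protocol
#' uses three: a 10–499 Hz band-pass for EMG, a 10 Hz low-pass for isometric
#' torque, and a 25 Hz low-pass for sled force/velocity. The filter family is
#' a Butterworth of the given order, applied forward and backward when
#' `zero_phase` is `TRUE` (the default), which doubles the effective order and
#' removes group delay so that the timing of rate-of-development events is
#' preserved.
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param low_hz Lower corner (band-pass only).
#' @param high_hz Upper corner (both kinds).
#' @param order Butterworth order of the one-way filter (default 4).
#' @param zero_phase Apply forward-backward for zero phase (default `TRUE`).
#'
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' emg_filter()       # 10-499 Hz band-pass
#' torque_filter()    # 10 Hz low-pass
#' exer_filter()      # 25 Hz low-pass
filter_spec <- function(kind = c("bandpass", "lowpass"), low_hz = NULL,
                        high_hz = NULL, order = 4L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (is.null(low_hz) || is.null(high_hz) || low_hz <= 0 || high_hz <= low_hz) {
      stop("bandpass requires 0 < low_hz < high_hz", call. = FALSE)
    }
  } else {
    if (is.null(high_hz) || high_hz <= 0) {
      stop("lowpass requires high_hz > 0", call. = FALSE)
    }
    low_hz <- NULL
  }
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
emg_filter <- function() filter_spec("bandpass", 10, 499)

#' @rdname filter_spec
#' @export
torque_filter <- function() filter_spec("lowpass", high_hz = 10)

#' @rdname filter_spec
#' @export
exer_filter <- function() filter_spec("lowpass", high_hz = 25)

#' Apply a filter to a signal
#'
#' Filters a [sampled_signal()] according to a [filter_spec()]. Corner
#' frequencies are validated against the signal's Nyquist frequency. With
#' `zero_phase = TRUE` the filter runs forward then backward over an
#' odd-symmetric edge extension, so the output has no group delay and the same
#' length as the input.
#'
#' @param signal A [sampled_signal()].
#' @param spec A [filter_spec()].
#' @return A filtered [sampled_signal()] with the same length, rate and units.
#' @export
apply_filter <- function(signal, spec) {
  stopifnot(inherits(signal, "sampled_signal"), inherits(spec, "filter_spec"))
  nyq <- signal$rate / 2
  if (spec$high_hz >= nyq) {
    stop(sprintf("invalid filter: corner %g Hz >= Nyquist %g Hz",
                 spec$high_hz, nyq), call. = FALSE)
  }
  if (spec$kind == "bandpass" && spec$low_hz >= nyq) {
    stop("invalid filter: lower corner >= Nyquist", call. = FALSE)
  }
  ba <- if (spec$kind == "bandpass") {
    butter_coeffs(spec$order, c(spec$low_hz, spec$high_hz) / nyq, "bandpass")
  } else {
    butter_coeffs(spec$order, spec$high_hz / nyq, "lowpass")
  }
  y <- if (spec$zero_phase) {
    filtfilt_ba(ba$b, ba$a, signal$values)
  } else {
    lfilter(ba$b, ba$a, signal$values)
  }
  out <- signal
  out$values <- y
  out
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth design by bilinear transform of the analog prototype.
#' `w` is the corner frequency (or length-2 band) normalized to Nyquist
#' (0 < w < 1). Returns transfer-function coefficients `b` (numerator) and
#' `a` (denominator, `a[1] == 1`). A band-pass of order `n` has `2n` poles.
#'
#' @param n Filter order.
#' @param w Normalized corner(s), in (0, 1).
#' @param kind `"lowpass"` or `"bandpass"`.
#' @return List with numeric vectors `b` and `a`.
#' @export
butter_coeffs <- function(n, w, kind = c("lowpass", "bandpass")) {
  kind <- match.arg(kind)
  if (any(w <= 0) || any(w >= 1)) stop("normalized corners must be in (0, 1)", call. = FALSE)
  fs <- 2
  warped <- 2 * fs * tan(pi * w / 2)
  # analog lowpass prototype: n poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  if (kind == "lowpass") {
    w0 <- warped[1]
    p <- w0 * p_proto
    z <- complex(0)
    gain <- w0^n
  } else {
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    plp <- p_proto * bw / 2
    disc <- sqrt(plp^2 - w0^2)
    p <- c(plp + disc, plp - disc)
    z <- rep(0 + 0i, n)
    gain <- bw^n
  }
  # bilinear transform s -> z
  fs2 <- 2 * fs
  z_d <- (fs2 + z) / (fs2 - z)
  p_d <- (fs2 + p) / (fs2 - p)
  gain_d <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # zeros at infinity map to z = -1
  z_d <- c(z_d, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(poly_from_roots(z_d)) * gain_d
  a <- Re(poly_from_roots(p_d))
  list(b = b / a[1] * 1, a = a / a[1])
}

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0i) - c(0i, cf * ri)
  cf
}

# one-way IIR filtering with zero initial state, via C-level stats::filter
lfilter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[nb:length(xp)]
  if (length(a) > 1L) {
    ma <- as.numeric(stats::filter(ma, -a[-1L], method = "recursive"))
  }
  ma
}

# forward-backward zero-phase filtering with odd-symmetric edge extension.
# Pad length covers both the scipy-style minimum and ~7 decay constants of the
# slowest pole so that the zero-initial-state transient dies inside the pad.
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  r <- max(Mod(polyroot(rev(a))))
  decay <- if (r < 1 && r > 0) ceiling(-7 / log(r)) else 3L * (nfilt - 1L)
  pad <- max(3L * (nfilt - 1L), min(decay, 1024L))
  if (n <= 3L * (nfilt - 1L)) {
    stop(sprintf("signal too short to filter: %d samples <= warm-up %d",
                 n, 3L * (nfilt - 1L)), call. = FALSE)
  }
  pad <- min(pad, n - 1L)
  # odd extension about the end points
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(pre, x, post)
  y <- lfilter(b, a, xe)
  y <- rev(lfilter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}
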