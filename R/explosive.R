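#' Sled ergometer parameters
#'
#' Physical constants of the inclined sled ergometer used for explosive
#' lower-limb extensions: the subject sits on a carriage (moving mass 31.6 kg
#' by default) on a rail inclined 20 degrees and pushes against fixed force
#' platforms, so the effective load is a fraction of body weight.
#'
#' @param body_mass_kg Subject body mass (kg).
#' @param moving_mass_kg Seat + carriage mass (kg), default 31.6.
#' @param incline_deg Rail incline (degrees), default 20.
#' @return An object of class `sled_params`.
#' @export
#' @examples
#' p <- sled_params(body_mass_kg = 77.5)
#' sled_load_fraction(p)  # effective pushed load as a fraction of body weight
sled_params <- function(body_mass_kg, moving_mass_kg = 31.6, incline_deg = 20) {
  if (body_mass_kg <= 0 || moving_mass_kg <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  if (incline_deg <= 0 || incline_deg >= 90) {
    stop("incline must be in (0, 90) degrees", call. = FALSE)
  }
  structure(list(body_mass_kg = body_mass_kg, moving_mass_kg = moving_mass_kg,
                 incline_deg = incline_deg), class = "sled_params")
}

#' @rdname sled_params
#' @details `sled_load_fraction()` returns the static load the subject must
#'   overcome, `(body + moving mass) * g * sin(incline)`, expressed as a
#'   fraction of body weight. With the default masses and incline and a
#'   77.5 kg subject this is about 0.48.
#' @param params A `sled_params` object.
#' @export
sled_load_fraction <- function(params) {
  stopifnot(inherits(params, "sled_params"))
  total <- params$body_mass_kg + params$moving_mass_kg
  total * sin(params$incline_deg * pi / 180) / params$body_mass_kg
}

#' Instantaneous mechanical power
#'
#' Sample-wise product of the (bilateral, summed) force and the backward
#' velocity of the sled.
#'
#' @param force,velocity [sampled_signal()] objects with equal rate/length,
#'   low-pass filtered at 25 Hz upstream.
#' @return A [sampled_signal()] in watts.
#' @export
instantaneous_power <- function(force, velocity) {
  stopifnot(inherits(force, "sampled_signal"), inherits(velocity, "sampled_signal"))
  if (length(force$values) != length(velocity$values) ||
      force$rate != velocity$rate) {
    stop("force and velocity must have the same length and rate", call. = FALSE)
  }
  sampled_signal(force$values * velocity$values, force$rate, units = "W",
                 label = "power")
}

#' Detect the push phase of an explosive extension
#'
#' The push phase spans the period of force development: onset is the first
#' sample at which force exceeds the pre-push baseline mean plus `k` baseline
#' SDs (baseline = the first `baseline_s` seconds, which must be quiescent);
#' the end is the earlier of (a) force falling back into the baseline band
#' after its peak and (b) foot-off, detected as the backward velocity
#' starting to fall (negative derivative sustained for 50 ms).
#'
#' @param force A [sampled_signal()] (25 Hz low-pass filtered upstream).
#' @param velocity Optional velocity [sampled_signal()] for foot-off
#'   detection.
#' @param baseline_s Duration of the pre-push baseline (default 0.2 s).
#' @param k Baseline SD multiplier for the onset threshold (default 3).
#' @return List with `onset_s` and `end_s`.
#' @export
push_phase <- function(force, velocity = NULL, baseline_s = 0.2, k = 3) {
  stopifnot(inherits(force, "sampled_signal"))
  x <- force$values
  rate <- force$rate
  n <- length(x)
  nb <- round_half_up(baseline_s * rate)
  if (nb < 2L || nb >= n) stop("baseline period invalid for this trace", call. = FALSE)
  mu <- mean(x[seq_len(nb)])
  sd0 <- stats::sd(x[seq_len(nb)])
  # floor the threshold at 1% of the peak excursion: a pure k*SD rule fires on
  # zero-phase filter pre-ringing when the baseline is (near-)noise-free
  thr <- mu + max(k * sd0, 0.01 * (max(x) - mu))
  above <- which(x[(nb + 1L):n] > thr)
  if (!length(above)) stop("no push detected: force never exceeds baseline band", call. = FALSE)
  onset <- nb + above[1]
  ipk <- onset - 1L + which.max(x[onset:n])
  back <- which(x[ipk:n] <= thr)
  end_force <- if (length(back)) ipk - 1L + back[1] else n
  end <- end_force
  if (!is.null(velocity)) {
    stopifnot(inherits(velocity, "sampled_signal"))
    v <- velocity$values
    dn <- round_half_up(0.05 * rate)
    dv <- diff(v)
    # first index >= onset where dv stays negative for 50 ms
    neg <- dv < 0
    run <- which(neg)
    run <- run[run >= onset]
    end_v <- n
    for (i in run) {
      if (i + dn - 1L <= length(dv) && all(neg[i:(i + dn - 1L)])) {
        end_v <- i
        break
      }
    }
    end <- min(end_force, end_v)
  }
  if (end <= onset) end <- min(n, onset + 1L)
  list(onset_s = (onset - 1L) / rate, end_s = (end - 1L) / rate)
}

#' Explosive extension trial metrics
#'
#' Computes the explosive-power outcomes from one sled trial: peak force,
#' peak rate of force development (central-difference slope within the push
#' phase), peak backward velocity and peak power (force x velocity), the push
#' phase bounds, and push-phase EMG amplitude (%MVC) of the knee extensors
#' (KE = mean of VL and RF), MG and TA of the dominant limb. Force and
#' velocity are low-pass filtered at 25 Hz and EMG band-pass filtered at
#' 10-499 Hz internally.
#'
#' @param trial A [trial_record()] with `task = "explosive"` and channels
#'   `force`, `velocity`, `VL`, `RF`, `MG`, `TA`.
#' @param emg_mvc_ref Named numeric, per-muscle session MVC reference EMG RMS.
#' @return An object of class `explosive_metrics`.
#' @export
explosive_metrics <- function(trial, emg_mvc_ref) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$task != "explosive") stop("trial task must be 'explosive'", call. = FALSE)
  need <- c("force", "velocity", "VL", "RF", "MG", "TA")
  miss <- setdiff(need, names(trial$channels))
  if (length(miss)) {
    stop(sprintf("missing channel(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  force <- apply_filter(trial$channels$force, exer_filter())
  velocity <- apply_filter(trial$channels$velocity, exer_filter())
  ph <- push_phase(force, velocity)
  rate <- force$rate
  i0 <- round_half_up(ph$onset_s * rate) + 1L
  i1 <- round_half_up(ph$end_s * rate) + 1L
  idx <- i0:i1
  f <- force$values
  pow <- f * velocity$values
  d <- (f[pmin(length(f), idx + 1L)] - f[pmax(1L, idx - 1L)]) * rate / 2
  mus <- emg_window_metrics(trial, c("VL", "RF", "MG", "TA"), emg_mvc_ref,
                            start_s = ph$onset_s, dur_s = ph$end_s - ph$onset_s)
  structure(
    list(peak_force = max(f[idx]),
         peak_rfd = max(0, max(d)),
         peak_velocity = max(velocity$values[idx]),
         peak_power = max(pow[idx]),
         push_onset_s = ph$onset_s, push_end_s = ph$end_s,
         emg_rms_pct_mvc = c(KE = mean(mus$pct[c("VL", "RF")]),
                             MG = unname(mus$pct["MG"]),
                             TA = unname(mus$pct["TA"]))),
    class = c("explosive_metrics", "limb_metrics")
  )
}

#' Simulate sled velocity from a force profile
#'
#' Point-mass dynamics of the inclined sled: `M dv/dt = F(t) - M g
#' sin(incline)` with `M = body + moving mass`, integrated by classical RK4
#' at the force signal's rate. Velocity is clipped at zero while the applied
#' force is below the gravity component (the mechanical blocks prevent any
#' countermovement).
#'
#' @param force_profile A nonnegative [sampled_signal()] in newtons.
#' @param params A [sled_params()].
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return A [sampled_signal()] of backward velocity in m/s.
#' @export
simulate_sled <- function(force_profile, params, g = 9.81) {
  stopifnot(inherits(force_profile, "sampled_signal"), inherits(params, "sled_params"))
  f <- force_profile$values
  if (any(f < 0)) stop("force profile must be nonnegative", call. = FALSE)
  rate <- force_profile$rate
  M <- params$body_mass_kg + params$moving_mass_kg
  fg <- M * g * sin(params$incline_deg * pi / 180)
  dt <- 1 / rate
  n <- length(f)
  v <- numeric(n)
  # force linearly interpolated at half steps for RK4
  fmid <- c((f[-n] + f[-1]) / 2, f[n])
  acc <- function(fi) (fi - fg) / M
  for (i in seq_len(n - 1L)) {
    k1 <- acc(f[i])
    k2 <- acc(fmid[i])
    k3 <- k2
    k4 <- acc(f[i + 1L])
    vn <- v[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (v[i] <= 0 && f[i] < fg) vn <- max(0, vn)  # blocks: no countermovement
    v[i + 1L] <- max(0, vn)
  }
  sampled_signal(v, rate, units = "m/s", label = "velocity")
}
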