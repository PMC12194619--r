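#' @title Synthetic trial and cohort generation
#' @description Generators that emulate the study's signals (MVC torque ramps
#'   with EMG, 20%-MVC steadiness holds, explosive sled extensions,
#'   recruitment-curve stimulus sweeps) and its crossover effect structure,
#'   so the full analysis chain can be exercised and verified without human
#'   data. Every generator records its programmed ground truth in a sidecar
#'   "truth" attribute retrievable with [trial_truth()].
#' @name synthetic-data
NULL

# evaluate code under a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Ground truth attached to a synthetic trial
#' @param trial A trial produced by one of the `synth_*_trial` generators.
#' @return Named list of programmed metric values.
#' @export
trial_truth <- function(trial) attr(trial, "truth")

#' Subject profile for the generators
#'
#' The latent per-subject parameters the generators draw signals from. Use
#' [sample_subject_profile()] to draw profiles around the published cohort
#' moments (body mass 77.5 +/- 10.1 kg, stature 178 +/- 7.2 cm), with
#' rejection sampling keeping BMI inside the 18.5-29.9 inclusion window.
#'
#' @param subject_id Identifier.
#' @param body_mass_kg,stature_cm Anthropometrics.
#' @param mvc_torque_Nm Single-limb maximal isometric knee-extension torque.
#' @param emg_mvc_rms_uV Named numeric: per-muscle EMG RMS at MVC (VL, RF,
#'   MG, TA).
#' @param baseline_mdf_hz EMG median power frequency.
#' @param recruitment_threshold_mA Latent activation threshold of the evoked
#'   responses.
#' @param recruitment_slope Logistic slope (mA) of the recruitment curve.
#' @param recruitment_max_uV Saturation amplitude of the evoked responses.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, body_mass_kg = 77.5, stature_cm = 178,
                            mvc_torque_Nm = 230,
                            emg_mvc_rms_uV = c(VL = 400, RF = 350, MG = 300, TA = 250),
                            baseline_mdf_hz = 80,
                            recruitment_threshold_mA = 50,
                            recruitment_slope = 6,
                            recruitment_max_uV = 2000) {
  vals <- c(body_mass_kg, stature_cm, mvc_torque_Nm, emg_mvc_rms_uV,
            baseline_mdf_hz, recruitment_threshold_mA, recruitment_slope,
            recruitment_max_uV)
  if (any(vals <= 0)) stop("all profile parameters must be positive", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 body_mass_kg = body_mass_kg, stature_cm = stature_cm,
                 mvc_torque_Nm = mvc_torque_Nm,
                 emg_mvc_rms_uV = emg_mvc_rms_uV,
                 baseline_mdf_hz = baseline_mdf_hz,
                 recruitment_threshold_mA = recruitment_threshold_mA,
                 recruitment_slope = recruitment_slope,
                 recruitment_max_uV = recruitment_max_uV),
            class = "subject_profile")
}

#' @rdname subject_profile
#' @param seed Optional RNG seed.
#' @export
sample_subject_profile <- function(subject_id, seed = NULL) {
  with_seed(seed, {
    repeat {
      mass <- stats::rnorm(1, 77.5, 10.1)
      stature <- stats::rnorm(1, 178, 7.2)
      bmi <- mass / (stature / 100)^2
      if (mass > 40 && stature > 140 && bmi >= 18.5 && bmi <= 29.9) break
    }
    subject_profile(
      subject_id,
      body_mass_kg = mass, stature_cm = stature,
      mvc_torque_Nm = max(120, stats::rnorm(1, 230, 35)),
      emg_mvc_rms_uV = c(VL = max(100, stats::rnorm(1, 400, 80)),
                         RF = max(100, stats::rnorm(1, 350, 70)),
                         MG = max(80, stats::rnorm(1, 300, 60)),
                         TA = max(80, stats::rnorm(1, 250, 50))),
      baseline_mdf_hz = min(110, max(60, stats::rnorm(1, 80, 8))),
      recruitment_threshold_mA = min(85, max(20, stats::rnorm(1, 51.6, 3.2 * sqrt(12)))),
      recruitment_slope = 6,
      recruitment_max_uV = max(500, stats::rnorm(1, 2000, 400))
    )
  })
}

#' BMI of a subject profile
#' @param profile A [subject_profile()].
#' @return Body mass index in kg/m^2.
#' @export
profile_bmi <- function(profile) {
  profile$body_mass_kg / (profile$stature_cm / 100)^2
}

# ---------------------------------------------------------------------------
# EMG synthesis

# memo cache for the band calibration
.mdf_band_cache <- new.env(parent = emptyenv())

# squared-magnitude response of b/a at frequencies f (Hz)
filter_mag2 <- function(ba, f, rate) {
  z <- exp(-2i * pi * f / rate)
  num <- outer(z, 0:(length(ba$b) - 1L), "^") %*% ba$b
  den <- outer(z, 0:(length(ba$a) - 1L), "^") %*% ba$a
  Mod(num / den)^2
}

# shaping band for a target MDF: a band-pass [0.6c, 1.6c] around a centre c
# calibrated so that the *estimated* median power frequency -- after the
# forward-backward shaping filter, the standard 10-499 Hz analysis band-pass
# (also forward-backward) and the Welch spectral smoothing of the estimator --
# equals the target. Power transfer of a forward-backward filter is |H|^4.
mdf_shaping_band <- function(target_mdf, rate) {
  key <- sprintf("%.3f_%g", target_mdf, rate)
  if (!is.null(.mdf_band_cache[[key]])) return(.mdf_band_cache[[key]])
  nyq <- rate / 2
  f <- seq(0.25, nyq - 0.25, by = 0.25)
  emg_hi <- min(499, nyq * 0.998)
  he <- filter_mag2(butter_coeffs(4, c(10, emg_hi) / nyq, "bandpass"), f, rate)^2
  # Welch smoothing kernel: squared-magnitude DFT of the 256 ms Hamming window
  nseg <- max(8L, round_half_up(0.256 * rate))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  nfft <- 16384L
  W2 <- Mod(stats::fft(c(w, rep(0, nfft - nseg))))^2
  fW <- (0:(nfft - 1L)) * rate / nfft
  keep <- fW <= 20
  kern_f <- c(-rev(fW[keep][-1]), fW[keep])
  kern <- c(rev(W2[keep][-1]), W2[keep])
  kern <- stats::approx(kern_f, kern, xout = seq(-20, 20, by = 0.25), rule = 2)$y
  kern <- kern / sum(kern)
  band_for <- function(ctr) c(max(10.5, 0.6 * ctr), min(nyq * 0.995, 1.6 * ctr))
  # Welch grid of the estimator; the median is computed exactly the way
  # median_power_frequency does it: power binned per Welch frequency,
  # cumulative sum restricted to the 10-499 Hz band, linear interpolation
  fw <- (0:(nseg %/% 2)) * rate / nseg
  bin <- pmin(length(fw), pmax(1L, round_half_up(f / (rate / nseg)) + 1L))
  realized <- function(ctr) {
    bd <- band_for(ctr)
    hs <- filter_mag2(butter_coeffs(4, bd / nyq, "bandpass"), f, rate)^2
    p <- as.numeric(hs * he)
    p <- stats::filter(c(rep(0, 80), p, rep(0, 80)), kern, sides = 2)
    p <- as.numeric(p)[81:(80 + length(f))]
    pb <- vapply(split(p, bin), sum, numeric(1))
    fb <- fw[as.integer(names(pb))]
    keep <- fb >= 10 & fb <= emg_hi
    pb <- pb[keep]; fb <- fb[keep]
    cum <- cumsum(pb)
    half <- cum[length(cum)] / 2
    k <- which(cum >= half)[1]
    if (k == 1L) return(fb[1])
    fb[k - 1] + (half - cum[k - 1]) / (cum[k] - cum[k - 1]) * (fb[k] - fb[k - 1])
  }
  lo <- 18; hi <- nyq * 0.62
  if (target_mdf <= realized(lo) || target_mdf >= realized(hi)) {
    stop(sprintf("infeasible target MDF %g Hz at rate %g", target_mdf, rate),
         call. = FALSE)
  }
  r <- stats::uniroot(function(x) realized(x) - target_mdf, c(lo, hi), tol = 0.02)
  band <- band_for(r$root)
  .mdf_band_cache[[key]] <- band
  band
}

#' Synthesize a surface-EMG-like signal
#'
#' Gaussian noise, band-pass shaped so that after the standard 10-499 Hz
#' analysis filter its median power frequency equals `target_mdf_hz` (the
#' shaping band is calibrated analytically from the designed filter
#' responses), amplitude-flattened by a 250 ms running-RMS normalization so
#' that sub-window RMS stays close to the target, and scaled to
#' `target_rms_uV` exactly over the whole trace.
#'
#' @param duration_s Duration in seconds.
#' @param target_rms_uV Target RMS amplitude.
#' @param target_mdf_hz Target median power frequency (after analysis
#'   filtering).
#' @param rate Sampling rate (default 1000).
#' @param seed Optional RNG seed.
#' @return A [sampled_signal()] in µV.
#' @export
synth_emg <- function(duration_s, target_rms_uV, target_mdf_hz, rate = 1000,
                      seed = NULL) {
  if (target_rms_uV <= 0) stop("target RMS must be positive", call. = FALSE)
  band <- mdf_shaping_band(target_mdf_hz, rate)  # errors if infeasible
  with_seed(seed, {
    n <- round_half_up(duration_s * rate)
    ba <- butter_coeffs(4, band / (rate / 2), "bandpass")
    x <- filtfilt_ba(ba$b, ba$a, stats::rnorm(n))
    # amplitude flattening: divide by centered running RMS
    w <- min(n, round_half_up(0.1 * rate))
    if (w %% 2L == 0L) w <- w + 1L
    p <- as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2))
    half <- (w - 1L) %/% 2L
    if (half > 0L && n > 2L * half) {
      p[seq_len(half)] <- p[half + 1L]
      p[(n - half + 1L):n] <- p[n - half]
    }
    x <- x / sqrt(pmax(p, .Machine$double.eps))
    x <- x * target_rms_uV / sqrt(mean(x^2))
    sampled_signal(x, rate, units = "uV", label = "emg")
  })
}

# ---------------------------------------------------------------------------
# Trial generators

#' Synthesize an MVC trial
#'
#' Logistic torque rise (time constant such that the peak slope is
#' `amplitude * k / 4`) to a plateau at `effect_multiplier` times the
#' profile's MVC torque, with proportionally scaled VL/RF EMG. The truth
#' attribute records the programmed maximum torque, peak RTD, EMG RMS,
#' %MVC (relative to the profile reference) and MDF.
#'
#' @param profile A [subject_profile()].
#' @param effect_multiplier Latent torque scaling (1 = the profile's MVC).
#' @param seed Optional RNG seed.
#' @param rate Sampling rate (default 1000).
#' @param duration_s Trial duration (default 5 s, a 4-5 s effort).
#' @param noise Scale for the additive instrumentation noise (0 = noise-free).
#' @param muscles EMG channels to generate (default VL and RF; explosive
#'   sessions use all four so the reference covers MG and TA).
#' @param limb,condition,time,session,attempt Trial labels.
#' @return A [trial_record()] with channels `torque` and one per muscle.
#' @export
synth_mvc_trial <- function(profile, effect_multiplier = 1, seed = NULL,
                            rate = 1000, duration_s = 5, noise = 1,
                            muscles = c("VL", "RF"),
                            limb = "right", condition = "none", time = "Pre",
                            session = 2L, attempt = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(seed, {
    n <- round_half_up(duration_s * rate)
    t <- (seq_len(n) - 1L) / rate
    A <- effect_multiplier * profile$mvc_torque_Nm
    k <- 12; t0 <- 1.5
    torque_true <- A * stats::plogis(k * (t - t0))
    torque <- torque_true + noise * 0.3 * stats::rnorm(n)
    env <- if (A > 0) torque_true / A else rep(0, n)
    mus <- muscles
    channels <- list(torque = sampled_signal(torque, rate, "N.m", "torque"))
    for (m in mus) {
      e <- synth_emg(duration_s, max(effect_multiplier, 1e-6) *
                       profile$emg_mvc_rms_uV[[m]],
                     profile$baseline_mdf_hz, rate)
      channels[[m]] <- sampled_signal(e$values * env +
                                        noise * 1.0 * stats::rnorm(n),
                                      rate, "uV", m)
    }
    trial <- trial_record(profile$subject_id, session, condition, time, "mvc",
                          limb, channels)
    trial$attempt <- as.integer(attempt)
    attr(trial, "truth") <- list(
      max_torque = A,
      peak_rtd = A * k / 4,
      emg_rms_uV = effect_multiplier * profile$emg_mvc_rms_uV[mus],
      emg_pct_mvc = 100 * effect_multiplier,
      emg_mdf = profile$baseline_mdf_hz,
      effect_multiplier = effect_multiplier
    )
    trial
  })
}

#' Synthesize a torque-steadiness trial
#'
#' A 2 s ramp to a 20%-MVC plateau held for the rest of the attempt, with a
#' smooth (<= 6 Hz) torque fluctuation standardized so the plateau
#' coefficient of variation equals `cv_pct` exactly, plus VL/RF EMG at 20% of
#' the MVC reference amplitude.
#'
#' @inheritParams synth_mvc_trial
#' @param cv_pct Programmed plateau CV in percent (default 1.5).
#' @param target_frac Plateau level as a fraction of MVC torque (default 0.2).
#' @param duration_s Attempt duration (default 18 s, a "~20 s" hold).
#' @return A [trial_record()] with channels `torque`, `VL`, `RF`.
#' @export
synth_steadiness_trial <- function(profile, cv_pct = 1.5, seed = NULL,
                                   rate = 1000, duration_s = 18,
                                   target_frac = 0.2, noise = 1,
                                   limb = "right", condition = "none",
                                   time = "Pre", session = 2L, attempt = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(seed, {
    n <- round_half_up(duration_s * rate)
    t <- (seq_len(n) - 1L) / rate
    mu <- target_frac * profile$mvc_torque_Nm
    ramp <- pmin(1, t / 2)
    plateau <- t >= 2
    torque <- mu * ramp
    if (cv_pct > 0) {
      ba <- butter_coeffs(4, 6 / (rate / 2), "lowpass")
      f <- filtfilt_ba(ba$b, ba$a, stats::rnorm(n))
      f <- (f - mean(f[plateau])) / stats::sd(f[plateau])
      torque <- torque + mu * (cv_pct / 100) * f * ramp
    }
    mus <- c("VL", "RF")
    channels <- list(torque = sampled_signal(torque, rate, "N.m", "torque"))
    for (m in mus) {
      e <- synth_emg(duration_s, target_frac * profile$emg_mvc_rms_uV[[m]],
                     profile$baseline_mdf_hz, rate)
      channels[[m]] <- sampled_signal(e$values * ramp +
                                        noise * 0.5 * stats::rnorm(n),
                                      rate, "uV", m)
    }
    trial <- trial_record(profile$subject_id, session, condition, time,
                          "steadiness", limb, channels)
    trial$attempt <- as.integer(attempt)
    attr(trial, "truth") <- list(
      cv_pct = cv_pct,
      emg_pct_mvc = 100 * target_frac,
      emg_rms_uV = target_frac * profile$emg_mvc_rms_uV[mus],
      emg_mdf = profile$baseline_mdf_hz,
      plateau_torque = mu
    )
    trial
  })
}

#' Synthesize an explosive sled-extension trial
#'
#' A smooth force pulse (raised-cosine, ~300 ms) against the inclined sled,
#' with velocity obtained from the point-mass sled dynamics
#' ([simulate_sled()]) and push-phase EMG bursts on VL, RF, MG, TA. The
#' truth attribute records the programmed peak force, analytic peak RFD
#' (`peak_force * pi / push_dur`), simulated peak velocity and power, the
#' programmed push duration and the EMG fraction.
#'
#' @inheritParams synth_mvc_trial
#' @param sled A [sled_params()]; defaults to the profile's body mass with
#'   the standard 31.6 kg moving mass and 20 degree incline.
#' @param peak_force_N Programmed peak force; default scales the profile's
#'   MVC torque by 7 N/(N.m), giving ~1600 N for a typical subject.
#' @param push_dur_s Programmed push duration (default 0.3 s).
#' @param emg_frac Push-phase EMG amplitude as a fraction of the MVC
#'   reference (default 0.9).
#' @param duration_s Trial duration (default 2.5 s).
#' @return A [trial_record()] with channels `force`, `velocity`, `VL`, `RF`,
#'   `MG`, `TA`.
#' @export
synth_explosive_trial <- function(profile, sled = NULL, seed = NULL,
                                  rate = 1000, duration_s = 2.5,
                                  peak_force_N = NULL, push_dur_s = 0.3,
                                  emg_frac = 0.9, noise = 1,
                                  condition = "none", time = "Pre",
                                  session = 4L, attempt = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(sled)) sled <- sled_params(body_mass_kg = profile$body_mass_kg)
  if (is.null(peak_force_N)) peak_force_N <- 7 * profile$mvc_torque_Nm
  with_seed(seed, {
    n <- round_half_up(duration_s * rate)
    t <- (seq_len(n) - 1L) / rate
    t0 <- 1.0
    inpush <- t >= t0 & t <= t0 + push_dur_s
    pulse <- numeric(n)
    pulse[inpush] <- peak_force_N * 0.5 *
      (1 - cos(2 * pi * (t[inpush] - t0) / push_dur_s))
    v_true <- simulate_sled(sampled_signal(pulse, rate, "N", "force"), sled)
    force <- pulse + noise * 2 * stats::rnorm(n)
    velocity <- v_true$values + noise * 0.005 * stats::rnorm(n)
    # push window truth: pulse support; velocity decelerates once the force
    # drops below the gravity component on the descending limb
    pow_true <- pulse * v_true$values
    channels <- list(
      force = sampled_signal(force, rate, "N", "force"),
      velocity = sampled_signal(velocity, rate, "m/s", "velocity")
    )
    mus <- c("VL", "RF", "MG", "TA")
    env <- ifelse(inpush, 1, 0.02)
    for (m in mus) {
      e <- synth_emg(duration_s, emg_frac * profile$emg_mvc_rms_uV[[m]],
                     profile$baseline_mdf_hz, rate)
      channels[[m]] <- sampled_signal(e$values * env +
                                        noise * 1.0 * stats::rnorm(n),
                                      rate, "uV", m)
    }
    trial <- trial_record(profile$subject_id, session, condition, time,
                          "explosive", "bilateral", channels)
    trial$attempt <- as.integer(attempt)
    # detectable push duration implied by the waveform and the detection
    # rules: onset at 1% of peak (threshold floor), end at the earlier of
    # force return and the start of deceleration (force below the gravity
    # component on the descending limb); closed form for the raised cosine
    M <- sled$body_mass_kg + sled$moving_mass_kg
    fg <- M * 9.81 * sin(sled$incline_deg * pi / 180)
    r_g <- fg / peak_force_N
    tau_on <- push_dur_s * acos(1 - 2 * 0.01) / (2 * pi)
    tau_end <- if (r_g < 1) {
      min(push_dur_s - tau_on,
          push_dur_s * (1 - acos(1 - 2 * r_g) / (2 * pi)))
    } else {
      push_dur_s - tau_on
    }
    attr(trial, "truth") <- list(
      peak_force = peak_force_N,
      peak_rfd = peak_force_N * pi / push_dur_s,
      peak_velocity = max(v_true$values),
      peak_power = max(pow_true),
      push_dur_s = push_dur_s,
      push_dur_detectable_s = tau_end - tau_on,
      emg_pct_mvc = 100 * emg_frac
    )
    trial
  })
}

#' Synthesize a recruitment-curve stimulation sweep
#'
#' A supine stimulation sweep: single pulses every `isi_s` seconds, 5 per
#' intensity from 5 to 100 mA in 5 mA steps, recorded on left and right VL.
#' Evoked responses are biphasic templates at 15 ms latency whose
#' peak-to-peak amplitude follows a hard-threshold logistic of intensity;
#' after priming (`post_priming = TRUE`) the threshold shifts down (default
#' -6 mA) and the saturation amplitude scales up (default x1.13). Baseline
#' Gaussian noise is added throughout.
#'
#' @inheritParams synth_mvc_trial
#' @param post_priming Logical: generate the post-priming sweep.
#' @param intensities_mA Intensity grid (default `seq(5, 100, 5)`).
#' @param n_per_intensity Stimuli per intensity (default 5).
#' @param isi_s Inter-stimulus interval (default 4 s).
#' @param noise_uV Baseline EMG noise SD (default 2).
#' @param thr_shift_post Post-priming threshold shift in mA (default -6).
#' @param max_scale_post Post-priming amplitude scaling (default 1.13).
#' @return A [trial_record()] with channels `VL_left`, `VL_right` and
#'   stimulus onsets/intensities.
#' @export
synth_recruitment_sweep <- function(profile, post_priming = FALSE, seed = NULL,
                                    rate = 1000,
                                    intensities_mA = seq(5, 100, by = 5),
                                    n_per_intensity = 5L, isi_s = 4,
                                    noise_uV = 2, thr_shift_post = -6,
                                    max_scale_post = 1.13,
                                    condition = "scTS", session = 6L) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(seed, {
    thr <- profile$recruitment_threshold_mA + if (post_priming) thr_shift_post else 0
    amp_max <- profile$recruitment_max_uV * if (post_priming) max_scale_post else 1
    slope <- profile$recruitment_slope
    ints <- rep(intensities_mA, each = n_per_intensity)
    onsets <- 2 + (seq_along(ints) - 1L) * isi_s
    dur <- max(onsets) + 2
    n <- round_half_up(dur * rate)
    # hard-threshold logistic recruitment: zero below threshold
    amp <- ifelse(ints < thr, 0,
                  amp_max / (1 + exp(-(ints - (thr + 15)) / slope)))
    # biphasic template, 10 ms single cycle, normalized to unit peak-to-peak
    # as sampled (so the injected amplitude is exact on the grid)
    tw <- seq(0, 0.01, by = 1 / rate)
    template <- sin(2 * pi * 100 * tw)
    template <- template / (max(template) - min(template))
    lat <- round_half_up(0.015 * rate)
    channels <- list()
    for (side in c("left", "right")) {
      x <- noise_uV * stats::rnorm(n)
      for (i in seq_along(onsets)) {
        if (amp[i] <= 0) next
        i0 <- round_half_up(onsets[i] * rate) + 1L + lat
        idx <- i0:(i0 + length(template) - 1L)
        x[idx] <- x[idx] + amp[i] * template
      }
      channels[[paste0("VL_", side)]] <- sampled_signal(x, rate, "uV",
                                                        paste0("VL_", side))
    }
    trial <- trial_record(profile$subject_id, session, condition,
                          if (post_priming) "Post" else "Pre", "recruitment",
                          "bilateral", channels,
                          stim_onsets_s = onsets, stim_intensities_mA = ints)
    grid_thr <- if (any(intensities_mA >= thr)) {
      min(intensities_mA[intensities_mA >= thr])
    } else NA_real_
    attr(trial, "truth") <- list(
      threshold_mA = thr, threshold_grid_mA = grid_thr,
      max_amp_uV = amp_max, amp_by_intensity = amp[!duplicated(ints)],
      max_curve_uV = max(amp)
    )
    trial
  })
}

# ---------------------------------------------------------------------------
# Cohort-level structure

#' Crossover effect model
#'
#' Programmed Post-Pre percent changes per condition and outcome variable,
#' used by the cohort generators. Defaults follow the study's headline
#' structure: maximum torque +4.7% (scTS) vs -4.3% (sham), peak force +0.2%
#' vs -3.3%, peak RFD +6.0% vs -15.1%, with between-subject SDs of the
#' percent changes derived from the reported between-condition effect sizes
#' (dz = 1.19 for maximum torque). Steadiness CV is programmed with null
#' effects.
#'
#' @param scts_delta_mean_pct,sham_delta_mean_pct Named numeric vectors of
#'   mean Post-Pre percent changes per variable.
#' @param scts_delta_sd_pct,sham_delta_sd_pct Matching SDs (>= 0).
#' @param attempt_cv_pct Within-cell attempt-to-attempt variability
#'   (coefficient of variation, percent).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(
    scts_delta_mean_pct = c(max_torque = 4.7, peak_force = 0.2, peak_rfd = 6.0,
                            cv_pct = 0, emg_pct = 0),
    sham_delta_mean_pct = c(max_torque = -4.3, peak_force = -3.3, peak_rfd = -15.1,
                            cv_pct = 0, emg_pct = 0),
    scts_delta_sd_pct = c(max_torque = 5.35, peak_force = 3.13, peak_rfd = 13.2,
                          cv_pct = 8, emg_pct = 5),
    sham_delta_sd_pct = scts_delta_sd_pct,
    attempt_cv_pct = 3) {
  if (any(scts_delta_sd_pct < 0) || any(sham_delta_sd_pct < 0)) {
    stop("delta SDs must be nonnegative", call. = FALSE)
  }
  structure(list(scts_delta_mean_pct = scts_delta_mean_pct,
                 sham_delta_mean_pct = sham_delta_mean_pct,
                 scts_delta_sd_pct = scts_delta_sd_pct,
                 sham_delta_sd_pct = sham_delta_sd_pct,
                 attempt_cv_pct = attempt_cv_pct),
            class = "effect_model")
}

#' Cohort design
#'
#' Sizes of the simulated crossover cohort: number of subjects and attempts
#' per task, following the experimental protocol (2 steadiness holds and 3
#' MVCs per limb, 4 explosive extensions).
#'
#' @param n_subjects Number of subjects (default 12).
#' @param steadiness_attempts,mvc_attempts,explosive_attempts Attempts per
#'   cell.
#' @param rate Sampling rate for generated signals.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 12L, steadiness_attempts = 2L,
                          mvc_attempts = 3L, explosive_attempts = 4L,
                          rate = 1000) {
  counts <- c(n_subjects, steadiness_attempts, mvc_attempts, explosive_attempts)
  if (any(counts < 1L)) stop("all design counts must be positive", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 steadiness_attempts = as.integer(steadiness_attempts),
                 mvc_attempts = as.integer(mvc_attempts),
                 explosive_attempts = as.integer(explosive_attempts),
                 rate = rate),
            class = "cohort_design")
}

#' Generate an outcome table directly from the effect model
#'
#' Draws the subject x condition x time values of one outcome variable from
#' the cohort-level model without synthesizing signals: Pre values vary
#' between subjects and sessions, Post values apply a per-subject,
#' per-condition percent change drawn from the effect model. This is the
#' fast path for statistical calibration studies (type-I error, power).
#'
#' @param variable Variable name (must appear in the effect model).
#' @param effects An [effect_model()].
#' @param n Number of subjects.
#' @param baseline_mean,baseline_sd Between-subject moments of the Pre value.
#' @param session_cv_pct Session-to-session variability of the Pre value
#'   (percent).
#' @param seed Optional RNG seed.
#' @return An [outcome_table()].
#' @export
synth_outcome_table <- function(variable = "max_torque", effects = effect_model(),
                                n = 12L, baseline_mean = 230, baseline_sd = 35,
                                session_cv_pct = 2, seed = NULL) {
  for (f in c("scts_delta_mean_pct", "sham_delta_mean_pct",
              "scts_delta_sd_pct", "sham_delta_sd_pct")) {
    if (!(variable %in% names(effects[[f]]))) {
      stop(sprintf("variable '%s' not in effect model field %s", variable, f),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    subj <- sprintf("S%02d", seq_len(n))
    base <- stats::rnorm(n, baseline_mean, baseline_sd)
    rows <- list()
    for (cond in c("scTS", "sham")) {
      dm <- if (cond == "scTS") effects$scts_delta_mean_pct[[variable]] else
        effects$sham_delta_mean_pct[[variable]]
      ds <- if (cond == "scTS") effects$scts_delta_sd_pct[[variable]] else
        effects$sham_delta_sd_pct[[variable]]
      pre <- base * (1 + session_cv_pct / 100 * stats::rnorm(n))
      delta <- stats::rnorm(n, dm, ds)
      post <- pre * (1 + delta / 100)
      rows[[paste0(cond, "_Pre")]] <- data.frame(
        subject_id = subj, condition = cond, time = "Pre", value = pre)
      rows[[paste0(cond, "_Post")]] <- data.frame(
        subject_id = subj, condition = cond, time = "Post", value = post)
    }
    outcome_table(variable, do.call(rbind, rows))
  })
}

#' Generate a full synthetic crossover cohort
#'
#' Generates trial-level signals for every subject, condition (scTS/sham),
#' time (Pre/Post), task and attempt of the crossover design, applying the
#' effect model's percent changes to the latent metric before attempt noise
#' so that best-attempt selection interacts realistically with variability.
#' Isometric sessions carry MVC and steadiness trials per limb; explosive
#' sessions carry bilateral sled trials plus a session-opening reference MVC;
#' the optional recruitment session carries Pre/Post stimulation sweeps
#' (scTS only, as in the protocol). A ledger data frame records the
#' programmed ground truth of every attempt and flags the best attempt per
#' cell.
#'
#' @param design A [cohort_design()].
#' @param effects An [effect_model()].
#' @param seed RNG seed for the whole cohort.
#' @param tasks Tasks to generate (any of `"mvc"`, `"steadiness"`,
#'   `"explosive"`, `"recruitment"`).
#' @param dir Optional directory: when given, trials are written as TSV
#'   files in a session-structured tree plus `ledger.tsv` and
#'   `manifest.json`.
#' @param noise Instrumentation-noise scale passed to the trial generators.
#' @return List with `trials` (list of [trial_record()]), `ledger`
#'   (data frame), `profiles` (list of [subject_profile()]).
#' @export
synth_cohort <- function(design = cohort_design(), effects = effect_model(),
                         seed = 1, tasks = c("mvc", "steadiness", "explosive"),
                         dir = NULL, noise = 1) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "effect_model"))
  tasks <- match.arg(tasks, c("mvc", "steadiness", "explosive", "recruitment"),
                     several.ok = TRUE)
  with_seed(seed, {
    trials <- list()
    ledger <- list()
    profiles <- list()
    add_ledger <- function(trial, variable, latent, attempt_value, best = NA) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        subject_id = trial$subject_id, session = trial$session,
        condition = trial$condition, time = trial$time, task = trial$task,
        limb = trial$limb, attempt = trial$attempt, variable = variable,
        latent = latent, attempt_value = attempt_value, best = best)
    }
    delta_for <- function(variable, cond, subj_deltas) {
      d <- subj_deltas[[cond]]
      if (variable %in% names(d)) d[[variable]] else 0
    }
    for (s in seq_len(design$n_subjects)) {
      prof <- sample_subject_profile(sprintf("S%02d", s))
      profiles[[prof$subject_id]] <- prof
      # per-subject, per-condition programmed percent changes
      subj_deltas <- list()
      for (cond in c("scTS", "sham")) {
        dm <- if (cond == "scTS") effects$scts_delta_mean_pct else effects$sham_delta_mean_pct
        ds <- if (cond == "scTS") effects$scts_delta_sd_pct else effects$sham_delta_sd_pct
        subj_deltas[[cond]] <- stats::setNames(
          stats::rnorm(length(dm), dm, ds), names(dm))
      }
      att_noise <- function() 1 + effects$attempt_cv_pct / 100 * stats::rnorm(1)
      for (cond in c("scTS", "sham")) {
        if (any(c("mvc", "steadiness") %in% tasks)) {
          session <- if (cond == "scTS") 2L else 3L
          for (tm in c("Pre", "Post")) {
            post <- tm == "Post"
            for (limb in c("left", "right")) {
              if ("mvc" %in% tasks) {
                lat <- 1 * (1 + post * delta_for("max_torque", cond, subj_deltas) / 100)
                mults <- lat * vapply(seq_len(design$mvc_attempts),
                                      function(a) att_noise(), numeric(1))
                best_i <- which.max(mults)
                for (a in seq_len(design$mvc_attempts)) {
                  tr <- synth_mvc_trial(prof, effect_multiplier = mults[a],
                                        rate = design$rate, noise = noise,
                                        limb = limb, condition = cond, time = tm,
                                        session = session, attempt = a)
                  trials[[length(trials) + 1L]] <- tr
                  add_ledger(tr, "max_torque", lat * prof$mvc_torque_Nm,
                             mults[a] * prof$mvc_torque_Nm, a == best_i)
                }
              }
              if ("steadiness" %in% tasks) {
                base_cv <- 1.5
                lat <- base_cv * (1 + post * delta_for("cv_pct", cond, subj_deltas) / 100)
                cvs <- lat * vapply(seq_len(design$steadiness_attempts),
                                    function(a) abs(att_noise()), numeric(1))
                best_i <- which.min(cvs)
                for (a in seq_len(design$steadiness_attempts)) {
                  tr <- synth_steadiness_trial(prof, cv_pct = cvs[a],
                                               rate = design$rate, noise = noise,
                                               limb = limb, condition = cond,
                                               time = tm, session = session,
                                               attempt = a)
                  trials[[length(trials) + 1L]] <- tr
                  add_ledger(tr, "cv_pct", lat, cvs[a], a == best_i)
                }
              }
            }
          }
        }
        if ("explosive" %in% tasks) {
          session <- if (cond == "scTS") 4L else 5L
          # session-opening reference MVCs (one per limb) for EMG normalization
          for (limb in c("left", "right")) {
            tr <- synth_mvc_trial(prof, effect_multiplier = 1,
                                  rate = design$rate, noise = noise,
                                  muscles = c("VL", "RF", "MG", "TA"),
                                  limb = limb, condition = cond, time = "Pre",
                                  session = session, attempt = 1L)
            trials[[length(trials) + 1L]] <- tr
            add_ledger(tr, "max_torque", prof$mvc_torque_Nm,
                       prof$mvc_torque_Nm, NA)
          }
          f_base <- 7 * prof$mvc_torque_Nm
          t_base <- 0.3
          for (tm in c("Pre", "Post")) {
            post <- tm == "Post"
            d_force <- delta_for("peak_force", cond, subj_deltas)
            d_rfd <- delta_for("peak_rfd", cond, subj_deltas)
            f_lat <- f_base * (1 + post * d_force / 100)
            # RFD = pi * Fpk / T: realize the RFD change through the duration
            t_lat <- t_base * (1 + post * d_force / 100) / (1 + post * d_rfd / 100)
            mults <- vapply(seq_len(design$explosive_attempts),
                            function(a) att_noise(), numeric(1))
            pows <- numeric(design$explosive_attempts)
            cell <- vector("list", design$explosive_attempts)
            for (a in seq_len(design$explosive_attempts)) {
              tr <- synth_explosive_trial(prof, rate = design$rate,
                                          peak_force_N = f_lat * mults[a],
                                          push_dur_s = t_lat, noise = noise,
                                          condition = cond, time = tm,
                                          session = session, attempt = a)
              trials[[length(trials) + 1L]] <- tr
              cell[[a]] <- tr
              pows[a] <- trial_truth(tr)$peak_power
            }
            best_i <- which.max(pows)
            for (a in seq_len(design$explosive_attempts)) {
              tru <- trial_truth(cell[[a]])
              add_ledger(cell[[a]], "peak_force", f_lat, tru$peak_force, a == best_i)
              add_ledger(cell[[a]], "peak_rfd", pi * f_lat / t_lat, tru$peak_rfd,
                         a == best_i)
              add_ledger(cell[[a]], "peak_power", NA_real_, tru$peak_power,
                         a == best_i)
            }
          }
        }
      }
      if ("recruitment" %in% tasks) {
        for (tm in c("Pre", "Post")) {
          tr <- synth_recruitment_sweep(prof, post_priming = (tm == "Post"),
                                        rate = design$rate)
          tr$attempt <- 1L
          trials[[length(trials) + 1L]] <- tr
          tru <- trial_truth(tr)
          add_ledger(tr, "vl_threshold_mA", tru$threshold_mA,
                     tru$threshold_grid_mA, TRUE)
        }
      }
    }
    ledger <- do.call(rbind, ledger)
    out <- list(trials = trials, ledger = ledger, profiles = profiles)
    if (!is.null(dir)) write_cohort(out, dir)
    out
  })
}

# write a cohort to a session-structured directory tree
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cohort$trials))
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    sub <- file.path(dir, tr$subject_id, sprintf("session%d", tr$session))
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    fn <- sprintf("%s_%s_%s_%s_a%d.tsv", tr$task, tr$condition, tr$time,
                  tr$limb, tr$attempt %||% 1L)
    write_trial(tr, file.path(sub, fn))
    paths[i] <- file.path(sub, fn)
  }
  utils::write.table(cohort$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(n_subjects = length(cohort$profiles),
                   n_trials = length(cohort$trials), files = paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
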