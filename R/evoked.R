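#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per stimulus out of a continuous EMG channel and quantifies
#' the evoked potential as the peak-to-peak amplitude within the response
#' window, together with the peak-to-peak amplitude of a pre-stimulus
#' baseline window (used for the noise floor). Default windows are 5-55 ms
#' after and 55-5 ms before the stimulus, clear of the 1 ms stimulus
#' artifact and covering posterior-root-reflex latencies of thigh and calf
#' muscles. Epochs whose windows fall outside the recording are skipped with
#' a warning.
#'
#' @param emg A [sampled_signal()] EMG channel.
#' @param onsets_s Stimulus onset times (seconds), strictly increasing.
#' @param intensities_mA Stimulus intensities aligned with `onsets_s`.
#' @param resp_win Response window relative to the stimulus, seconds.
#' @param base_win Baseline window relative to the stimulus, seconds
#'   (negative = before).
#' @return A data.frame with one row per epoch: `stim_time_s`,
#'   `intensity_mA`, `p2p_uV`, `base_p2p_uV`.
#' @export
extract_epochs <- function(emg, onsets_s, intensities_mA,
                           resp_win = c(0.005, 0.055),
                           base_win = c(-0.055, -0.005)) {
  stopifnot(inherits(emg, "sampled_signal"))
  if (length(onsets_s) != length(intensities_mA)) {
    stop("onsets and intensities must have equal length", call. = FALSE)
  }
  if (resp_win[1] < 0 || resp_win[2] <= resp_win[1]) {
    stop("response window must lie after the stimulus", call. = FALSE)
  }
  if (base_win[2] > 0 || base_win[1] >= base_win[2]) {
    stop("baseline window must lie before the stimulus", call. = FALSE)
  }
  rate <- emg$rate
  n <- length(emg$values)
  rows <- vector("list", length(onsets_s))
  skipped <- 0L
  for (i in seq_along(onsets_s)) {
    on_i <- round_half_up(onsets_s[i] * rate) + 1L
    ri <- (on_i + round_half_up(resp_win[1] * rate)):(on_i + round_half_up(resp_win[2] * rate))
    bi <- (on_i + round_half_up(base_win[1] * rate)):(on_i + round_half_up(base_win[2] * rate))
    if (min(bi) < 1L || max(ri) > n) {
      skipped <- skipped + 1L
      next
    }
    r <- emg$values[ri]
    b <- emg$values[bi]
    rows[[i]] <- data.frame(stim_time_s = onsets_s[i],
                            intensity_mA = intensities_mA[i],
                            p2p_uV = max(r) - min(r),
                            base_p2p_uV = max(b) - min(b))
  }
  if (skipped > 0L) {
    warning(sprintf("%d epoch(s) skipped: window outside recording", skipped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(stim_time_s = numeric(0),
                                      intensity_mA = numeric(0),
                                      p2p_uV = numeric(0),
                                      base_p2p_uV = numeric(0))
  out
}

#' Baseline noise floor
#'
#' Mean and SD of the baseline-window peak-to-peak amplitudes pooled across
#' epochs. The activation-threshold criterion is `mean + 3 * sd`.
#'
#' @param epochs Epoch data.frame from [extract_epochs()].
#' @param min_epochs Minimum number of baseline windows (default 10).
#' @return List with `mean_uV` and `sd_uV`.
#' @export
noise_floor <- function(epochs, min_epochs = 10L) {
  if (nrow(epochs) < min_epochs) {
    stop(sprintf("insufficient data: %d baseline windows < %d", nrow(epochs),
                 min_epochs), call. = FALSE)
  }
  list(mean_uV = mean(epochs$base_p2p_uV), sd_uV = stats::sd(epochs$base_p2p_uV))
}

#' Build a recruitment curve from epochs
#'
#' Groups stimulus-locked epochs by intensity and averages the per-stimulus
#' peak-to-peak amplitudes (five stimuli per intensity in the supported
#' protocol). `max_p2p_uV` is the largest per-intensity mean. Missing levels
#' of the expected 5 mA grid are flagged in `gaps_mA`.
#'
#' @param epochs Epoch data.frame from [extract_epochs()].
#' @param muscle,side Labels carried on the curve.
#' @return An object of class `recruitment_curve`.
#' @export
build_curve <- function(epochs, muscle = "VL", side = c("left", "right")) {
  side <- match.arg(side)
  if (nrow(epochs) == 0L) stop("no epochs to build a curve from", call. = FALSE)
  ints <- sort(unique(epochs$intensity_mA))
  per_stim <- lapply(ints, function(I) epochs$p2p_uV[epochs$intensity_mA == I])
  mean_p2p <- vapply(per_stim, mean, numeric(1))
  step <- if (length(ints) > 1L) min(diff(ints)) else NA_real_
  gaps <- numeric(0)
  if (length(ints) > 1L && is.finite(step) && step > 0) {
    grid <- seq(min(ints), max(ints), by = step)
    gaps <- setdiff(round(grid, 9), round(ints, 9))
    if (length(gaps)) {
      warning(sprintf("recruitment curve has gap(s) at %s mA",
                      paste(gaps, collapse = ", ")))
    }
  }
  structure(
    list(muscle = muscle, side = side, intensities_mA = ints,
         mean_p2p_uV = mean_p2p, per_stim_p2p = per_stim,
         threshold_mA = NA_real_, max_p2p_uV = max(mean_p2p),
         normalized_pct = NULL, gaps_mA = gaps),
    class = "recruitment_curve"
  )
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("<recruitment_curve> %s (%s): %d intensities %g-%g mA, max p2p %.1f\n",
              x$muscle, x$side, length(x$intensities_mA),
              min(x$intensities_mA), max(x$intensities_mA), x$max_p2p_uV))
  if (!is.na(x$threshold_mA)) cat(sprintf("  activation threshold: %g mA\n", x$threshold_mA))
  invisible(x)
}

#' Muscle activation threshold
#'
#' The lowest stimulation intensity evoking reproducible responses above the
#' noise floor criterion (baseline mean + 3 SD). "Reproducible" is
#' operationalized as at least `min_frac` (default 4/5) of the per-stimulus
#' responses exceeding the criterion at the candidate intensity *and* at the
#' next available intensity; the final intensity of a sweep, having no
#' confirmation step, qualifies on its own responses. Thresholds are
#' reported on the stimulation grid (no interpolation).
#'
#' @param curve A [build_curve()] result.
#' @param floor A [noise_floor()] result.
#' @param min_frac Minimum fraction of supra-criterion responses (default 0.8).
#' @return Threshold intensity in mA, or `NA` if no intensity qualifies.
#' @export
activation_threshold <- function(curve, floor, min_frac = 0.8) {
  stopifnot(inherits(curve, "recruitment_curve"))
  crit <- floor$mean_uV + 3 * floor$sd_uV
  nI <- length(curve$intensities_mA)
  ok <- vapply(curve$per_stim_p2p, function(p) {
    mean(p > crit) >= min_frac
  }, logical(1))
  for (i in seq_len(nI)) {
    if (!ok[i]) next
    if (i == nI || ok[i + 1L]) return(curve$intensities_mA[i])
  }
  NA_real_
}

#' Normalize a Pre/Post pair of recruitment curves
#'
#' Expresses both curves as a percentage of the largest per-intensity mean
#' amplitude observed across the Pre and Post sweeps (joint maximum, the
#' default), so exactly one curve attains 100%. Set `scope = "per_phase"` to
#' normalize each curve to its own maximum instead.
#'
#' @param pre,post [build_curve()] results for the same muscle and side.
#' @param scope `"joint"` (default) or `"per_phase"`.
#' @return List with elements `pre` and `post`, each with `normalized_pct`
#'   filled in.
#' @export
normalize_curves <- function(pre, post, scope = c("joint", "per_phase")) {
  scope <- match.arg(scope)
  stopifnot(inherits(pre, "recruitment_curve"), inherits(post, "recruitment_curve"))
  if (pre$muscle != post$muscle || pre$side != post$side) {
    stop("curves must be from the same muscle and side", call. = FALSE)
  }
  if (max(pre$max_p2p_uV, post$max_p2p_uV) <= 0) {
    stop("cannot normalize: both curves have zero amplitude", call. = FALSE)
  }
  if (scope == "joint") {
    ref <- max(pre$max_p2p_uV, post$max_p2p_uV)
    pre$normalized_pct <- 100 * pre$mean_p2p_uV / ref
    post$normalized_pct <- 100 * post$mean_p2p_uV / ref
  } else {
    pre$normalized_pct <- 100 * pre$mean_p2p_uV / pre$max_p2p_uV
    post$normalized_pct <- 100 * post$mean_p2p_uV / post$max_p2p_uV
  }
  list(pre = pre, post = post)
}

#' Average left and right recruitment curves
#'
#' Point-wise mean of the normalized amplitudes (and of the thresholds and
#' maxima) of two curves on the same intensity grid, collapsing the bilateral
#' recordings to one subject-level curve.
#'
#' @param left,right Normalized [build_curve()] results on matching grids.
#' @return A list with `intensities_mA`, `normalized_pct`, `mean_p2p_uV`,
#'   `threshold_mA`, `max_p2p_uV`.
#' @export
average_bilateral <- function(left, right) {
  stopifnot(inherits(left, "recruitment_curve"), inherits(right, "recruitment_curve"))
  if (!isTRUE(all.equal(left$intensities_mA, right$intensities_mA))) {
    stop("intensity grids do not match", call. = FALSE)
  }
  norm <- if (!is.null(left$normalized_pct) && !is.null(right$normalized_pct)) {
    (left$normalized_pct + right$normalized_pct) / 2
  } else NULL
  list(intensities_mA = left$intensities_mA,
       normalized_pct = norm,
       mean_p2p_uV = (left$mean_p2p_uV + right$mean_p2p_uV) / 2,
       threshold_mA = mean(c(left$threshold_mA, right$threshold_mA)),
       max_p2p_uV = mean(c(left$max_p2p_uV, right$max_p2p_uV)))
}
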