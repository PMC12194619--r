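test_that("epoch extraction quantifies injected templates and counts stimuli", {
  rate <- 1000
  n <- 130 * rate
  x <- numeric(n)
  onsets <- 2 + (0:29) * 4          # 30 stimuli, 4 s apart, in a 130 s trace
  ints <- rep(seq(5, 30, 5), each = 5)
  # biphasic template +/- 50 uV at 15 ms latency
  for (o in onsets) {
    i0 <- round(o * rate) + 15
    x[i0:(i0 + 4)] <- 50
    x[(i0 + 5):(i0 + 9)] <- -50
  }
  ep <- extract_epochs(sampled_signal(x, rate, "uV"), onsets, ints)
  expect_equal(nrow(ep), 30)
  expect_true(all(abs(ep$p2p_uV - 100) < 1e-9))
  expect_true(all(ep$base_p2p_uV == 0))

  # flat EMG -> zero p2p
  ep0 <- extract_epochs(sampled_signal(numeric(n), rate), onsets, ints)
  expect_true(all(ep0$p2p_uV == 0))

  # stimulus too close to the edge is skipped with a warning
  expect_warning(
    ep2 <- extract_epochs(sampled_signal(x[1:(3 * rate)], rate),
                          c(0.02, 2), c(5, 5)),
    "skipped")
  expect_equal(nrow(ep2), 1)
  expect_error(extract_epochs(sampled_signal(x, rate), onsets, ints[1:3]),
               "equal length")
})

test_that("noise floor matches a Monte-Carlo oracle for Gaussian baselines", {
  rate <- 1000
  sigma <- 3
  set.seed(8)
  onsets <- 2 + (0:99) * 4
  n <- (max(onsets) + 2) * rate
  x <- rnorm(n, sd = sigma)
  ep <- extract_epochs(sampled_signal(x, rate), onsets, rep(5, 100))
  nf <- noise_floor(ep)
  # oracle: direct simulation of the peak-to-peak of 51-sample Gaussian windows
  mc <- replicate(4000, { w <- rnorm(51, sd = sigma); max(w) - min(w) })
  expect_equal(nf$mean_uV, mean(mc), tolerance = 0.10 * mean(mc))
  expect_equal(nf$sd_uV, sd(mc), tolerance = 0.25 * sd(mc))

  # degenerate cases
  ep0 <- data.frame(stim_time_s = 1:12, intensity_mA = 5, p2p_uV = 0,
                    base_p2p_uV = 0)
  expect_equal(noise_floor(ep0), list(mean_uV = 0, sd_uV = 0))
  expect_error(noise_floor(ep0[1:5, ]), "insufficient")
})

test_that("recruitment curves aggregate per-stimulus amplitudes", {
  ints <- rep(seq(5, 100, 5), each = 5)
  set.seed(2)
  p2p <- 10 * (ints >= 50) * (1 + 0.05 * rnorm(length(ints)))
  ep <- data.frame(stim_time_s = seq_along(ints), intensity_mA = ints,
                   p2p_uV = p2p, base_p2p_uV = 0.1)
  cu <- build_curve(ep, "VL", "left")
  expect_equal(length(cu$intensities_mA), 20)
  for (k in seq_along(cu$intensities_mA)) {
    expect_equal(cu$mean_p2p_uV[k], mean(cu$per_stim_p2p[[k]]))
  }
  expect_equal(cu$max_p2p_uV, max(cu$mean_p2p_uV))

  zero <- ep; zero$p2p_uV <- 0
  cuz <- build_curve(zero, "VL", "left")
  expect_equal(cuz$max_p2p_uV, 0)

  gap <- ep[ep$intensity_mA != 40, ]
  expect_warning(cg <- build_curve(gap, "VL", "left"), "gap")
  expect_equal(cg$gaps_mA, 40)
})

test_that("activation threshold follows the noise-floor + reproducibility rule", {
  ints <- rep(seq(5, 100, 5), each = 5)
  p2p <- ifelse(ints >= 50, 20, 0)
  ep <- data.frame(stim_time_s = seq_along(ints), intensity_mA = ints,
                   p2p_uV = p2p, base_p2p_uV = 0)
  cu <- build_curve(ep, "VL", "left")
  expect_equal(activation_threshold(cu, list(mean_uV = 0, sd_uV = 0)), 50)

  # all subthreshold -> none
  expect_true(is.na(activation_threshold(cu, list(mean_uV = 25, sd_uV = 0))))

  # monotone in the floor: a larger SD can never lower the threshold
  set.seed(9)
  noisy <- ep
  noisy$p2p_uV <- pmax(0, p2p + rnorm(length(ints), sd = 4)) +
    abs(rnorm(length(ints), sd = 1))
  cun <- build_curve(noisy, "VL", "left")
  thr_prev <- -Inf
  for (sdv in seq(0, 10, by = 0.5)) {
    th <- activation_threshold(cun, list(mean_uV = 2, sd_uV = sdv))
    thv <- if (is.na(th)) Inf else th
    expect_gte(thv, thr_prev)
    thr_prev <- thv
  }
})

test_that("normalization uses the joint maximum and preserves curve shape", {
  ints <- rep(seq(5, 100, 5), each = 5)
  mk <- function(scale) {
    p2p <- scale * plogis((ints - 50) / 8)
    build_curve(data.frame(stim_time_s = seq_along(ints), intensity_mA = ints,
                           p2p_uV = p2p, base_p2p_uV = 0), "VL", "left")
  }
  pre <- mk(2); post <- mk(4)
  nc <- normalize_curves(pre, post)
  expect_equal(max(nc$post$normalized_pct), 100)
  expect_equal(max(nc$pre$normalized_pct), 50, tolerance = 1e-9)

  same <- normalize_curves(mk(2), mk(2))
  expect_equal(max(same$pre$normalized_pct), 100)
  expect_equal(max(same$post$normalized_pct), 100)

  # shape preservation: ratio of any two points unchanged
  r_raw <- pre$mean_p2p_uV[15] / pre$mean_p2p_uV[10]
  r_norm <- nc$pre$normalized_pct[15] / nc$pre$normalized_pct[10]
  expect_equal(r_norm, r_raw, tolerance = 1e-12)

  # per-phase option: each curve attains 100%
  pp <- normalize_curves(pre, post, scope = "per_phase")
  expect_equal(max(pp$pre$normalized_pct), 100)

  z <- mk(0)
  expect_error(normalize_curves(z, z), "zero amplitude")
})

test_that("bilateral averaging is point-wise and averages thresholds", {
  ints <- rep(seq(5, 100, 5), each = 5)
  mk <- function(scale, side, thr) {
    cu <- build_curve(data.frame(stim_time_s = seq_along(ints),
                                 intensity_mA = ints,
                                 p2p_uV = scale * plogis((ints - 50) / 8),
                                 base_p2p_uV = 0), "VL", side)
    cu$threshold_mA <- thr
    cu$normalized_pct <- 100 * cu$mean_p2p_uV / cu$max_p2p_uV
    cu
  }
  L <- mk(2, "left", 40); R <- mk(3, "right", 50)
  avg <- average_bilateral(L, R)
  expect_equal(avg$threshold_mA, 45)
  expect_equal(avg$normalized_pct, (L$normalized_pct + R$normalized_pct) / 2)
  same <- average_bilateral(L, L)
  expect_equal(same$mean_p2p_uV, L$mean_p2p_uV)

  R2 <- R; R2$intensities_mA <- R2$intensities_mA + 5
  expect_error(average_bilateral(L, R2), "do not match")
})

test_that("generated sweeps reproduce the programmed recruitment curve", {
  prof <- fixture_profile()
  rs <- synth_recruitment_sweep(prof, seed = 15, noise_uV = 0)
  tru <- trial_truth(rs)
  expect_equal(length(rs$stim_onsets_s), 100)  # 20 intensities x 5 stimuli
  ep <- extract_epochs(rs$channels$VL_left, rs$stim_onsets_s,
                       rs$stim_intensities_mA)
  cu <- build_curve(ep, "VL", "left")
  expect_equal(length(cu$intensities_mA), 20)
  expect_equal(cu$mean_p2p_uV, tru$amp_by_intensity, tolerance = 1e-9)
  # zero noise: threshold recovered exactly on the grid
  expect_equal(activation_threshold(cu, noise_floor(ep)), tru$threshold_grid_mA)
  # zero-noise curves are non-decreasing in intensity up to saturation
  expect_true(all(diff(cu$mean_p2p_uV) > -1e-9))

  # post-priming: threshold shifts down, maximum scales up
  rp <- synth_recruitment_sweep(prof, post_priming = TRUE, seed = 16,
                                noise_uV = 0)
  trup <- trial_truth(rp)
  expect_equal(trup$threshold_mA, tru$threshold_mA - 6)
  expect_equal(trup$max_amp_uV, tru$max_amp_uV * 1.13)
})
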