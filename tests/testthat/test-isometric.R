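test_that("max torque window: constant, ramp oracle, and earliest-tie rule", {
  const <- sampled_signal(rep(100, 400), 100)
  w <- max_torque_window(const, win_s = 1)
  expect_equal(w$value, 100)
  expect_equal(w$start_s, 0)

  # triangular ramp 0 -> 200 -> 0 over 4 s: window centred at the apex
  rate <- 100
  x <- c(seq(0, 200, length.out = 200), seq(200, 0, length.out = 200))
  s <- sampled_signal(x, rate)
  w <- max_torque_window(s, win_s = 1)
  br <- brute_max_window(x, rate, 1)
  expect_equal(w$value, br$value)
  expect_equal(w$start_s, br$start_s)
  expect_equal(w$start_s + 0.5, 2, tolerance = 0.05)  # centred at apex

  # two equal plateaus: earlier start returned
  x2 <- rep(0, 500); x2[101:200] <- 50; x2[301:400] <- 50
  w2 <- max_torque_window(sampled_signal(x2, 100), win_s = 1)
  expect_equal(w2$start_s, 1.0)

  expect_error(max_torque_window(sampled_signal(1:10, 100), win_s = 1), "short")
})

test_that("sliding-window searches equal exhaustive brute force on random traces", {
  set.seed(11)
  for (r in 1:20) {
    rate <- 100
    x <- 50 + cumsum(rnorm(1200, sd = 0.5)) + rnorm(1200)
    x <- x - min(x) + 10  # keep means positive for the CV search
    s <- sampled_signal(x, rate)
    wm <- max_torque_window(s, win_s = 1)
    bm <- brute_max_window(x, rate, 1)
    expect_equal(wm$value, bm$value, tolerance = 1e-10)
    expect_equal(wm$start_s, bm$start_s)
    expect_lte(wm$value, max(x))
    wc <- steadiness_cv(s, win_s = 10)
    bc <- brute_min_cv(x, rate, 10)
    expect_equal(wc$cv, bc$cv, tolerance = 1e-10)
    expect_equal(wc$start_s, bc$start_s)
  }
})

test_that("steadiness CV: zero variance, closed form, programmed quiet segment", {
  const <- sampled_signal(rep(80, 1500), 100)
  w <- steadiness_cv(const, win_s = 10)
  expect_equal(w$cv, 0)
  expect_equal(w$start_s, 0)

  # square alternation mu +/- delta over whole periods: CV = delta / mu
  mu <- 50; delta <- 2
  x <- mu + delta * rep(c(1, -1), each = 5, times = 150)  # 10-sample period
  w2 <- steadiness_cv(sampled_signal(x, 100), win_s = 10)
  expect_equal(w2$cv, delta / mu, tolerance = 1e-3)

  # noisy trace with a programmed quiet segment
  set.seed(3)
  x3 <- 100 + rnorm(1500, sd = 5)
  x3[301:1400] <- 100 + rnorm(1100, sd = 0.5)  # quiet from 3 s to 14 s
  w3 <- steadiness_cv(sampled_signal(x3, 100), win_s = 10)
  b3 <- brute_min_cv(x3, 100, 10)
  expect_equal(w3$cv, b3$cv, tolerance = 1e-10)
  expect_gte(w3$start_s, 3); expect_lte(w3$start_s, 4)

  expect_error(steadiness_cv(sampled_signal(rnorm(1500), 100), win_s = 10),
               "nonpositive")
})

test_that("peak RTD: constant slope, flat trace, analytic sigmoid, reversed trace", {
  rate <- 1000
  ramp <- sampled_signal(c(rep(0, 300), seq(0, 100, by = 0.5), rep(100, 300)), rate)
  expect_equal(peak_rtd(ramp), 500, tolerance = 0.01 * 500)

  expect_warning(r0 <- peak_rtd(sampled_signal(rep(50, 1000), rate)), "no rising")
  expect_equal(r0, 0)

  # logistic rise: analytic max slope = A * k / 4
  t <- seq(0, 3, by = 1e-3)
  A <- 180; k <- 10
  sig <- sampled_signal(A * plogis(k * (t - 1.5)), rate)
  expect_equal(peak_rtd(sig), A * k / 4, tolerance = 0.02 * A * k / 4)

  # time-reversed rising trace: maximum at the first sample, no rising phase
  expect_warning(rr <- peak_rtd(sampled_signal(rev(A * plogis(k * (t - 1.5))), rate)),
                 "no rising")
  expect_equal(rr, 0)
})

test_that("MVC metrics: self-normalization, KE aggregation, ledger round trip", {
  prof <- fixture_profile()
  tr <- synth_mvc_trial(prof, effect_multiplier = 1, seed = 11, noise = 0)
  ref <- mvc_reference(tr)
  tru <- trial_truth(tr)
  expect_equal(ref$max_torque, tru$max_torque, tolerance = 0.02)

  # normalizing a trial by its own max-window RMS gives exactly 100%
  m_self <- mvc_metrics(tr, emg_mvc_ref = ref$ref_rms)
  expect_equal(unname(m_self$emg_rms_pct_mvc), c(100, 100))

  m <- mvc_metrics(tr, emg_mvc_ref = prof$emg_mvc_rms_uV)
  expect_equal(m$max_torque, tru$max_torque, tolerance = 0.02 * tru$max_torque)
  expect_equal(m$peak_rtd, tru$peak_rtd, tolerance = 0.02 * tru$peak_rtd)
  # KE values are the VL/RF means by definition
  expect_equal(m$ke_emg_rms_pct_mvc, mean(m$emg_rms_pct_mvc))
  expect_equal(m$ke_mdf, mean(m$emg_mdf))
  # 1 s spectral windows carry sampling noise; see the methods vignette
  expect_equal(unname(m$emg_mdf), rep(tru$emg_mdf, 2), tolerance = 15 / tru$emg_mdf)

  expect_error(mvc_metrics(tr, emg_mvc_ref = c(VL = 400)), "emg_mvc_ref")
  tr2 <- tr; tr2$channels$VL <- NULL
  expect_error(mvc_metrics(tr2, emg_mvc_ref = prof$emg_mvc_rms_uV), "missing channel")
})

test_that("%MVC is invariant to common rescaling of EMG and reference", {
  prof <- fixture_profile()
  tr <- synth_mvc_trial(prof, seed = 13, noise = 0)
  ref <- prof$emg_mvc_rms_uV
  m1 <- mvc_metrics(tr, emg_mvc_ref = ref)
  tr2 <- tr
  for (m in c("VL", "RF")) tr2$channels[[m]]$values <- 3.7 * tr2$channels[[m]]$values
  m2 <- mvc_metrics(tr2, emg_mvc_ref = 3.7 * ref)
  expect_equal(m1$emg_rms_pct_mvc, m2$emg_rms_pct_mvc, tolerance = 1e-10)
})

test_that("steadiness metrics recover the programmed hold and average into KE", {
  prof <- fixture_profile()
  tr <- synth_steadiness_trial(prof, cv_pct = 1.5, seed = 12, noise = 0)
  sm <- steadiness_metrics(tr, emg_mvc_ref = prof$emg_mvc_rms_uV)
  expect_equal(sm$cv_pct, 1.5, tolerance = 0.3 / 1.5)
  expect_equal(unname(sm$emg_rms_pct_mvc), c(20, 20), tolerance = 0.05)
  expect_equal(sm$ke_emg_rms_pct_mvc, mean(sm$emg_rms_pct_mvc))

  tr0 <- synth_steadiness_trial(prof, cv_pct = 0, seed = 12, noise = 0)
  sm0 <- steadiness_metrics(tr0, emg_mvc_ref = prof$emg_mvc_rms_uV)
  expect_lt(sm0$cv_pct, 0.05)
})

test_that("limb averaging is a field-wise mean and type-checked", {
  prof <- fixture_profile()
  trL <- synth_mvc_trial(prof, seed = 21, noise = 0, limb = "left")
  trR <- synth_mvc_trial(prof, effect_multiplier = 0.9, seed = 22, noise = 0,
                         limb = "right")
  mL <- mvc_metrics(trL, emg_mvc_ref = prof$emg_mvc_rms_uV)
  mR <- mvc_metrics(trR, emg_mvc_ref = prof$emg_mvc_rms_uV)
  avg <- average_limbs(mL, mR)
  expect_equal(avg$max_torque, (mL$max_torque + mR$max_torque) / 2)
  expect_equal(avg$emg_rms_pct_mvc, (mL$emg_rms_pct_mvc + mR$emg_rms_pct_mvc) / 2)
  expect_equal(average_limbs(mL, mL)$max_torque, mL$max_torque)

  st <- steadiness_metrics(synth_steadiness_trial(prof, seed = 23, noise = 0),
                           emg_mvc_ref = prof$emg_mvc_rms_uV)
  expect_error(average_limbs(mL, st), "same type")
})
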