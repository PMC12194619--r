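test_that("synthetic EMG hits its RMS and MDF targets and is reproducible", {
  e <- synth_emg(10, 100, 80, seed = 3)
  expect_equal(signal_rms(e), 100, tolerance = 0.02)
  ef <- apply_filter(e, emg_filter())
  expect_equal(median_power_frequency(ef), 80, tolerance = 5 / 80)

  e2 <- synth_emg(10, 100, 80, seed = 3)
  expect_identical(e$values, e2$values)

  expect_error(synth_emg(5, 100, 5), "infeasible")
  expect_error(synth_emg(5, 100, 400), "infeasible")
  expect_error(synth_emg(5, -1, 80), "positive")
})

test_that("subject profiles stay inside the anthropometric inclusion window", {
  for (s in 1:30) {
    p <- sample_subject_profile(sprintf("S%02d", s), seed = 100 + s)
    b <- profile_bmi(p)
    expect_gte(b, 18.5); expect_lte(b, 29.9)
    expect_gt(p$mvc_torque_Nm, 0)
  }
})

test_that("MVC generator round trip and the no-rise degenerate case", {
  prof <- fixture_profile()
  tr <- synth_mvc_trial(prof, effect_multiplier = 0.95, seed = 19, noise = 0)
  tru <- trial_truth(tr)
  m <- mvc_metrics(tr, emg_mvc_ref = prof$emg_mvc_rms_uV)
  expect_equal(m$max_torque, tru$max_torque, tolerance = 0.02 * tru$max_torque)
  expect_equal(m$peak_rtd, tru$peak_rtd, tolerance = 0.02 * tru$peak_rtd)
  expect_equal(unname(m$emg_rms_pct_mvc), rep(95, 2), tolerance = 0.02 * 95)

  # determinism: identical seed and parameters -> identical trial
  tr2 <- synth_mvc_trial(prof, effect_multiplier = 0.95, seed = 19, noise = 0)
  expect_identical(tr$channels$torque$values, tr2$channels$torque$values)
  expect_identical(tr$channels$VL$values, tr2$channels$VL$values)

  # multiplier 0: no rise anywhere
  tr0 <- synth_mvc_trial(prof, effect_multiplier = 0, seed = 20)
  expect_lt(max(abs(tr0$channels$torque$values)), 5)
})

test_that("steadiness and explosive generators are reproducible and physical", {
  prof <- fixture_profile()
  st1 <- synth_steadiness_trial(prof, seed = 5)
  st2 <- synth_steadiness_trial(prof, seed = 5)
  expect_identical(st1$channels$torque$values, st2$channels$torque$values)
  # plateau level is 20% of MVC
  expect_equal(mean(st1$channels$torque$values[5000:15000]),
               0.2 * prof$mvc_torque_Nm, tolerance = 0.01 * prof$mvc_torque_Nm)

  # a push weaker than the gravity component never moves the sled
  weak <- synth_explosive_trial(prof, seed = 6, peak_force_N = 100, noise = 0)
  expect_true(all(weak$channels$velocity$values == 0))

  tr <- synth_explosive_trial(prof, seed = 7)
  pw <- tr$channels$force$values * tr$channels$velocity$values
  expect_lte(max(pw),
             max(tr$channels$force$values) * max(tr$channels$velocity$values))
  expect_lte(trial_truth(tr)$peak_power,
             trial_truth(tr)$peak_force * trial_truth(tr)$peak_velocity)
})

test_that("noisy recruitment sweeps recover the programmed threshold within one step", {
  prof <- subject_profile("S01", recruitment_threshold_mA = 45)
  hits <- 0L
  nseeds <- 20  # scaled-down spot check; 200 seeds in the acceptance suite
  for (s in seq_len(nseeds)) {
    rs <- synth_recruitment_sweep(prof, seed = 300 + s)
    ep <- extract_epochs(rs$channels$VL_left, rs$stim_onsets_s,
                         rs$stim_intensities_mA)
    thr <- activation_threshold(build_curve(ep, "VL", "left"), noise_floor(ep))
    if (!is.na(thr) && abs(thr - trial_truth(rs)$threshold_grid_mA) <= 5) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / nseeds, 0.9)
})

test_that("cohort generation: ledger flags match pipeline best-attempt selection", {
  design <- cohort_design(n_subjects = 3, steadiness_attempts = 1,
                          mvc_attempts = 2, explosive_attempts = 2)
  co <- synth_cohort(design, seed = 9, tasks = "mvc")
  an <- analyze_cohort(co)

  led <- co$ledger[co$ledger$variable == "max_torque" & !is.na(co$ledger$best) &
                     co$ledger$best, ]
  at <- an$attempts[an$attempts$variable == "max_torque", ]
  sel <- select_best_attempt(
    data.frame(subject_id = paste(at$subject_id, at$limb), condition = at$condition,
               time = at$time, attempt = at$attempt, value = at$value), "mvc")
  key <- function(s, c, t, a) paste(s, c, t, a)
  expect_setequal(key(paste(led$subject_id, led$limb), led$condition, led$time,
                      led$attempt),
                  key(sel$subject_id, sel$condition, sel$time, sel$attempt))

  # programmed Post/Pre structure: analysed best values track the ledger's
  # latent cell values
  b <- an$best[an$best$variable == "max_torque", ]
  led_best <- co$ledger[co$ledger$variable == "max_torque" & !is.na(co$ledger$best) &
                          co$ledger$best, ]
  led_cell <- stats::aggregate(attempt_value ~ subject_id + condition + time,
                               data = led_best, FUN = mean)
  mrg <- merge(b, led_cell, by = c("subject_id", "condition", "time"))
  expect_equal(mrg$value, mrg$attempt_value, tolerance = 0.005)
})

test_that("cohort trees round-trip through the TSV tree deterministically", {
  design <- cohort_design(n_subjects = 1, steadiness_attempts = 1,
                          mvc_attempts = 1, explosive_attempts = 1)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  co1 <- synth_cohort(design, seed = 4, tasks = "mvc", dir = d1)
  co2 <- synth_cohort(design, seed = 4, tasks = "mvc", dir = d2)
  f1 <- list.files(d1, recursive = TRUE, pattern = "_a\\d+\\.tsv$", full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, pattern = "_a\\d+\\.tsv$", full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))  # byte-identical
  }
  back <- read_cohort(d1)
  expect_equal(length(back$trials), length(co1$trials))
  key <- function(tr) paste(tr$subject_id, tr$session, tr$condition, tr$time,
                            tr$task, tr$limb, tr$attempt)
  orig <- co1$trials[[match(key(back$trials[[1]]),
                            vapply(co1$trials, key, character(1)))]]
  expect_equal(back$trials[[1]]$channels$torque$values,
               orig$channels$torque$values, tolerance = 1e-8)
})
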