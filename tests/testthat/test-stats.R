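test_that("best-attempt selection applies the task rules with earliest ties", {
  at <- data.frame(subject_id = "S01", condition = "scTS", time = "Pre",
                   attempt = 1:2, value = c(1.8, 1.2))
  expect_equal(select_best_attempt(at, "steadiness")$attempt, 2L)

  at2 <- data.frame(subject_id = "S01", condition = "scTS", time = "Pre",
                    attempt = 1:3, value = c(210, 195, 220))
  expect_equal(select_best_attempt(at2, "mvc")$attempt, 3L)

  # exact tie -> earliest attempt
  at3 <- data.frame(subject_id = "S01", condition = "scTS", time = "Pre",
                    attempt = 1:3, value = c(220, 220, 200))
  expect_equal(select_best_attempt(at3, "explosive")$attempt, 1L)

  cells <- data.frame(subject_id = "S01", condition = "sham", time = "Post")
  expect_error(select_best_attempt(at, "mvc", expect = cells), "S01 sham Post")
})

test_that("outcome tables enforce complete cells and compute percent changes", {
  Y <- cbind(c(200, 210), c(220, 205), c(198, 215), c(190, 212))
  tab <- fixture_table(rbind(Y, c(205, 205, 205, 205)))
  dp <- tab$delta_pct
  expect_equal(dp$delta_pct[dp$subject_id == "S01" & dp$condition == "scTS"],
               100 * (220 - 200) / 200)
  rows <- tab$rows[-1, ]
  expect_error(outcome_table("x", rows), "incomplete cells")
  rows0 <- tab$rows; rows0$value[1] <- 0
  expect_error(outcome_table("x", rows0), "delta_pct undefined")
})

test_that("2x2 within-subject ANOVA matches the projection oracle and aov", {
  set.seed(21)
  for (r in 1:10) {
    Y <- matrix(rnorm(12 * 4, 200, 15), 12, 4) + rnorm(12, 0, 25)
    tab <- fixture_table(Y)
    a <- rm_anova_2x2(tab)
    o <- anova_projection_oracle(Y)
    expect_equal(a$effects$SS, unname(o$SS), tolerance = 1e-8)
    expect_equal(a$effects$SS_error, unname(o$SS_error), tolerance = 1e-8)
    expect_equal(a$effects$F, unname(o$F), tolerance = 1e-8)
    # conservation: total SS = sum of all effect and stratum SS
    expect_equal(a$SS_total, sum(a$effects$SS) + sum(a$strata$SS),
                 tolerance = 1e-8 * a$SS_total)
  }
  # independent route: base aov with the within-subject error structure
  Y <- matrix(rnorm(8 * 4, 100, 10), 8, 4)
  tab <- fixture_table(Y)
  a <- rm_anova_2x2(tab)
  d <- tab$rows
  d$subject_id <- factor(d$subject_id)
  d$time <- factor(d$time); d$condition <- factor(d$condition)
  fit <- summary(stats::aov(value ~ time * condition +
                              Error(subject_id / (time * condition)), data = d))
  p_aov <- c(fit[["Error: subject_id:time"]][[1]]["time", "Pr(>F)"],
             fit[["Error: subject_id:condition"]][[1]]["condition", "Pr(>F)"],
             fit[["Error: subject_id:time:condition"]][[1]]["time:condition", "Pr(>F)"])
  expect_equal(a$effects$p, unname(p_aov), tolerance = 1e-10)
})

test_that("ANOVA degenerate and invariance behaviour", {
  Y <- matrix(150, 6, 4)
  expect_warning(a <- rm_anova_2x2(fixture_table(Y)), "zero error variance")
  expect_true(all(a$effects$SS == 0))
  expect_true(all(is.na(a$effects$F)))

  # additive subject offsets only: all effect SS exactly 0, p = 1
  set.seed(3)
  offs <- rnorm(8, 0, 30)
  Y2 <- matrix(100, 8, 4) + offs
  expect_warning(a2 <- rm_anova_2x2(fixture_table(Y2)), "zero error")
  expect_equal(a2$effects$SS, rep(0, 3), tolerance = 1e-18)

  # shift invariance and scale behaviour of F
  Y3 <- matrix(rnorm(10 * 4, 50, 8), 10, 4)
  a3 <- rm_anova_2x2(fixture_table(Y3))
  a3s <- rm_anova_2x2(fixture_table(Y3 + 1000))
  expect_equal(a3$effects$F, a3s$effects$F, tolerance = 1e-6)
  a3m <- rm_anova_2x2(fixture_table(Y3 * 4))
  expect_equal(a3m$effects$SS, a3$effects$SS * 16, tolerance = 1e-8)
  expect_equal(a3m$effects$F, a3$effects$F, tolerance = 1e-8)
})

test_that("Bonferroni post hoc flags the shifted cell and never lowers p", {
  Y <- matrix(100, 8, 4)
  ph_eq <- bonferroni_posthoc(fixture_table(Y))
  expect_true(all(ph_eq$p_adj == 1))

  set.seed(5)
  Y2 <- matrix(rnorm(12 * 4, 100, 2), 12, 4)
  Y2[, 2] <- Y2[, 2] + 20  # shift scTS-Post by 10 SD
  ph <- bonferroni_posthoc(fixture_table(Y2))
  sig <- ph$p_adj < 0.05
  expect_true(sig[ph$comparison == "scTS: Post - Pre"])
  expect_true(sig[ph$comparison == "Post: scTS - sham"])
  expect_false(any(sig[ph$comparison %in% c("sham: Post - Pre", "Pre: scTS - sham")]))
  expect_true(all(ph$p_adj >= ph$p))
})

test_that("delta% comparison: normality gate, dz arithmetic, ES bins", {
  expect_error(delta_pct_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), "degenerate")

  # hand-computed dz for (1,2,3,4) vs (0,0,0,0): wait for n >= 5
  x <- c(1, 2, 3, 4, 6); y <- rep(0, 5)
  d <- x - y
  r <- delta_pct_test(x, y)
  expect_equal(r$es, mean(d) / sd(d), tolerance = 1e-12)
  # the documented 4-pair arithmetic, checked directly on the formula
  d4 <- c(1, 2, 3, 4)
  expect_equal(mean(d4) / sd(d4), 1.936492, tolerance = 1e-6)
  expect_equal(es_bin(1.94), "large")

  expect_equal(es_bin(0.19), "negligible")
  expect_equal(es_bin(0.20), "small")
  expect_equal(es_bin(0.49), "small")
  expect_equal(es_bin(0.50), "medium")
  expect_equal(es_bin(0.79), "medium")
  expect_equal(es_bin(0.80), "large")
  expect_equal(es_bin(-1.2), "large")

  # normal-looking differences -> paired t, matching base R
  set.seed(6)
  a <- rnorm(12, 5, 2); b <- rnorm(12, 3, 2)
  r2 <- delta_pct_test(a, b)
  expect_equal(r2$test_used, "paired_t")
  expect_equal(r2$p, t.test(a, b, paired = TRUE)$p.value)

  # strongly skewed differences -> Wilcoxon, matching base R exact p
  set.seed(9)
  d3 <- rexp(14)^3 + 0.01
  r3 <- delta_pct_test(d3, rep(0, 14))
  expect_equal(r3$test_used, "wilcoxon")
  expect_equal(r3$p, wilcox.test(d3, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("matched-pairs power: null case, a-priori design point, MC oracle", {
  expect_equal(matched_pairs_power(0, 12), 0.05, tolerance = 1e-12)
  expect_gt(matched_pairs_power(0.9, 12), 0.80)
  expect_equal(required_n(0.9, target_power = 0.80), 12)

  # doubling dz never increases the required n
  for (dz in c(0.3, 0.5, 0.9, 1.2)) {
    expect_lte(required_n(2 * dz), required_n(dz))
  }
  # scan oracle at dz = 2
  n_scan <- which(vapply(2:50, function(n) matched_pairs_power(2, n) >= 0.8,
                         logical(1)))[1] + 1L
  expect_equal(required_n(2, target_power = 0.8), n_scan)

  # Monte-Carlo power (scaled to 5000 reps here; 50000 in the acceptance suite)
  set.seed(12)
  nrep <- 5000
  D <- matrix(rnorm(12 * nrep, 0.9, 1), 12, nrep)
  tstat <- sqrt(12) * colMeans(D) / apply(D, 2, sd)
  mc <- mean(abs(tstat) > qt(0.975, 11))
  expect_equal(mc, matched_pairs_power(0.9, 12), tolerance = 0.02)
})

test_that("delta% rejection rate matches analytic power at the headline effect size", {
  # percent changes drawn at the study's structure: +4.7 vs -4.3, dz = 1.19
  set.seed(31)
  nrep <- 400
  rej <- vapply(seq_len(nrep), function(r) {
    tab <- synth_outcome_table("max_torque", n = 12)
    dp <- tab$delta_pct
    delta_pct_test(dp$delta_pct[dp$condition == "scTS"],
                   dp$delta_pct[dp$condition == "sham"])$p < 0.05
  }, logical(1))
  dz <- (4.7 - (-4.3)) / sqrt(2 * 5.35^2)
  expect_equal(dz, 1.19, tolerance = 0.01)
  expect_equal(mean(rej), matched_pairs_power(dz, 12), tolerance = 0.04)
})
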