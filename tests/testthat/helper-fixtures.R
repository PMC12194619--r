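# shared fixtures: built in code, deterministic under fixed seeds

fixture_profile <- function(seed = 7) sample_subject_profile("S01", seed = seed)

# a small complete 2x2 outcome table from explicit values
fixture_table <- function(Y, subjects = sprintf("S%02d", seq_len(nrow(Y)))) {
  rows <- rbind(
    data.frame(subject_id = subjects, condition = "scTS", time = "Pre", value = Y[, 1]),
    data.frame(subject_id = subjects, condition = "scTS", time = "Post", value = Y[, 2]),
    data.frame(subject_id = subjects, condition = "sham", time = "Pre", value = Y[, 3]),
    data.frame(subject_id = subjects, condition = "sham", time = "Post", value = Y[, 4])
  )
  outcome_table("x", rows)
}

# first-principles projection-matrix oracle for the 2x2 within-subject ANOVA:
# project the response onto each effect subspace and take squared norms
anova_projection_oracle <- function(Y) {
  n <- nrow(Y)
  y <- as.vector(Y)  # cell order: scTS.Pre, scTS.Post, sham.Pre, sham.Post
  subj <- factor(rep(seq_len(n), 4))
  time <- factor(rep(c("Pre", "Post", "Pre", "Post"), each = n))
  trt <- factor(rep(c("scTS", "scTS", "sham", "sham"), each = n))
  P <- function(X) X %*% solve(crossprod(X), t(X))
  ss <- function(M) drop(crossprod(M %*% y))
  one <- matrix(1, length(y), 1)
  Xs <- stats::model.matrix(~ subj)
  Xt <- stats::model.matrix(~ time)
  Xc <- stats::model.matrix(~ trt)
  Xtc <- stats::model.matrix(~ time * trt)
  Xst <- stats::model.matrix(~ subj * time)
  Xsc <- stats::model.matrix(~ subj * trt)
  P1 <- P(one)
  ss_subj <- ss(P(Xs) - P1)
  ss_time <- ss(P(Xt) - P1)
  ss_trt <- ss(P(Xc) - P1)
  ss_int <- ss(P(Xtc) - P(Xt) - P(Xc) + P1)
  ss_err_t <- ss(P(Xst) - P(Xs) - P(Xt) + P1)
  ss_err_c <- ss(P(Xsc) - P(Xs) - P(Xc) + P1)
  ss_tot <- ss(diag(length(y)) - P1)
  ss_err_i <- ss_tot - ss_subj - ss_time - ss_trt - ss_int - ss_err_t - ss_err_c
  dfe <- n - 1
  list(SS = c(Time = ss_time, Treatment = ss_trt, `Time:Treatment` = ss_int),
       SS_error = c(ss_err_t, ss_err_c, ss_err_i),
       F = c(ss_time / (ss_err_t / dfe), ss_trt / (ss_err_c / dfe),
             ss_int / (ss_err_i / dfe)),
       SS_total = ss_tot, SS_subject = ss_subj)
}

# brute-force sliding-window search oracles (naive loops, O(n * w))
brute_max_window <- function(x, rate, win_s) {
  wn <- floor(win_s * rate + 0.5)
  starts <- seq_len(length(x) - wn + 1L)
  means <- vapply(starts, function(i) mean(x[i:(i + wn - 1L)]), numeric(1))
  i <- which.max(means)
  list(value = means[i], start_s = (starts[i] - 1L) / rate)
}

brute_min_cv <- function(x, rate, win_s) {
  wn <- floor(win_s * rate + 0.5)
  starts <- seq_len(length(x) - wn + 1L)
  cvs <- vapply(starts, function(i) {
    w <- x[i:(i + wn - 1L)]
    stats::sd(w) / mean(w)
  }, numeric(1))
  i <- which.min(cvs)
  list(cv = cvs[i], start_s = (starts[i] - 1L) / rate)
}

# exactly band-limited noise via frequency-domain synthesis (flat spectrum)
flat_band_noise <- function(n, rate, lo, hi, seed = 1) {
  set.seed(seed)
  f <- (0:(n - 1)) * rate / n
  keep <- (f >= lo & f <= hi) | (f >= rate - hi & f <= rate - lo)
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}
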