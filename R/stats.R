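#' Outcome table for one variable
#'
#' Assembles the subject x condition (scTS/sham) x time (Pre/Post) values of
#' one outcome variable and computes the within-session percent change
#' `delta_pct = 100 * (Post - Pre) / Pre` per subject and condition. The
#' 2x2 cell set must be complete for every subject (the crossover design is
#' complete-case; missing cells are errors, not imputed).
#'
#' @param variable Name of the outcome variable.
#' @param rows Data frame with columns `subject_id`, `condition` (`"scTS"` /
#'   `"sham"`), `time` (`"Pre"` / `"Post"`), `value`.
#' @return An object of class `outcome_table`: the input rows plus a
#'   `delta_pct` data frame (subject_id, condition, delta_pct).
#' @export
outcome_table <- function(variable, rows) {
  need <- c("subject_id", "condition", "time", "value")
  if (!all(need %in% names(rows))) {
    stop(sprintf("rows must have columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  rows <- rows[, need]
  rows$subject_id <- as.character(rows$subject_id)
  subjects <- unique(rows$subject_id)
  cells <- expand.grid(subject_id = subjects, condition = c("scTS", "sham"),
                       time = c("Pre", "Post"), stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$condition, d$time)
  missing <- cells[!(key(cells) %in% key(rows)), , drop = FALSE]
  if (nrow(missing)) {
    stop(sprintf("incomplete cells for '%s': %s", variable,
                 paste(key(missing), collapse = "; ")), call. = FALSE)
  }
  dup <- duplicated(key(rows))
  if (any(dup)) {
    stop(sprintf("duplicated cell(s): %s", paste(unique(key(rows)[dup]), collapse = "; ")),
         call. = FALSE)
  }
  get_val <- function(s, cond, tm) {
    rows$value[rows$subject_id == s & rows$condition == cond & rows$time == tm]
  }
  dp <- expand.grid(subject_id = subjects, condition = c("scTS", "sham"),
                    stringsAsFactors = FALSE)
  dp$delta_pct <- mapply(function(s, cond) {
    pre <- get_val(s, cond, "Pre")
    post <- get_val(s, cond, "Post")
    if (pre == 0) stop(sprintf("Pre value is 0 for subject %s (%s); delta_pct undefined",
                               s, cond), call. = FALSE)
    100 * (post - pre) / pre
  }, dp$subject_id, dp$condition)
  structure(list(variable = variable, rows = rows, delta_pct = dp,
                 subjects = subjects),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("<outcome_table> %s: %d subjects x scTS/sham x Pre/Post\n",
              x$variable, length(x$subjects)))
  invisible(x)
}

#' Select the best attempt per design cell
#'
#' Applies the best-attempt rule to repeated attempts within each (subject,
#' condition, time) cell: lowest CV for steadiness, highest torque for MVC,
#' highest peak power for explosive extensions. Ties go to the earliest
#' attempt.
#'
#' @param attempts Data frame with columns `subject_id`, `condition`, `time`,
#'   `attempt` (ordering within the cell) and `value` (the selection metric).
#' @param task `"mvc"`, `"steadiness"` or `"explosive"`.
#' @param expect Optional data frame of cells (`subject_id`, `condition`,
#'   `time`) that must all be present; missing cells raise an error naming
#'   them.
#' @return One row per cell (the winning attempt), as a data frame.
#' @export
select_best_attempt <- function(attempts, task = c("mvc", "steadiness", "explosive"),
                                expect = NULL) {
  task <- match.arg(task)
  need <- c("subject_id", "condition", "time", "attempt", "value")
  if (!all(need %in% names(attempts))) {
    stop(sprintf("attempts must have columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(expect)) {
    key <- function(d) paste(d$subject_id, d$condition, d$time)
    missing <- expect[!(key(expect) %in% key(attempts)), , drop = FALSE]
    if (nrow(missing)) {
      stop(sprintf("no attempts for cell(s): %s", paste(key(missing), collapse = "; ")),
           call. = FALSE)
    }
  }
  better <- if (task == "steadiness") function(v) which.min(v) else function(v) which.max(v)
  grp <- interaction(attempts$subject_id, attempts$condition, attempts$time, drop = TRUE)
  picked <- unlist(lapply(split(seq_len(nrow(attempts)), grp), function(i) {
    i <- i[order(attempts$attempt[i])]  # earliest attempt wins ties
    i[better(attempts$value[i])]
  }), use.names = FALSE)
  out <- attempts[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way within-subject ANOVA for the 2x2 crossover
#'
#' Repeated-measures ANOVA with Time (Pre/Post) and Treatment (scTS/sham) as
#' within-subject factors, computed from the classical sum-of-squares
#' decomposition: each effect is tested against its own effect-by-subject
#' error stratum with F(1, n-1). With two-level factors sphericity holds by
#' construction.
#'
#' @param table An [outcome_table()].
#' @return An object of class `anova_result`: `effects` (data frame with SS,
#'   df, F, p per effect), `strata` (subject and error-stratum SS/df),
#'   `n_subjects`, and `degenerate` (`TRUE` when an error stratum has zero
#'   variance, in which case the affected F/p are `NA`).
#' @export
rm_anova_2x2 <- function(table) {
  stopifnot(inherits(table, "outcome_table"))
  Y <- outcome_matrix(table)     # n x 4: (Pre,scTS) (Post,scTS) (Pre,sham) (Post,sham)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_time <- c(Pre = mean(Y[, c(1, 3)]), Post = mean(Y[, c(2, 4)]))
  m_trt <- c(scTS = mean(Y[, c(1, 2)]), sham = mean(Y[, c(3, 4)]))
  m_cell <- colMeans(Y)

  ss_total <- sum((Y - grand)^2)
  ss_subj <- 4 * sum((m_subj - grand)^2)
  ss_time <- 2 * n * sum((m_time - grand)^2)
  ss_trt <- 2 * n * sum((m_trt - grand)^2)
  cell_time <- c("Pre", "Post", "Pre", "Post")
  cell_trt <- c("scTS", "scTS", "sham", "sham")
  ss_int <- n * sum((m_cell - m_time[cell_time] - m_trt[cell_trt] + grand)^2)
  # subject-level means within each factor level
  ms_time <- cbind(rowMeans(Y[, c(1, 3)]), rowMeans(Y[, c(2, 4)]))
  ms_trt <- cbind(rowMeans(Y[, c(1, 2)]), rowMeans(Y[, c(3, 4)]))
  ss_err_time <- 2 * sum((ms_time - m_subj - rep(m_time, each = n) + grand)^2)
  ss_err_trt <- 2 * sum((ms_trt - m_subj - rep(m_trt, each = n) + grand)^2)
  ss_err_int <- ss_total - ss_subj - ss_time - ss_trt - ss_int -
    ss_err_time - ss_err_trt
  ss_err_int <- max(0, ss_err_int)

  dfe <- n - 1L
  eff <- data.frame(
    effect = c("Time", "Treatment", "Time:Treatment"),
    SS = c(ss_time, ss_trt, ss_int),
    df = 1L,
    SS_error = c(ss_err_time, ss_err_trt, ss_err_int),
    df_error = dfe
  )
  degenerate <- any(eff$SS_error <= .Machine$double.eps * max(1, ss_total))
  eff$F <- ifelse(eff$SS_error > .Machine$double.eps * max(1, ss_total),
                  eff$SS / (eff$SS_error / dfe), NA_real_)
  eff$p <- ifelse(is.na(eff$F), NA_real_, stats::pf(eff$F, 1, dfe, lower.tail = FALSE))
  if (degenerate) warning("zero error variance in at least one stratum; F flagged as NA")
  structure(
    list(effects = eff,
         strata = data.frame(
           stratum = c("Subject", "Time x Subject", "Treatment x Subject",
                       "Time x Treatment x Subject"),
           SS = c(ss_subj, ss_err_time, ss_err_trt, ss_err_int),
           df = c(dfe, dfe, dfe, dfe)),
         SS_total = ss_total, n_subjects = n, degenerate = degenerate),
    class = "anova_result"
  )
}

# subjects x 4 matrix in fixed cell order (scTS.Pre, scTS.Post, sham.Pre, sham.Post)
outcome_matrix <- function(table) {
  r <- table$rows
  subjects <- table$subjects
  cell <- function(cond, tm) {
    v <- r$value[r$condition == cond & r$time == tm]
    names(v) <- r$subject_id[r$condition == cond & r$time == tm]
    v[subjects]
  }
  cbind(cell("scTS", "Pre"), cell("scTS", "Post"),
        cell("sham", "Pre"), cell("sham", "Post"))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> two-way within-subject ANOVA, n = %d\n", x$n_subjects))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni post hoc tests for the 2x2 crossover
#'
#' Paired t-tests on the four simple effects (Pre vs Post within each
#' condition, scTS vs sham within each time point), with p values multiplied
#' by the family size (default 4) and capped at 1. Meant to be run when the
#' interaction is significant.
#'
#' @param table An [outcome_table()].
#' @param family Number of comparisons used for the correction (default 4).
#' @return Data frame with one row per comparison: mean difference, t, df,
#'   raw and adjusted p.
#' @export
bonferroni_posthoc <- function(table, family = 4L) {
  stopifnot(inherits(table, "outcome_table"))
  Y <- outcome_matrix(table)
  comp <- list(
    "scTS: Post - Pre" = Y[, 2] - Y[, 1],
    "sham: Post - Pre" = Y[, 4] - Y[, 3],
    "Pre: scTS - sham" = Y[, 1] - Y[, 3],
    "Post: scTS - sham" = Y[, 2] - Y[, 4]
  )
  n <- nrow(Y)
  out <- do.call(rbind, lapply(names(comp), function(nm) {
    d <- comp[[nm]]
    se <- stats::sd(d) / sqrt(n)
    if (se > 0) {
      tval <- mean(d) / se
      p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
    } else {
      # zero-variance contrast: no difference at all -> p = 1; a constant
      # nonzero shift is detected with certainty
      tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    }
    data.frame(comparison = nm, mean_diff = mean(d), t = tval, df = n - 1L,
               p = p, p_adj = pmin(1, p * family))
  }))
  rownames(out) <- NULL
  out
}

#' Compare Post-Pre percent changes between conditions
#'
#' Tests whether the within-session percent change differs between the scTS
#' and sham priming sessions. The paired differences are checked for
#' normality (Shapiro-Wilk); if normality is not rejected a paired t-test is
#' used, otherwise a Wilcoxon signed-rank test (Pratt handling of zero
#' differences; exact p for n <= 25 when there are no ties or zeros). The
#' effect size is Cohen's dz (mean of differences / SD of differences) by
#' default, binned as negligible (< 0.20), small (0.20-0.49), medium
#' (0.50-0.79) or large (>= 0.80).
#'
#' @param deltas_scts,deltas_sham Paired per-subject percent changes.
#' @param normality_alpha Shapiro-Wilk gate (default 0.05).
#' @param es_formula `"dz"` (default) or `"dav"` (mean difference over the
#'   average of the two SDs).
#' @return An object of class `delta_test_result`.
#' @export
delta_pct_test <- function(deltas_scts, deltas_sham, normality_alpha = 0.05,
                           es_formula = c("dz", "dav")) {
  es_formula <- match.arg(es_formula)
  if (length(deltas_scts) != length(deltas_sham)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(deltas_scts)
  if (n < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- deltas_scts - deltas_sham
  if (stats::sd(d) == 0) {
    stop("degenerate: all paired differences identical", call. = FALSE)
  }
  normality_p <- stats::shapiro.test(d)$p.value
  if (normality_p >= normality_alpha) {
    tt <- stats::t.test(deltas_scts, deltas_sham, paired = TRUE)
    test_used <- "paired_t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    w <- wilcoxon_signed_rank(d)
    test_used <- "wilcoxon"
    statistic <- w$statistic
    p <- w$p
  }
  es <- if (es_formula == "dz") {
    mean(d) / stats::sd(d)
  } else {
    mean(d) / mean(c(stats::sd(deltas_scts), stats::sd(deltas_sham)))
  }
  structure(
    list(normality_p = normality_p, test_used = test_used,
         statistic = statistic, p = p, es = es, es_bin = es_bin(es), n = n),
    class = "delta_test_result"
  )
}

#' Effect size magnitude bin
#'
#' Bins an effect size by absolute magnitude: negligible below 0.20, small
#' from 0.20, medium from 0.50, large from 0.80.
#'
#' @param es Effect size (sign is ignored).
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
es_bin <- function(es) {
  a <- abs(es)
  if (a < 0.20) "negligible" else if (a < 0.50) "small" else if (a < 0.80) "medium" else "large"
}

# Wilcoxon signed-rank with Pratt handling of zero differences: zeros are
# ranked with the rest, then dropped from the statistic. Exact p (psignrank)
# when there are no zeros and no ties and n <= 25, otherwise a normal
# approximation with zero/tie-corrected moments and continuity correction.
wilcoxon_signed_rank <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  zeros <- d == 0
  n0 <- sum(zeros)
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d[!zeros])))
  if (n0 == 0L && !ties && n <= 25L) {
    Wm <- n * (n + 1) / 4
    p <- if (W > Wm) {
      2 * (1 - stats::psignrank(W - 1, n))
    } else {
      2 * stats::psignrank(W, n)
    }
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - n0 * (n0 + 1) * (2 * n0 + 1) / 24
    tt <- table(abs(d[!zeros]))
    sig2 <- sig2 - sum(tt^3 - tt) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, p = p)
}

#' Power of a two-sided matched-pairs t-test
#'
#' Exact noncentral-t power for a paired t-test with effect size dz
#' (mean/SD of the paired differences), `n` pairs and significance level
#' `alpha`.
#'
#' @param dz Effect size (Cohen's dz).
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param sides 1 or 2 (default 2).
#' @return Power in `[0, 1]`.
#' @export
matched_pairs_power <- function(dz, n, alpha = 0.05, sides = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!sides %in% c(1, 2)) stop("sides must be 1 or 2", call. = FALSE)
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching a target power
#'
#' Scans `n` upward until [matched_pairs_power()] reaches `target_power`.
#'
#' @inheritParams matched_pairs_power
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param n_max Search cap (default 10000).
#' @return The smallest integer `n` with power >= `target_power`.
#' @export
required_n <- function(dz, alpha = 0.05, sides = 2, target_power = 0.80,
                       n_max = 10000L) {
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must be in (alpha, 1)", call. = FALSE)
  }
  if (dz == 0) stop("power unreachable with dz = 0", call. = FALSE)
  for (n in 2:n_max) {
    if (matched_pairs_power(dz, n, alpha, sides) >= target_power) return(n)
  }
  stop(sprintf("target power not reached by n = %d", n_max), call. = FALSE)
}
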