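# The statistical battery used on the per-player indicator tables:
# Welch and paired t-tests with 95% CIs, step-down Holm adjustment,
# Hedges' g (pooled for between-subject contrasts, "average g" for
# within-subject ones), JZS Bayes factors with a Cauchy(0, 0.707) prior
# on the standardized effect, a 2x2 mixed ANOVA with Type-III sums of
# squares and generalized eta squared, and Morey-corrected within-subject
# confidence intervals.

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' two-sided p, and a CI for the mean difference `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples, each of length >= 2 with positive variance.
#' @param conf confidence level (default 0.95).
#' @return list with `mean_x`, `mean_y`, `sd_x`, `sd_y`, `diff`,
#'   `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @export
welch_t <- function(x, y, conf = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("welch_t() needs at least 2 observations per sample")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx <= 0 && vy <= 0) stop("welch_t() needs positive variance")
  sex2 <- vx / nx; sey2 <- vy / ny
  se <- sqrt(sex2 + sey2)
  df <- (sex2 + sey2)^2 / (sex2^2 / (nx - 1) + sey2^2 / (ny - 1))
  d <- mean(x) - mean(y)
  tt <- d / se
  q <- stats::qt(1 - (1 - conf) / 2, df)
  list(mean_x = mean(x), mean_y = mean(y), sd_x = sqrt(vx), sd_y = sqrt(vy),
       n_x = nx, n_y = ny, diff = d, ci_low = d - q * se, ci_high = d + q * se,
       t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Paired-samples t-test on difference scores
#'
#' @param diffs numeric vector of within-subject differences, length >= 2
#'   with positive variance.
#' @param conf confidence level (default 0.95).
#' @return list with `mean_diff`, `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @export
paired_t <- function(diffs, conf = 0.95) {
  d <- diffs[!is.na(diffs)]
  n <- length(d)
  if (n < 2L) stop("paired_t() needs at least 2 pairs")
  v <- stats::var(d)
  if (v <= 0) stop("paired_t() needs positive variance of the differences")
  se <- sqrt(v / n)
  tt <- mean(d) / se
  q <- stats::qt(1 - (1 - conf) / 2, n - 1)
  list(mean_diff = mean(d), sd_diff = sqrt(v), n = n,
       ci_low = mean(d) - q * se, ci_high = mean(d) + q * se,
       t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1))
}

#' JZS Bayes factor for a t-statistic (natural log)
#'
#' The default Bayes-factor t-test: under H1 the standardized effect
#' follows a Cauchy prior with scale `r`; BF10 is the ratio of the
#' marginal likelihood of the observed t under H1 (a non-central t
#' density averaged over the prior) to its density under H0. Evaluated by
#' adaptive quadrature on the log scale, split at the peak, so extreme t
#' values do not underflow. For a paired/one-sample design
#' `n_eff = n`, `df = n - 1`; for two samples
#' `n_eff = n1 * n2 / (n1 + n2)`, `df = n1 + n2 - 2`.
#'
#' @param t observed t statistic.
#' @param n_eff effective sample size.
#' @param df degrees of freedom (>= 1).
#' @param r Cauchy prior scale (default `sqrt(2) / 2`).
#' @return `ln(BF10)`; positive favors the alternative.
#' @export
jzs_ln_bf <- function(t, n_eff, df, r = sqrt(2) / 2) {
  stopifnot(is.finite(t), n_eff > 0, df >= 1, r > 0)
  sn <- sqrt(n_eff)
  ln_h0 <- stats::dt(t, df, log = TRUE)
  delta_hat <- t / sn
  peak <- suppressWarnings(stats::dt(t, df, ncp = delta_hat * sn, log = TRUE))
  # dt(ncp) warns about pnt precision in far tails; harmless at the
  # quadrature tolerance used here
  f <- function(delta)
    suppressWarnings(exp(stats::dt(t, df, ncp = delta * sn, log = TRUE) - peak)) *
      stats::dcauchy(delta, 0, r)
  lower <- tryCatch(stats::integrate(f, -Inf, delta_hat,
                                     rel.tol = 1e-10, abs.tol = 0),
                    error = function(e) e)
  upper <- tryCatch(stats::integrate(f, delta_hat, Inf,
                                     rel.tol = 1e-10, abs.tol = 0),
                    error = function(e) e)
  if (inherits(lower, "error") || inherits(upper, "error"))
    stop("JZS quadrature failed (t = ", t, ", n_eff = ", n_eff, ", df = ", df,
         "): ", conditionMessage(if (inherits(lower, "error")) lower else upper))
  total <- lower$value + upper$value
  if (!is.finite(total) || total <= 0)
    stop("JZS quadrature degenerate (t = ", t, ", n_eff = ", n_eff,
         ", df = ", df, "): integral = ", total)
  (peak + log(total)) - ln_h0
}

# exact small-sample bias correction for standardized mean differences
.hedges_correction <- function(df) {
  if (df <= 1) stop("Hedges correction needs df > 1")
  exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
}

#' Hedges' g effect size
#'
#' Between-subjects: the pooled-sd standardized mean difference with the
#' exact small-sample correction on `n1 + n2 - 2` df. Within-subjects
#' ("average g"): the mean difference divided by the average of the two
#' condition standard deviations, corrected on `n - 1` df.
#'
#' @param a,b numeric samples; paired (same length, same subjects) for
#'   `design = "within"`.
#' @param design `"between"` or `"within"`.
#' @return Hedges' g (signed, `a` minus `b`).
#' @export
hedges_g <- function(a, b, design = c("between", "within")) {
  design <- match.arg(design)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (design == "between") {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("hedges_g() needs positive pooled variance")
    (mean(a) - mean(b)) / sqrt(sp2) * .hedges_correction(n1 + n2 - 2)
  } else {
    if (length(a) != length(b)) stop("within design needs paired samples")
    n <- length(a)
    s_av <- (stats::sd(a) + stats::sd(b)) / 2
    if (!is.finite(s_av) || s_av <= 0) stop("hedges_g() needs positive variance")
    (mean(a) - mean(b)) / s_av * .hedges_correction(n - 1)
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted ascending, the i-th smallest p is multiplied by (m - i + 1);
#' running maxima enforce monotonicity and results are capped at 1. Ties
#' keep their original relative order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)  # stable: ties keep original index order
  stepped <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))
  out <- numeric(m)
  out[o] <- stepped
  out
}

#' 2x2 mixed ANOVA (one between-, one within-subject factor)
#'
#' Each subject contributes a value in two within-subject conditions
#' (here: after a loss and after a win) and belongs to one of two groups.
#' Sums of squares are Type III (sum-to-zero coding; the groups are
#' allowed to be unbalanced), errors are split into the between-subjects
#' stratum (subjects within groups) and the within-subjects residual, and
#' generalized eta squared uses both error strata in its denominator.
#'
#' @param tbl data with columns `group` (two levels), `value_loss`,
#'   `value_win` (one row per subject).
#' @param group_levels order of the two group levels (default
#'   `c("high", "low")` if present).
#' @return `data.table` with one row per effect (`group`, `outcome`,
#'   `interaction`): `df_num`, `df_den`, `MSE`, `F`, `ges`, `p`.
#' @export
mixed_anova_2x2 <- function(tbl, group_levels = NULL) {
  dt <- data.table::as.data.table(tbl)
  stopifnot(all(c("group", "value_loss", "value_win") %in% names(dt)))
  dt <- dt[stats::complete.cases(dt[, .(group, value_loss, value_win)])]
  if (is.null(group_levels))
    group_levels <- if (all(c("high", "low") %in% dt$group)) c("high", "low")
                    else sort(unique(dt$group))
  if (length(unique(dt$group)) != 2L)
    stop("mixed_anova_2x2() needs exactly two groups")
  g <- factor(dt$group, levels = group_levels)
  n <- tabulate(g, 2L)
  if (any(n < 2L)) stop("each group needs at least 2 subjects")
  N <- sum(n)
  s <- (dt$value_loss + dt$value_win) / 2   # subject means
  d <- dt$value_loss - dt$value_win         # within-subject differences
  sbar <- tapply(s, g, mean)
  dbar <- tapply(d, g, mean)
  # between stratum (2 observations per subject)
  ss_group <- 2 * sum(n * (sbar - stats::weighted.mean(sbar, n))^2)
  ss_subj <- 2 * sum((s - sbar[g])^2)
  # within stratum, Type III via model comparisons on d with sum coding
  x <- ifelse(g == group_levels[1L], 1, -1)
  sse_full <- sum((d - dbar[g])^2)
  beta_nox <- sum(x * d) / sum(x^2)                  # model without intercept
  ss_outcome <- (sum((d - beta_nox * x)^2) - sse_full) / 2
  ss_inter <- (sum((d - mean(d))^2) - sse_full) / 2
  ss_resid <- sse_full / 2
  df_den <- N - 2L
  ms_subj <- ss_subj / df_den
  ms_resid <- ss_resid / df_den
  eff <- data.table::data.table(
    effect = c("group", "outcome", "interaction"),
    df_num = 1L, df_den = df_den,
    MSE = c(ms_subj, ms_resid, ms_resid),
    ss = c(ss_group, ss_outcome, ss_inter))
  eff[, F := ss / MSE]
  eff[, ges := ss / (ss + ss_subj + ss_resid)]
  eff[, p := stats::pf(F, df_num, df_den, lower.tail = FALSE)]
  eff[, ss := NULL]
  eff[]
}

#' Within-subject confidence intervals for a paired design
#'
#' Cousineau subject-centering (each subject's values recentred at the
#' grand mean) with the Morey J/(J-1) variance inflation, J = 2
#' conditions, and t-based per-condition intervals. For J = 2 the
#' half-width equals `qt(0.975, n-1) * sd(d) / sqrt(2n)` where `d` is the
#' difference score.
#'
#' @param value_loss,value_win paired per-subject values.
#' @param level confidence level (default 0.95).
#' @return `data.table` with one row per condition: `mean`, `ci_low`,
#'   `ci_high`.
#' @export
within_subject_ci <- function(value_loss, value_win, level = 0.95) {
  keep <- !is.na(value_loss) & !is.na(value_win)
  l <- value_loss[keep]; w <- value_win[keep]
  n <- length(l)
  if (n < 2L) stop("within_subject_ci() needs at least 2 subjects")
  subj <- (l + w) / 2
  grand <- mean(subj)
  cl <- l - subj + grand
  cw <- w - subj + grand
  infl <- 2  # J / (J - 1) with J = 2
  q <- stats::qt(1 - (1 - level) / 2, n - 1)
  half <- q * sqrt(infl * c(stats::var(cl), stats::var(cw)) / n)
  data.table::data.table(condition = c("loss", "win"),
                         mean = c(mean(l), mean(w)),
                         ci_low = c(mean(l), mean(w)) - half,
                         ci_high = c(mean(l), mean(w)) + half)
}
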