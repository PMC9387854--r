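# Independent oracles, written against the game rules / definitions
# directly and kept free of the package's own scoring and quadrature code
# paths.

# Brute-force round scorer: enumerate the 5 lines of each slot explicitly.
oracle_score_round <- function(slots, values = c(5, 10, 15, 20, 25, 30, 40, 50, 100),
                               bonus_face = 10, threshold_bonus = 200,
                               m3 = 1.5, m4 = 2) {
  line_idx <- list(
    rbind(c(1, 1), c(1, 2), c(1, 3)),
    rbind(c(2, 1), c(2, 2), c(2, 3)),
    rbind(c(3, 1), c(3, 2), c(3, 3)),
    rbind(c(1, 1), c(2, 2), c(3, 3)),
    rbind(c(3, 1), c(2, 2), c(1, 3)))
  slot_pts <- numeric(4)
  n_bonus_lines <- 0
  any_nine <- FALSE
  for (s in 1:4) {
    g <- slots[[s]]
    for (li in line_idx) {
      f <- c(g[li[1, 1], li[1, 2]], g[li[2, 1], li[2, 2]], g[li[3, 1], li[3, 2]])
      if (f[1] == f[2] && f[1] == f[3]) {
        if (f[1] == bonus_face) n_bonus_lines <- n_bonus_lines + 1
        else slot_pts[s] <- slot_pts[s] + values[f[1]]
      }
    }
    if (all(g == g[1, 1])) any_nine <- TRUE
  }
  nw <- sum(slot_pts > 0)
  mult <- 1
  if (nw == 3) mult <- m3
  if (nw == 4) mult <- m4
  total <- sum(slot_pts) * mult
  if (any_nine) total <- total + threshold_bonus
  list(slot_points = slot_pts, total_points = total,
       bonus_triggered = n_bonus_lines > 0)
}

# Fixed-grid Simpson quadrature for the JZS Bayes factor, on the log scale.
oracle_jzs_lnbf <- function(t, n, df, r = sqrt(2) / 2, lim = 20, np = 40001) {
  x <- seq(-lim, lim, length.out = np)
  h <- x[2] - x[1]
  lg <- suppressWarnings(stats::dt(t, df, ncp = x * sqrt(n), log = TRUE)) +
    stats::dcauchy(x, 0, r, log = TRUE)
  m <- max(lg)
  w <- c(1, rep(c(4, 2), (np - 3) / 2), 4, 1)
  log(sum(w * exp(lg - m)) * h / 3) + m - stats::dt(t, df, log = TRUE)
}

# Reference 2x2 mixed ANOVA via base aov() error strata (valid for
# balanced groups, where all SS types coincide), with generalized eta
# squared assembled from the stratum sums of squares.
oracle_mixed_anova <- function(tbl) {
  long <- rbind(
    data.frame(player = tbl$player_id, group = tbl$group, outcome = "loss",
               y = tbl$value_loss),
    data.frame(player = tbl$player_id, group = tbl$group, outcome = "win",
               y = tbl$value_win))
  fit <- stats::aov(y ~ group * outcome + Error(player / outcome), data = long)
  s <- summary(fit)
  b <- s[[1]][[1]]; w <- s[[2]][[1]]
  ss_g <- b["group", "Sum Sq"]; ss_s <- b["Residuals", "Sum Sq"]
  ss_o <- w["outcome", "Sum Sq"]; ss_i <- w["group:outcome", "Sum Sq"]
  ss_r <- w["Residuals", "Sum Sq"]
  df_den <- b["Residuals", "Df"]
  eff_ss <- c(group = ss_g, outcome = ss_o, interaction = ss_i)
  data.frame(
    effect = names(eff_ss),
    F = c(ss_g / (ss_s / df_den), ss_o / (ss_r / df_den), ss_i / (ss_r / df_den)),
    MSE = c(ss_s / df_den, ss_r / df_den, ss_r / df_den),
    ges = eff_ss / (eff_ss + ss_s + ss_r),
    df_den = df_den,
    p = c(stats::pf(ss_g / (ss_s / df_den), 1, df_den, lower.tail = FALSE),
          stats::pf(ss_o / (ss_r / df_den), 1, df_den, lower.tail = FALSE),
          stats::pf(ss_i / (ss_r / df_den), 1, df_den, lower.tail = FALSE)),
    row.names = NULL)
}

random_grid <- function() matrix(sample.int(10L, 9L, replace = TRUE), nrow = 3)
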