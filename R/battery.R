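# Assembles, for one facet's per-player table, the comparison battery
# reported for operator cohorts: the 2x2 mixed ANOVA plus five pairwise
# comparisons (within each group: after-loss vs after-win, paired; between
# groups: after-loss, after-win, and the loss-minus-win difference scores,
# Welch), with Holm adjustment over the 5-comparison family, JZS log
# Bayes factors and Hedges' g per row.

.battery_comparisons <- c("high_loss_vs_high_win", "low_loss_vs_low_win",
                          "high_loss_vs_low_loss", "high_win_vs_low_win",
                          "diff_high_vs_diff_low")

.empty_comparisons <- function() {
  data.table::data.table(comparison = .battery_comparisons,
                         mean_a = NA_real_, sd_a = NA_real_,
                         mean_b = NA_real_, sd_b = NA_real_,
                         diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                         df = NA_real_, t = NA_real_, p_raw = NA_real_,
                         p_holm = NA_real_, ln_bf = NA_real_, g = NA_real_)
}

#' Comparison battery for one facet
#'
#' @param tbl per-player facet table with columns `player_id`, `group`
#'   (`"high"`/`"low"`), `value_loss`, `value_win`; rows failing the
#'   facet's inclusion filter must already be removed.
#' @param conf confidence level for CIs (default 0.95).
#' @param bf_r Cauchy prior scale for the Bayes factors (default
#'   `sqrt(2) / 2`).
#' @return object of class `facet_battery`: list with `n` (players per
#'   group), `anova`, `comparisons`, `ws_ci` (within-subject CIs per
#'   group) and `note` (non-`NULL` when the analysis set was too small
#'   and a structured empty result is returned).
#' @export
comparison_battery <- function(tbl, conf = 0.95, bf_r = sqrt(2) / 2) {
  dt <- data.table::as.data.table(tbl)
  stopifnot(all(c("group", "value_loss", "value_win") %in% names(dt)))
  dt <- dt[stats::complete.cases(dt[, .(group, value_loss, value_win)])]
  hi <- dt[group == "high"]; lo <- dt[group == "low"]
  n <- data.table::data.table(group = c("high", "low"),
                              n_players = c(nrow(hi), nrow(lo)))
  # paired rows need n >= 3 (the Hedges correction requires df > 1)
  if (nrow(hi) < 3L || nrow(lo) < 3L) {
    return(structure(list(n = n, anova = NULL,
                          comparisons = .empty_comparisons(), ws_ci = NULL,
                          note = "analysis set too small; no result"),
                     class = "facet_battery"))
  }
  d_hi <- hi$value_loss - hi$value_win
  d_lo <- lo$value_loss - lo$value_win

  paired_row <- function(a, b) {
    pt <- paired_t(a - b, conf)
    list(mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b),
         diff = pt$mean_diff, ci_low = pt$ci_low, ci_high = pt$ci_high,
         df = pt$df, t = pt$t, p_raw = pt$p,
         ln_bf = jzs_ln_bf(pt$t, n_eff = pt$n, df = pt$df, r = bf_r),
         g = hedges_g(a, b, "within"))
  }
  welch_row <- function(a, b) {
    wt <- welch_t(a, b, conf)
    n1 <- wt$n_x; n2 <- wt$n_y
    # the Bayes factor uses the classical pooled-variance t on n1+n2-2 df
    sp2 <- ((n1 - 1) * wt$sd_x^2 + (n2 - 1) * wt$sd_y^2) / (n1 + n2 - 2)
    t_pooled <- wt$diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(mean_a = wt$mean_x, sd_a = wt$sd_x, mean_b = wt$mean_y, sd_b = wt$sd_y,
         diff = wt$diff, ci_low = wt$ci_low, ci_high = wt$ci_high,
         df = wt$df, t = wt$t, p_raw = wt$p,
         ln_bf = jzs_ln_bf(t_pooled, n_eff = n1 * n2 / (n1 + n2),
                           df = n1 + n2 - 2, r = bf_r),
         g = hedges_g(a, b, "between"))
  }
  rows <- list(
    paired_row(hi$value_loss, hi$value_win),
    paired_row(lo$value_loss, lo$value_win),
    welch_row(hi$value_loss, lo$value_loss),
    welch_row(hi$value_win, lo$value_win),
    welch_row(d_hi, d_lo))
  cmp <- data.table::rbindlist(lapply(rows, data.table::as.data.table))
  cmp[, comparison := .battery_comparisons]
  cmp[, p_holm := holm_adjust(p_raw)]
  data.table::setcolorder(cmp, c("comparison", "mean_a", "sd_a", "mean_b",
                                 "sd_b", "diff", "ci_low", "ci_high", "df",
                                 "t", "p_raw", "p_holm", "ln_bf", "g"))
  ws <- data.table::rbindlist(list(
    cbind(group = "high", within_subject_ci(hi$value_loss, hi$value_win, conf)),
    cbind(group = "low", within_subject_ci(lo$value_loss, lo$value_win, conf))))
  structure(list(n = n,
                 anova = mixed_anova_2x2(dt[, .(group, value_loss, value_win)]),
                 comparisons = cmp, ws_ci = ws, note = NULL),
            class = "facet_battery")
}

# per-facet analysis tables (inclusion filters applied) from cohort metrics
.facet_tables <- function(metrics) {
  stopifnot(inherits(metrics, "cohort_metrics"))
  list(
    stop = metrics$stop[included == TRUE,
                        .(player_id, group, value_loss = rl_loss,
                          value_win = rl_win)],
    stake_prob = metrics$stake[included == TRUE,
                               .(player_id, group,
                                 value_loss = 100 * p_change_loss,
                                 value_win = 100 * p_change_win)],
    stake_amount = metrics$stake[included == TRUE,
                                 .(player_id, group,
                                   value_loss = mean_delta_loss,
                                   value_win = mean_delta_win)],
    speed = metrics$speed[included == TRUE,
                          .(player_id, group, value_loss = mean_z_loss,
                            value_win = mean_z_win)])
}

#' Run the comparison battery on every facet
#'
#' Four analyses: relative likelihood of stopping, probability of
#' changing stake (percent), mean stake change (euro cents) and mean RT z
#' score, each analyzed by prior outcome and involvement group.
#'
#' @param metrics a [cohort_metrics()] object.
#' @inheritParams comparison_battery
#' @return named list of [comparison_battery()] results, class
#'   `chasing_batteries`.
#' @export
chasing_batteries <- function(metrics, conf = 0.95, bf_r = sqrt(2) / 2) {
  tabs <- .facet_tables(metrics)
  structure(lapply(tabs, comparison_battery, conf = conf, bf_r = bf_r),
            class = "chasing_batteries")
}

#' @export
print.facet_battery <- function(x, ...) {
  cat("Facet battery:", x$n$n_players[1], "high /", x$n$n_players[2],
      "low players\n")
  if (!is.null(x$note)) { cat(" ", x$note, "\n"); return(invisible(x)) }
  cat("\nMixed ANOVA (Type III, ges with both error strata):\n")
  print(x$anova, digits = 4)
  cat("\nPairwise comparisons (p_holm over the 5-comparison family):\n")
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Markdown rendering of a battery
#'
#' @param batteries a `chasing_batteries` object.
#' @param labels optional named facet titles.
#' @return character vector of markdown lines.
#' @export
format_batteries_md <- function(batteries,
                                labels = c(stop = "When to stop (relative likelihood of stopping)",
                                           stake_prob = "Probability of changing stake (%)",
                                           stake_amount = "Change in stake amount (euro cents)",
                                           speed = "Speed of play (RT z scores)")) {
  out <- character(0)
  num <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 4, format = "fg"))
  for (nm in names(batteries)) {
    b <- batteries[[nm]]
    out <- c(out, paste0("## ", if (nm %in% names(labels)) labels[[nm]] else nm), "")
    out <- c(out, paste0("Players included: high = ", b$n$n_players[1],
                         ", low = ", b$n$n_players[2]), "")
    if (!is.null(b$note)) { out <- c(out, b$note, ""); next }
    out <- c(out, "| Effect | df | MSE | F | ges | p |",
             "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(b$anova))) {
      a <- b$anova[i]
      out <- c(out, paste0("| ", a$effect, " | ", a$df_num, ", ", a$df_den,
                           " | ", num(a$MSE), " | ", num(a$F), " | ",
                           num(a$ges), " | ", num(a$p), " |"))
    }
    out <- c(out, "",
             "| Comparison (A vs. B) | A-mean (SD) | B-mean (SD) | diff | lowerCI | upperCI | df | t | p | lnBF | g |",
             "|---|---|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(b$comparisons))) {
      cm <- b$comparisons[i]
      out <- c(out, paste0("| ", cm$comparison, " | ", num(cm$mean_a), " (",
                           num(cm$sd_a), ") | ", num(cm$mean_b), " (",
                           num(cm$sd_b), ") | ", num(cm$diff), " | ",
                           num(cm$ci_low), " | ", num(cm$ci_high), " | ",
                           num(cm$df), " | ", num(cm$t), " | ", num(cm$p_holm),
                           " | ", num(cm$ln_bf), " | ", num(cm$g), " |"))
    }
    out <- c(out, "")
  }
  out
}

#' Plot within-subject condition means of a facet battery
#'
#' A minimal base-graphics rendition of the condition means (after loss /
#' after win) per group with 95% within-subject error bars.
#'
#' @param x a `facet_battery`.
#' @param main plot title.
#' @param ... unused.
#' @export
plot.facet_battery <- function(x, main = "facet battery", ...) {
  if (is.null(x$ws_ci)) stop("no plottable result")
  ci <- x$ws_ci
  xs <- c(1, 2, 1.1, 2.1)
  ord <- ci[order(group, condition)]
  # order: high-loss, high-win, low-loss, low-win
  graphics::plot(xs, ord$mean, xlim = c(0.5, 2.6),
                 ylim = range(c(ci$ci_low, ci$ci_high)),
                 pch = c(19, 19, 1, 1), xaxt = "n",
                 xlab = "prior outcome", ylab = "mean", main = main)
  graphics::axis(1, at = c(1.05, 2.05), labels = c("loss", "win"))
  graphics::arrows(xs, ord$ci_low, xs, ord$ci_high,
                   angle = 90, code = 3, length = 0.04)
  graphics::legend("topleft", pch = c(19, 1), bty = "n",
                   legend = c("high involvement", "low involvement"))
  invisible(x)
}
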