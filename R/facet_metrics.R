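# The three per-player chasing indicators. A round is a win iff its
# recorded win amount is positive (a round below the point threshold pays
# 0); a round "stops" iff it is the last round of its session. Prior
# outcome always refers to the immediately preceding round of the same
# session, so the first round of each session is excluded from the stake
# and speed facets.

.prep_player <- function(records) {
  dt <- data.table::as.data.table(records)
  dt <- dt[order(session_id, round_in_session)]
  if (nrow(dt) == 0L) {
    dt[, `:=`(is_win = logical(0), stop = logical(0), prev_win = logical(0),
              prev_stake = integer(0))]
    return(dt)
  }
  dt[, is_win := win_cents > 0L]
  dt[, stop := round_in_session == max(round_in_session), by = session_id]
  dt[, prev_win := data.table::shift(is_win), by = session_id]
  dt[, prev_stake := data.table::shift(stake_cents), by = session_id]
  dt
}

#' Stopping facet of one player
#'
#' Conditional probabilities of ending a session after a win and after a
#' loss, normalized by the player's overall stopping probability. The
#' relative likelihood after a loss above 1 means the player stops more
#' readily after losing than their base rate.
#'
#' @param records one player's tracking records (all sessions).
#' @param min_count inclusion filter: at least this many wins and losses
#'   (default 5).
#' @return list with round counts, conditional/overall stop
#'   probabilities, relative likelihoods `rl_win`/`rl_loss` and the
#'   `included` flag.
#' @export
stop_facet <- function(records, min_count = 5L) {
  dt <- .prep_player(records)
  if (nrow(dt) == 0L) stop("stop_facet() requires at least one session")
  n_win <- sum(dt$is_win)
  n_loss <- sum(!dt$is_win)
  p_overall <- mean(dt$stop)
  p_win <- if (n_win > 0L) sum(dt$stop & dt$is_win) / n_win else NA_real_
  p_loss <- if (n_loss > 0L) sum(dt$stop & !dt$is_win) / n_loss else NA_real_
  list(n_win = n_win, n_loss = n_loss,
       p_stop_given_win = p_win, p_stop_given_loss = p_loss,
       p_stop_overall = p_overall,
       rl_win = p_win / p_overall, rl_loss = p_loss / p_overall,
       included = n_win >= min_count && n_loss >= min_count)
}

#' Stake-change facet of one player
#'
#' For every round with a previous round in the same session, the signed
#' stake change in euro cents relative to that previous round, summarized
#' by the prior outcome: probability of any change and mean signed change.
#'
#' @param records one player's tracking records.
#' @param min_count inclusion filter: at least this many retained rounds
#'   after a win and after a loss (default 5).
#' @return list with per-prior-outcome counts, change probabilities,
#'   mean deltas (euro cents) and the `included` flag.
#' @export
stake_facet <- function(records, min_count = 5L) {
  dt <- .prep_player(records)
  ret <- dt[!is.na(prev_stake)]
  ret[, delta := as.numeric(stake_cents - prev_stake)]
  n_w <- ret[prev_win == TRUE, .N]
  n_l <- ret[prev_win == FALSE, .N]
  list(n_after_win = n_w, n_after_loss = n_l,
       p_change_win = if (n_w) ret[prev_win == TRUE, mean(delta != 0)] else NA_real_,
       p_change_loss = if (n_l) ret[prev_win == FALSE, mean(delta != 0)] else NA_real_,
       mean_delta_win = if (n_w) ret[prev_win == TRUE, mean(delta)] else NA_real_,
       mean_delta_loss = if (n_l) ret[prev_win == FALSE, mean(delta)] else NA_real_,
       included = n_w >= min_count && n_l >= min_count)
}

#' Speed-of-play facet of one player
#'
#' First-column response times are filtered (first round of each session;
#' RTs strictly above `rt_max_ms`), then z-standardized within the player
#' over all retained rounds, and averaged by prior outcome. A negative
#' `rt_diff` (post-loss minus post-win mean z) is post-loss speeding.
#'
#' @param records one player's tracking records.
#' @param rt_max_ms RT exclusion cutoff in ms; rounds with RT strictly
#'   above it are dropped (default 5000).
#' @param min_count inclusion filter: at least this many retained rounds
#'   after a win and after a loss (default 5).
#' @return list with post-exclusion counts, mean z per prior outcome,
#'   `rt_diff`, the retained z-scores (`z`, for diagnostics) and the
#'   `included` flag.
#' @export
speed_facet <- function(records, rt_max_ms = 5000, min_count = 5L) {
  dt <- .prep_player(records)
  ret <- dt[round_in_session > 1L & !is.na(first_column_rt_ms) &
              first_column_rt_ms <= rt_max_ms]
  n_w <- ret[prev_win == TRUE, .N]
  n_l <- ret[prev_win == FALSE, .N]
  sd_rt <- if (nrow(ret) >= 2L) stats::sd(ret$first_column_rt_ms) else NA_real_
  degenerate <- !is.na(sd_rt) && sd_rt == 0
  if (degenerate)
    warning("player has zero RT variance over retained rounds; excluded")
  if (nrow(ret) >= 2L && !degenerate) {
    ret[, z := (first_column_rt_ms - mean(first_column_rt_ms)) / sd_rt]
    mz_w <- if (n_w) ret[prev_win == TRUE, mean(z)] else NA_real_
    mz_l <- if (n_l) ret[prev_win == FALSE, mean(z)] else NA_real_
  } else {
    mz_w <- mz_l <- NA_real_
  }
  list(n_after_win = n_w, n_after_loss = n_l,
       mean_z_win = mz_w, mean_z_loss = mz_l,
       rt_diff = mz_l - mz_w,
       z = if (nrow(ret) >= 2L && !degenerate) ret$z else numeric(0),
       included = n_w >= min_count && n_l >= min_count && !degenerate)
}

#' Per-player facet tables for a labeled cohort
#'
#' Applies the three facets to every player and assembles the analysis
#' tables fed to [comparison_battery()], together with the
#' included-player and retained-round counts per facet and group.
#'
#' @param records multi-player tracking records.
#' @param groups labels: a `data.table`/`data.frame` with `player_id` and
#'   `group` (`"high"`/`"low"`), or a named character vector.
#' @param min_count,rt_max_ms facet filter parameters.
#' @return object of class `cohort_metrics`: list with `stop`, `stake`,
#'   `speed` per-player tables and a `counts` table.
#' @export
cohort_metrics <- function(records, groups, min_count = 5L, rt_max_ms = 5000) {
  dt <- data.table::as.data.table(records)
  if (!is.data.frame(groups))
    groups <- data.table::data.table(player_id = names(groups),
                                     group = unname(groups))
  groups <- data.table::as.data.table(groups)[, .(player_id, group)]
  players <- unique(dt$player_id)
  unlabeled <- setdiff(players, groups$player_id)
  if (length(unlabeled))
    stop("unlabeled player(s): ", paste(utils::head(unlabeled, 5), collapse = ", "))
  # vectorized equivalents of stop_facet()/stake_facet()/speed_facet(),
  # computed in one pass per facet (the single-player functions define the
  # semantics; equality of the two routes is under test)
  dt <- dt[order(player_id, session_id, round_in_session)]
  dt[, is_win := win_cents > 0L]
  dt[, stop := seq_len(.N) == .N, by = .(player_id, session_id)]
  dt[, prev_win := data.table::shift(is_win), by = .(player_id, session_id)]
  dt[, prev_stake := data.table::shift(stake_cents), by = .(player_id, session_id)]
  all_players <- data.table::data.table(player_id = players)

  stop_tb <- dt[, .(n_win = sum(is_win), n_loss = sum(!is_win),
                    .stops_win = sum(stop & is_win),
                    .stops_loss = sum(stop & !is_win),
                    p_stop_overall = mean(stop)), by = player_id]
  stop_tb[, p_stop_given_win := ifelse(n_win > 0L, .stops_win / n_win, NA_real_)]
  stop_tb[, p_stop_given_loss := ifelse(n_loss > 0L, .stops_loss / n_loss, NA_real_)]
  stop_tb[, `:=`(rl_win = p_stop_given_win / p_stop_overall,
                 rl_loss = p_stop_given_loss / p_stop_overall,
                 included = n_win >= min_count & n_loss >= min_count)]
  stop_tb[, c(".stops_win", ".stops_loss") := NULL]
  data.table::setcolorder(stop_tb, c("player_id", "n_win", "n_loss",
                                     "p_stop_given_win", "p_stop_given_loss",
                                     "p_stop_overall", "rl_win", "rl_loss",
                                     "included"))

  ret <- dt[!is.na(prev_stake)]
  ret[, delta := as.numeric(stake_cents - prev_stake)]
  stake_tb <- ret[, .(
    n_after_win = sum(prev_win), n_after_loss = sum(!prev_win),
    p_change_win = if (any(prev_win)) mean(delta[prev_win] != 0) else NA_real_,
    p_change_loss = if (any(!prev_win)) mean(delta[!prev_win] != 0) else NA_real_,
    mean_delta_win = if (any(prev_win)) mean(delta[prev_win]) else NA_real_,
    mean_delta_loss = if (any(!prev_win)) mean(delta[!prev_win]) else NA_real_),
    by = player_id]
  stake_tb <- merge(all_players, stake_tb, by = "player_id", all.x = TRUE)
  stake_tb[is.na(n_after_win), `:=`(n_after_win = 0L, n_after_loss = 0L)]
  stake_tb[, included := n_after_win >= min_count & n_after_loss >= min_count]

  rts <- dt[round_in_session > 1L & !is.na(first_column_rt_ms) &
              first_column_rt_ms <= rt_max_ms]
  rts[, `:=`(.mu = mean(first_column_rt_ms),
             .sd = if (.N >= 2L) stats::sd(first_column_rt_ms) else NA_real_),
      by = player_id]
  n_zero_var <- rts[.sd == 0, data.table::uniqueN(player_id)]
  if (length(n_zero_var) && !is.na(n_zero_var) && n_zero_var > 0L)
    warning(n_zero_var, " player(s) excluded from the speed facet for zero RT variance")
  rts[, z := (first_column_rt_ms - .mu) / .sd]
  speed_tb <- rts[, .(
    n_after_win = sum(prev_win), n_after_loss = sum(!prev_win),
    mean_z_win = if (any(prev_win)) mean(z[prev_win]) else NA_real_,
    mean_z_loss = if (any(!prev_win)) mean(z[!prev_win]) else NA_real_,
    .degenerate = isTRUE(.sd[1L] == 0)), by = player_id]
  speed_tb <- merge(all_players, speed_tb, by = "player_id", all.x = TRUE)
  speed_tb[is.na(n_after_win), `:=`(n_after_win = 0L, n_after_loss = 0L,
                                    .degenerate = FALSE)]
  speed_tb[, rt_diff := mean_z_loss - mean_z_win]
  speed_tb[, included := n_after_win >= min_count & n_after_loss >= min_count &
             !.degenerate]
  speed_tb[, .degenerate := NULL]

  stop_tb <- merge(stop_tb, groups, by = "player_id")
  stake_tb <- merge(stake_tb, groups, by = "player_id")
  speed_tb <- merge(speed_tb, groups, by = "player_id")
  rng <- function(x, f) if (length(x)) as.numeric(f(x)) else NA_real_
  count_block <- function(tb, facet, x_expr) {
    tb[included == TRUE,
       {
         x <- eval(x_expr, .SD)
         .(facet = facet, n_players = .N, rounds_total = sum(x),
           rounds_mean = mean(x), rounds_min = rng(x, min),
           rounds_max = rng(x, max))
       }, by = group]
  }
  counts <- data.table::rbindlist(list(
    count_block(stop_tb, "stop", quote(n_win + n_loss)),
    count_block(stake_tb, "stake", quote(n_after_win + n_after_loss)),
    count_block(speed_tb, "speed", quote(n_after_win + n_after_loss))),
    use.names = TRUE)
  if (nrow(counts)) data.table::setcolorder(counts, c("facet", "group"))
  structure(list(stop = stop_tb, stake = stake_tb, speed = speed_tb,
                 counts = counts),
            class = "cohort_metrics")
}

#' Play-behavior summary (12 parameters per player)
#'
#' The involvement "manipulation check" table: per player, session and
#' round counts, rounds per session, stake levels, win probability, net
#' win on winning rounds (presented amount minus stake), loss on losing
#' rounds (equal to the stake) and total money spent (positive = net
#' loss).
#'
#' @param records multi-player tracking records.
#' @param groups player labels as in [cohort_metrics()] (optional).
#' @return one-row-per-player `data.table`.
#' @export
play_summary <- function(records, groups = NULL) {
  dt <- data.table::as.data.table(records)
  dt <- dt[order(player_id, session_id, round_in_session)]
  out <- dt[, {
    win <- win_cents > 0L
    per_ses <- .SD[, .N, by = session_id]$N
    net_win_eur <- (win_cents[win] - stake_cents[win]) / 100
    loss_eur <- stake_cents[!win] / 100
    .(n_sessions = length(per_ses),
      n_rounds = .N,
      mean_rounds_per_session = mean(per_ses),
      median_rounds_per_session = as.numeric(stats::median(per_ses)),
      mean_stake_eur = mean(stake_cents) / 100,
      median_stake_eur = as.numeric(stats::median(stake_cents)) / 100,
      win_prob_pct = 100 * mean(win),
      mean_win_eur = if (any(win)) mean(net_win_eur) else NA_real_,
      median_win_eur = if (any(win)) stats::median(net_win_eur) else NA_real_,
      mean_loss_eur = if (any(!win)) mean(loss_eur) else NA_real_,
      median_loss_eur = if (any(!win)) stats::median(loss_eur) else NA_real_,
      total_spent_eur = (sum(stake_cents) - sum(win_cents)) / 100)
  }, by = player_id]
  if (!is.null(groups)) {
    if (!is.data.frame(groups))
      groups <- data.table::data.table(player_id = names(groups),
                                       group = unname(groups))
    out <- merge(out, data.table::as.data.table(groups)[, .(player_id, group)],
                 by = "player_id")
  }
  out[]
}
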