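# Hand-built tracking fixtures. A session is described by its win/loss
# sequence (logical vector) plus optional per-round stakes (euro), RTs and
# start latencies; fx_rounds() assembles a valid tracking table from one
# or more players' session lists.

fx_session <- function(wins, stake_eur = 1, rt_ms = 1000, gap_ms = 5000) {
  n <- length(wins)
  stake_cents <- as.integer(round(rep_len(stake_eur, n) * 100))
  data.table::data.table(
    round_in_session = seq_len(n),
    stake_cents = stake_cents,
    win_cents = ifelse(wins, 2L * stake_cents, 0L),
    start_latency_ms = as.numeric(rep_len(gap_ms, n)),
    first_column_rt_ms = as.numeric(rep_len(rt_ms, n)),
    bonus = FALSE)
}

# players: named list; each element a list of sessions, each session either
# a logical vector of wins or a ready data.table from fx_session()
fx_rounds <- function(players) {
  ses_id <- 0L
  out <- list()
  for (pid in names(players)) {
    for (s in players[[pid]]) {
      ses_id <- ses_id + 1L
      dt <- if (is.logical(s)) fx_session(s) else data.table::copy(s)
      dt[, `:=`(player_id = pid, session_id = ses_id)]
      out[[length(out) + 1L]] <- dt
    }
  }
  dt <- data.table::rbindlist(out)
  dt[, round_id := seq_len(.N)]
  data.table::setcolorder(dt, c("player_id", "session_id", "round_id",
                                "round_in_session", "stake_cents", "win_cents",
                                "start_latency_ms", "first_column_rt_ms",
                                "bonus"))
  dt[]
}

# a small grid constructor: g3(row1, row2, row3) with face ids
g3 <- function(r1, r2, r3) matrix(c(r1, r2, r3), nrow = 3, byrow = TRUE)

# a filled slot guaranteed to score nothing: rows 1-3 and both diagonals
# all mixed
g_zero <- function() g3(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))

# a slot whose only matching line is its top row of face `f`
g_toprow <- function(f) g3(c(f, f, f), c(1, 2, 3), c(3, 2, 1))

# fast one-shot sim config for tests
fx_sim_config <- function(n_high = 10, n_low = 10, seed = 1, ...) {
  sim_config(n_players = c(high = n_high, low = n_low), seed = seed, ...)
}
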