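test_that("sim_config validates its inputs and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(group_params(h_w = 1.2), "\\[0, 1\\]")
  expect_error(group_params(rt_log_sd = 0), "rt_log_sd")
  expect_error(sim_config(n_players = c(a = 1, b = 2), seed = 1), "named")
})

test_that("point-mass parameter distributions give identical profiles", {
  g <- group_params(n_sessions_mean = 1, base_level_range = c(3, 3),
                    rt_log_mean_sd = 0, delta_sd = 0)
  cfg <- sim_config(n_players = c(high = 8, low = 8), seed = 4,
                    groups = list(high = g, low = g))
  set.seed(4)
  prof <- sample_profiles(cfg)
  for (col in setdiff(names(prof), c("player_id", "group")))
    expect_equal(data.table::uniqueN(prof[[col]]), 1L, info = col)
  expect_true(all(prof$n_sessions == 1L))
})

test_that("profile sampling and dataset generation are seed-deterministic", {
  cfg <- fx_sim_config(6, 6, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$rounds, b$rounds)
})

test_that("group contrasts in the profile distributions are recovered", {
  cfg <- sim_config(n_players = c(high = 500, low = 500), seed = 9)
  set.seed(9)
  prof <- sample_profiles(cfg)
  # high group: higher base stake level, more sessions, weaker RT shift
  expect_gt(prof[group == "high", mean(base_level)],
            prof[group == "low", mean(base_level)])
  expect_gt(prof[group == "high", mean(n_sessions)],
            prof[group == "low", mean(n_sessions)])
  expect_gt(prof[group == "high", mean(delta)], prof[group == "low", mean(delta)])
})

test_that("degenerate hazards and stake policies behave as stated", {
  # h = 1: every session is exactly one round
  g1 <- group_params(h_w = 1, h_l = 1, n_sessions_mean = 3)
  cfg1 <- sim_config(n_players = c(high = 4, low = 4), seed = 21,
                     groups = list(high = g1, low = g1))
  ds1 <- generate_dataset(cfg1)
  expect_true(all(ds1$rounds$round_in_session == 1L))
  expect_equal(nrow(ds1$rounds), sum(ds1$profiles$n_sessions))
  # q = 0: stake never changes within a session
  g2 <- group_params(q_w = 0, q_l = 0)
  cfg2 <- sim_config(n_players = c(high = 3, low = 3), seed = 22,
                     groups = list(high = g2, low = g2))
  ds2 <- generate_dataset(cfg2)
  expect_true(all(ds2$rounds[, data.table::uniqueN(stake_cents),
                             by = .(player_id, session_id)]$V1 == 1L))
})

test_that("forcing one round per session gives exact row counts", {
  # 2 + 2 players, 3 sessions each, h = 1 -> exactly 12 rows
  g <- group_params(h_w = 1, h_l = 1)
  cfg <- sim_config(n_players = c(high = 2, low = 2), seed = 3,
                    groups = list(high = g, low = g))
  set.seed(3)
  prof <- sample_profiles(cfg)
  prof[, n_sessions := 3L]
  pool <- chasemetrics:::.round_pool(cfg$game, chunk = 256L)
  rows <- sum(vapply(seq_len(nrow(prof)), function(i)
    nrow(simulate_player(prof[i], cfg, pool)), integer(1)))
  expect_equal(rows, 12L)
})

test_that("a negative post-loss RT shift speeds up post-loss rounds", {
  g <- group_params(n_sessions_mean = 6, h_w = 0.01, h_l = 0.01,
                    delta_mean = -0.5, delta_sd = 0, rt_log_mean_sd = 0)
  cfg <- sim_config(n_players = c(high = 1, low = 1), seed = 31,
                    groups = list(high = g, low = g))
  set.seed(31)
  prof <- sample_profiles(cfg)
  prof[, n_sessions := 10L]
  dt <- simulate_player(prof[1], cfg)
  expect_gt(nrow(dt), 500)
  dt[, prev_win := data.table::shift(win_cents > 0), by = session_index]
  m_loss <- dt[prev_win == FALSE, mean(log(first_column_rt_ms))]
  m_win <- dt[prev_win == TRUE, mean(log(first_column_rt_ms))]
  expect_lt(m_loss, m_win)
  # the shift is recovered within Monte-Carlo error on the log scale
  expect_lt(abs((m_loss - m_win) - (-0.5)), 0.15)
})

test_that("emitted datasets conform to the tracking schema", {
  cfg <- fx_sim_config(8, 8, seed = 13, later_columns = TRUE)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(validate_rounds(ds$rounds)), 0L)
  # all stakes on the configured ladder
  expect_true(all(ds$rounds$stake_cents %in% as.integer(cfg$game$stakes)))
  # win amount is 0 on losses and at least the stake on wins
  # (>= 100 points at 1/100 euro per point per euro staked)
  expect_true(all(ds$rounds$win_cents == 0L |
                    ds$rounds$win_cents >= ds$rounds$stake_cents))
  expect_true(all(paste0("column_rt_", 2:12, "_ms") %in% names(ds$rounds)))
  # unique ids and 1-based strictly increasing round indices
  expect_equal(anyDuplicated(ds$rounds$round_id), 0L)
  expect_true(all(ds$rounds[, round_in_session[1L] == 1L,
                            by = .(player_id, session_id)]$V1))
})

test_that("a finite session bankroll forces stops before overdraft", {
  g <- group_params(h_w = 0.001, h_l = 0.001, bankroll_eur = 3,
                    base_level_range = c(4, 4), q_w = 0, q_l = 0)
  cfg <- sim_config(n_players = c(high = 5, low = 5), seed = 41,
                    groups = list(high = g, low = g))
  ds <- generate_dataset(cfg)
  # walk each session's bankroll: it must cover every stake when placed
  ok <- ds$rounds[, {
    bank <- 300
    fine <- TRUE
    for (i in seq_len(.N)) {
      if (bank < stake_cents[i]) { fine <- FALSE; break }
      bank <- bank - stake_cents[i] + win_cents[i]
    }
    fine
  }, by = .(player_id, session_id)]$V1
  expect_true(all(ok))
})

test_that("stop hazards leave their footprint in the stopping facet", {
  # h_l > h_w must surface as rl_loss > rl_win at cohort level in (nearly)
  # every simulated cohort; 12/12 here is stricter than the 95% bound
  hits <- 0L
  for (rep in 1:12) {
    g_hi <- group_params(n_sessions_mean = 3, h_w = 0.008, h_l = 0.022,
                         base_level_range = c(4, 7))
    g_lo <- group_params(n_sessions_mean = 3)
    cfg <- sim_config(n_players = c(high = 100, low = 100), seed = 500 + rep,
                      groups = list(high = g_hi, low = g_lo))
    ds <- generate_dataset(cfg)
    m <- suppressWarnings(
      cohort_metrics(ds$rounds, ds$profiles[, .(player_id, group)]))
    inc <- m$stop[included == TRUE]
    if (nrow(inc) > 10 && mean(inc$rl_loss) > mean(inc$rl_win)) hits <- hits + 1L
  }
  expect_equal(hits, 12L)
})

test_that("with no RT shift the speed-facet group test is calibrated", {
  # both groups delta = 0 -> the between-group Welch test on the per-player
  # rt_diff must reject at about the nominal .05; 200 replicate cohorts.
  # A high-payout table keeps rounds-per-player small while retaining
  # enough post-win rounds for inclusion.
  tab <- point_table(values = c(100, 100, 100, 100, 100, 100, 100, 100, 100))
  game <- game_config(table = tab)
  g <- group_params(n_sessions_mean = 2, h_w = 0.04, h_l = 0.04,
                    delta_mean = 0, delta_sd = 0, break_prob = 0)
  rej <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    cfg <- sim_config(n_players = c(high = 40, low = 40), seed = 9000 + rep,
                      game = game, groups = list(high = g, low = g))
    ds <- generate_dataset(cfg)
    m <- suppressWarnings(
      cohort_metrics(ds$rounds, ds$profiles[, .(player_id, group)]))
    sp <- m$speed[included == TRUE]
    if (sp[group == "high", .N] >= 5 && sp[group == "low", .N] >= 5) {
      w <- welch_t(sp[group == "high", rt_diff], sp[group == "low", rt_diff])
      if (w$p < 0.05) rej <- rej + 1L
    }
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})
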