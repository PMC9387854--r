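# W = winning round, L = losing round; sessions end at their last element.

test_that("stop facet computes conditional and relative stop likelihoods", {
  # 10 wins (2 session-final) and 20 losses (4 session-final):
  # p|win = 2/10, p|loss = 4/20, overall = 6/30, rl = 1 for both
  p1 <- list(A = list(c(FALSE, TRUE, TRUE, FALSE, TRUE),
                      c(TRUE, FALSE, TRUE, FALSE, TRUE),
                      c(TRUE, FALSE, FALSE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE, FALSE, FALSE)))
  st <- stop_facet(fx_rounds(p1))
  expect_equal(st$n_win, 10L)
  expect_equal(st$n_loss, 20L)
  expect_equal(st$p_stop_given_win, 0.2)
  expect_equal(st$p_stop_given_loss, 0.2)
  expect_equal(st$p_stop_overall, 0.2)
  expect_equal(st$rl_win, 1)
  expect_equal(st$rl_loss, 1)
  expect_true(st$included)

  # 5 wins (0 final), 15 losses (4 final): rl_win 0, rl_loss (4/15)/(4/20)
  p2 <- list(A = list(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE, FALSE, FALSE),
                      c(FALSE, FALSE, FALSE, FALSE, FALSE)))
  st2 <- stop_facet(fx_rounds(p2))
  expect_equal(st2$p_stop_overall, 0.2)
  expect_equal(st2$rl_win, 0)
  expect_equal(st2$rl_loss, (4 / 15) / 0.2)
  expect_true(st2$included)

  # inclusion requires at least 5 wins and 5 losses
  p3 <- list(A = list(rep(c(TRUE, FALSE), c(4, 30))))
  expect_false(stop_facet(fx_rounds(p3))$included)
  expect_error(stop_facet(fx_rounds(list(A = list(c(TRUE))))[0]), "session")
})

test_that("the weighted identity holds whenever wins and losses exhaust rounds", {
  ds <- generate_dataset(fx_sim_config(8, 8, seed = 55))
  m <- suppressWarnings(cohort_metrics(ds$rounds, ds$profiles[, .(player_id, group)]))
  inc <- m$stop[included == TRUE]
  expect_gt(nrow(inc), 0)
  lhs <- with(inc, (n_win * rl_win + n_loss * rl_loss) / (n_win + n_loss))
  expect_true(all(abs(lhs - 1) < 1e-12))
})

test_that("stake facet drops first rounds and measures exact cent deltas", {
  ses <- fx_session(c(FALSE, TRUE, FALSE, TRUE, FALSE),
                    stake_eur = c(0.25, 0.50, 0.50, 0.75, 0.75))
  sk <- stake_facet(fx_rounds(list(A = list(ses))))
  # retained rounds 2..5; prior outcomes: L, W, L, W
  expect_equal(sk$n_after_win, 2L)
  expect_equal(sk$n_after_loss, 2L)
  # after-loss deltas: +25 (0.25 -> 0.50), +25 (0.50 -> 0.75)
  expect_equal(sk$mean_delta_loss, 25)
  # after-win deltas: 0 (0.50 -> 0.50), 0 (0.75 -> 0.75)
  expect_equal(sk$mean_delta_win, 0)
  expect_equal(sk$p_change_loss, 1)
  expect_equal(sk$p_change_win, 0)
  expect_false(sk$included)

  # constant stake: zero change probability and delta
  sk2 <- stake_facet(fx_rounds(list(A = list(
    fx_session(rep(c(TRUE, FALSE), 10))))))
  expect_equal(sk2$p_change_win, 0)
  expect_equal(sk2$p_change_loss, 0)
  expect_equal(sk2$mean_delta_win, 0)
  expect_equal(sk2$mean_delta_loss, 0)
  expect_true(sk2$included)

  # a 3-round session contributes exactly 2 retained rounds
  sk3 <- stake_facet(fx_rounds(list(A = list(rep(FALSE, 3)))))
  expect_equal(sk3$n_after_win + sk3$n_after_loss, 2L)
})

test_that("speed facet applies the strict RT cutoff before standardizing", {
  rts <- c(900, 1000, 5000, 5001, 1100, 1200, 800, 950, 1050, 990)
  wins <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  sp <- speed_facet(fx_rounds(list(A = list(fx_session(wins, rt_ms = rts)))))
  # round 1 (no prior) and round 4 (RT 5001 > 5000) are dropped; RT 5000 stays
  expect_equal(sp$n_after_win + sp$n_after_loss, 8L)
  expect_equal(length(sp$z), 8L)
  expect_lt(abs(mean(sp$z)), 1e-9)
  expect_lt(abs(sd(sp$z) - 1), 1e-9)
  expect_equal(sp$rt_diff, sp$mean_z_loss - sp$mean_z_win)

  # no post-win rounds -> excluded
  sp2 <- speed_facet(fx_rounds(list(A = list(
    fx_session(rep(FALSE, 12), rt_ms = seq(600, 1700, by = 100))))))
  expect_false(sp2$included)

  # zero RT variance -> warning and exclusion
  expect_warning(
    sp3 <- speed_facet(fx_rounds(list(A = list(
      fx_session(rep(c(TRUE, FALSE), 8), rt_ms = 1000))))),
    "zero RT variance")
  expect_false(sp3$included)
})

test_that("speed facet is invariant to affine rescaling of raw RTs", {
  set.seed(8)
  wins <- runif(40) < 0.4
  rts <- runif(40, 500, 2000)
  base <- fx_rounds(list(A = list(fx_session(wins, rt_ms = rts))))
  scaled <- fx_rounds(list(A = list(fx_session(wins, rt_ms = 2 * rts + 300))))
  a <- speed_facet(base)
  b <- speed_facet(scaled)  # no round crosses the 5000 ms cut (max 4300)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_equal(a$rt_diff, b$rt_diff, tolerance = 1e-12)
})

test_that("filters only remove: padding with excluded rounds changes nothing", {
  set.seed(9)
  wins <- runif(30) < 0.4
  core <- list(fx_session(wins, rt_ms = runif(30, 500, 2000)))
  # pad with single-round sessions (always dropped by the stake and speed
  # facets: a first round has no prior outcome)
  padded <- c(core, list(c(TRUE), c(FALSE), c(FALSE)))
  a_sk <- stake_facet(fx_rounds(list(A = core)))
  b_sk <- stake_facet(fx_rounds(list(A = padded)))
  expect_equal(a_sk, b_sk)
  a_sp <- speed_facet(fx_rounds(list(A = core)))
  b_sp <- speed_facet(fx_rounds(list(A = padded)))
  expect_equal(a_sp, b_sp)
})

test_that("cohort_metrics agrees with the per-player facet functions", {
  ds <- generate_dataset(fx_sim_config(6, 6, seed = 14))
  m <- suppressWarnings(cohort_metrics(ds$rounds, ds$profiles[, .(player_id, group)]))
  for (pid in unique(ds$rounds$player_id)) {
    rec <- ds$rounds[player_id == pid]
    st <- stop_facet(rec); sk <- stake_facet(rec)
    sp <- suppressWarnings(speed_facet(rec))
    vs <- as.list(m$stop[player_id == pid])
    vk <- as.list(m$stake[player_id == pid])
    vp <- as.list(m$speed[player_id == pid])
    expect_equal(vs[names(st)], st, info = pid)
    expect_equal(vk[names(sk)], sk, info = pid)
    expect_equal(vp[setdiff(names(sp), "z")], sp[setdiff(names(sp), "z")],
                 info = pid)
  }
})

test_that("cohort counts match a hand-enumerated fixture", {
  mk_ok <- function() rep(c(TRUE, FALSE), c(6, 6))      # included everywhere
  mk_few_wins <- function() rep(c(TRUE, FALSE), c(3, 9)) # too few wins
  players <- c(
    setNames(lapply(1:4, function(i) list(mk_ok())), paste0("H", 1:4)),
    setNames(lapply(1:2, function(i) list(mk_few_wins())), paste0("H", 5:6)),
    setNames(lapply(1:3, function(i) list(mk_ok())), paste0("L", 1:3)),
    setNames(lapply(1:1, function(i) list(mk_few_wins())), "L4"))
  dt <- fx_rounds(players)
  groups <- data.table::data.table(
    player_id = c(paste0("H", 1:6), paste0("L", 1:4)),
    group = rep(c("high", "low"), c(6, 4)))
  m <- suppressWarnings(cohort_metrics(dt, groups))  # constant RTs: speed facet all excluded
  cn <- m$counts[facet == "stop"]
  expect_equal(cn[group == "high", n_players], 4L)
  expect_equal(cn[group == "low", n_players], 3L)
  expect_equal(cn[group == "high", rounds_total], 4L * 12L)
  # stake facet: 11 retained rounds per player (12 minus first round); the
  # few-win players have only 3 post-win rounds and fail the >= 5 filter
  expect_equal(m$counts[facet == "stake" & group == "low", n_players], 3L)
  expect_equal(m$counts[facet == "stake" & group == "low", rounds_total],
               3L * 11L)
  expect_equal(nrow(m$counts[facet == "speed"]), 0L)
  expect_error(cohort_metrics(dt, groups[1:9]), "unlabeled")
  # all players filtered out -> empty counts, no crash
  few <- fx_rounds(list(X = list(c(TRUE, FALSE))))
  m2 <- cohort_metrics(few, data.table::data.table(player_id = "X", group = "low"))
  expect_equal(nrow(m2$counts), 0L)
})

test_that("play_summary computes the 12 play-behavior parameters", {
  # one session, 4 losing rounds at 1 euro: total spent = 4
  ps <- play_summary(fx_rounds(list(A = list(rep(FALSE, 4)))))
  expect_equal(ps$n_sessions, 1L)
  expect_equal(ps$n_rounds, 4L)
  expect_equal(ps$total_spent_eur, 4)
  expect_equal(ps$mean_loss_eur, 1)
  expect_true(is.na(ps$mean_win_eur))

  # hand-built 20-round mix: stake 1, 8 wins paying 2 euro gross
  wins <- rep(c(TRUE, FALSE), c(8, 12))
  ps2 <- play_summary(fx_rounds(list(B = list(wins[1:10], wins[11:20]))))
  expect_equal(ps2$win_prob_pct, 100 * 8 / 20)
  expect_equal(ps2$mean_win_eur, 1)      # presented 2 euro minus 1 euro stake
  expect_equal(ps2$mean_loss_eur, 1)     # the loss equals the stake
  expect_equal(ps2$median_rounds_per_session, 10)
  expect_equal(ps2$total_spent_eur, 20 - 16)

  # mean loss equals mean stake on losing rounds, by construction
  ds <- generate_dataset(fx_sim_config(4, 4, seed = 66))
  ps3 <- play_summary(ds$rounds, ds$profiles[, .(player_id, group)])
  ref <- ds$rounds[win_cents == 0L, mean(stake_cents) / 100, by = player_id]
  cmp <- merge(ps3, ref, by = "player_id")
  expect_equal(cmp$mean_loss_eur, cmp$V1)
  expect_true(all(c("group") %in% names(ps3)))
})
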