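# Cohort simulator: latent per-player behavioral parameters (stop hazards,
# stake policy, response-time model) generate round-level tracking logs
# with known ground truth, so the chasing pipeline can be tested against
# effects it is supposed to recover.

#' Per-group parameter distributions
#'
#' Describes how the latent [player profile][sample_profiles()] fields of
#' one involvement group are drawn. Point masses (sd = 0) are allowed
#' everywhere. Defaults are set by [sim_config()] per group.
#'
#' @param n_sessions_mean mean session count; sessions per player are
#'   drawn as `1 + rpois(n_sessions_mean - 1)`.
#' @param h_w,h_l probability of ending the session after a winning
#'   (losing) round.
#' @param q_w,q_l probability of changing the stake on the round after a
#'   win (loss).
#' @param step_up_prob_win,step_up_prob_loss given a stake change, the
#'   probability that it is one ladder level up (otherwise one down).
#' @param base_level_range integer range of starting stake-ladder levels,
#'   sampled uniformly.
#' @param rt_log_mean_mean,rt_log_mean_sd distribution of the player's
#'   baseline log first-column response time (log-ms).
#' @param rt_log_sd within-player log-RT standard deviation.
#' @param delta_mean,delta_sd distribution of the post-loss RT shift on
#'   the log scale (negative = speeding up after a loss).
#' @param gap_log_mean,gap_log_sd lognormal inter-round start latency
#'   (log-ms).
#' @param break_prob probability that a non-initial round follows an
#'   in-session break (its start latency is drawn from the break
#'   distribution instead).
#' @param break_log_mean,break_log_sd lognormal break duration (log-ms).
#' @param bankroll_eur optional per-session bankroll in euro; when finite,
#'   a session is also forced to end once the bankroll cannot cover the
#'   next stake (probing forced rather than chosen stopping).
#' @return a list of class `group_params`.
#' @export
group_params <- function(n_sessions_mean = 6,
                         h_w = 0.010, h_l = 0.030,
                         q_w = 0.03, q_l = 0.06,
                         step_up_prob_win = 0.85, step_up_prob_loss = 0.30,
                         base_level_range = c(2L, 4L),
                         rt_log_mean_mean = log(900), rt_log_mean_sd = 0.15,
                         rt_log_sd = 0.45,
                         delta_mean = -0.25, delta_sd = 0.05,
                         gap_log_mean = log(3000), gap_log_sd = 0.6,
                         break_prob = 0.01,
                         break_log_mean = log(1.5e6), break_log_sd = 0.4,
                         bankroll_eur = Inf) {
  p <- as.list(environment())
  probs <- c(p$h_w, p$h_l, p$q_w, p$q_l, p$step_up_prob_win,
             p$step_up_prob_loss, p$break_prob)
  if (any(probs < 0 | probs > 1)) stop("hazards and probabilities must be in [0, 1]")
  if (p$rt_log_sd <= 0) stop("rt_log_sd must be > 0")
  if (p$n_sessions_mean < 1) stop("n_sessions_mean must be >= 1")
  if (p$delta_sd < 0 || p$rt_log_mean_sd < 0) stop("sds must be >= 0")
  structure(p, class = "group_params")
}

#' Simulation configuration
#'
#' The stated world of the synthetic cohort: two involvement groups whose
#' defaults mirror the qualitative contrasts of operator data (the high
#' group plays more sessions, longer sessions, higher stakes and faster),
#' with win-chasing in stopping and staking (lower stop hazard and
#' net-upward stake moves after wins) and post-loss speeding that is
#' attenuated in the high group.
#'
#' @param n_players named vector `c(high = ..., low = ...)`.
#' @param seed mandatory integer RNG seed.
#' @param game a [game_config()].
#' @param groups named list with `high` and `low` [group_params()].
#' @param max_rounds_per_session truncation guard (default 1000).
#' @param later_columns logical; also emit the 11 later column-placement
#'   latencies (nuisance fields unused by any indicator; default `FALSE`).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_players = c(high = 50L, low = 50L),
                       seed,
                       game = game_config(),
                       groups = list(
                         high = group_params(n_sessions_mean = 8,
                                             h_w = 0.008, h_l = 0.022,
                                             base_level_range = c(4L, 7L),
                                             rt_log_mean_mean = log(700),
                                             delta_mean = -0.10),
                         low = group_params()),
                       max_rounds_per_session = 1000L,
                       later_columns = FALSE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("sim_config() requires an explicit integer seed")
  if (!all(c("high", "low") %in% names(n_players)))
    stop("n_players must be named c(high = ..., low = ...)")
  if (!all(c("high", "low") %in% names(groups)))
    stop("groups must contain 'high' and 'low' group_params")
  lapply(groups, function(g) if (!inherits(g, "group_params"))
    stop("each group must be a group_params() object"))
  stopifnot(inherits(game, "game_config"), max_rounds_per_session >= 1)
  structure(list(n_players = n_players, seed = as.integer(seed), game = game,
                 groups = groups,
                 max_rounds_per_session = as.integer(max_rounds_per_session),
                 later_columns = isTRUE(later_columns)),
            class = "sim_config")
}

#' Read a simulation configuration from a JSON file
#'
#' Top-level keys: `n_players` (object with `high`/`low`), `seed`,
#' `max_rounds_per_session`, `later_columns`, `game` (see
#' [read_game_config()] keys) and `groups` (object with `high`/`low`, each
#' holding [group_params()] arguments).
#'
#' @param path path to a JSON file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(cfg$n_players))
    args$n_players <- unlist(cfg$n_players)
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(cfg$max_rounds_per_session))
    args$max_rounds_per_session <- cfg$max_rounds_per_session
  if (!is.null(cfg$later_columns)) args$later_columns <- cfg$later_columns
  if (!is.null(cfg$game)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(cfg$game, tmp, auto_unbox = TRUE)
    args$game <- read_game_config(tmp)
  }
  if (!is.null(cfg$groups)) {
    defaults <- eval(formals(sim_config)$groups)
    args$groups <- list(
      high = do.call(group_params, utils::modifyList(
        unclass(defaults$high), as.list(cfg$groups$high %||% list()))),
      low = do.call(group_params, utils::modifyList(
        unclass(defaults$low), as.list(cfg$groups$low %||% list()))))
  }
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw latent player profiles
#'
#' One row per player, with the generating involvement group recorded as
#' ground truth. Uses the global RNG.
#'
#' @param config a [sim_config()].
#' @return a `data.table`, one row per player.
#' @export
sample_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_levels <- length(config$game$stakes)
  out <- lapply(c("high", "low"), function(grp) {
    n <- as.integer(config$n_players[[grp]])
    if (n < 1L) return(NULL)
    g <- config$groups[[grp]]
    lo <- max(1L, as.integer(g$base_level_range[1L]))
    hi <- min(n_levels, as.integer(g$base_level_range[2L]))
    data.table::data.table(
      group = grp,
      n_sessions = 1L + stats::rpois(n, g$n_sessions_mean - 1),
      h_w = g$h_w, h_l = g$h_l, q_w = g$q_w, q_l = g$q_l,
      step_up_prob_win = g$step_up_prob_win,
      step_up_prob_loss = g$step_up_prob_loss,
      base_level = if (lo == hi) rep(lo, n)
                   else sample(seq.int(lo, hi), n, replace = TRUE),
      rt_log_mean = stats::rnorm(n, g$rt_log_mean_mean, g$rt_log_mean_sd),
      rt_log_sd = g$rt_log_sd,
      delta = stats::rnorm(n, g$delta_mean, g$delta_sd),
      gap_log_mean = g$gap_log_mean, gap_log_sd = g$gap_log_sd,
      break_prob = g$break_prob,
      break_log_mean = g$break_log_mean, break_log_sd = g$break_log_sd,
      bankroll_cents = if (is.finite(g$bankroll_eur))
        round(g$bankroll_eur * 100) else Inf)
  })
  prof <- data.table::rbindlist(out)
  prof[, player_id := sprintf("P%04d", seq_len(nrow(prof)))]
  data.table::setcolorder(prof, "player_id")
  prof[]
}

# A lazily extended pool of pre-simulated i.i.d. round results. Round
# outcomes do not depend on the stake or on play history, so rounds can be
# drawn in large vectorized batches and consumed sequentially.
.round_pool <- function(game, chunk = 32768L) {
  env <- new.env(parent = emptyenv())
  env$dt <- simulate_rounds(chunk, game)
  env$pos <- 0L
  env$game <- game
  env$chunk <- chunk
  env
}

.pool_peek <- function(pool, k) {
  while (pool$pos + k > nrow(pool$dt)) {
    pool$dt <- data.table::rbindlist(list(
      pool$dt, simulate_rounds(max(pool$chunk, k), pool$game)))
  }
  pool$dt[pool$pos + seq_len(k)]
}

.pool_consume <- function(pool, k) pool$pos <- pool$pos + k

#' Simulate all rounds of one player
#'
#' Round results come from the game engine; after each round the session
#' ends with probability `h_w` after a win and `h_l` after a loss (or at
#' the truncation guard, or when a finite bankroll cannot cover the next
#' stake). The stake moves along the ladder with outcome-dependent change
#' probability and direction. The first-column response time is lognormal
#' with an additive log-scale shift after losses.
#'
#' @param profile a single-row profile (one row of [sample_profiles()]
#'   output, or a named list with the same fields).
#' @param config a [sim_config()].
#' @param pool internal round pool (shared across players by
#'   [generate_dataset()]); created on the fly if `NULL`.
#' @return a `data.table` of this player's rounds with columns
#'   `session_index`, `round_in_session`, `stake_cents`, `win_cents`,
#'   `start_latency_ms`, `first_column_rt_ms`, `bonus` (and
#'   `column_rt_2_ms` .. `column_rt_12_ms` when configured).
#' @export
simulate_player <- function(profile, config, pool = NULL) {
  p <- as.list(profile)
  if (is.null(pool)) pool <- .round_pool(config$game, chunk = 4096L)
  guard <- config$max_rounds_per_session
  stakes <- as.integer(config$game$stakes)
  n_levels <- length(stakes)
  prize_rate <- config$game$table$prize_rate
  acc <- vector("list", p$n_sessions)
  for (s in seq_len(p$n_sessions)) {
    # session length: first round whose stop draw fires, scanned in chunks
    len <- 0L
    repeat {
      k <- min(128L, guard - len)
      if (k == 0L) break
      w <- .pool_peek(pool, len + k)$is_win[len + seq_len(k)]
      u <- stats::runif(k)
      hit <- which(u < ifelse(w, p$h_w, p$h_l))
      if (length(hit)) { len <- len + hit[1L]; break }
      len <- len + k
      if (len >= guard) break
    }
    rounds <- .pool_peek(pool, len)
    win <- rounds$is_win
    # stake path (and optional bankroll-forced stop)
    level <- integer(len)
    level[1L] <- min(max(p$base_level, 1L), n_levels)
    bank <- p$bankroll_cents
    forced_at <- -1L
    j <- 1L
    while (j <= len) {
      if (is.finite(bank)) {
        if (bank < stakes[level[j]]) { forced_at <- j - 1L; break }
        gross <- if (win[j])
          round(rounds$total_points[j] * prize_rate * stakes[level[j]]) else 0
        bank <- bank - stakes[level[j]] + gross
      }
      if (j == len) break
      q <- if (win[j]) p$q_w else p$q_l
      up <- if (win[j]) p$step_up_prob_win else p$step_up_prob_loss
      lv <- level[j]
      if (stats::runif(1) < q) {
        lv <- lv + (if (stats::runif(1) < up) 1L else -1L)
        lv <- min(max(lv, 1L), n_levels)
      }
      level[j + 1L] <- lv
      j <- j + 1L
    }
    if (forced_at >= 0L) {
      len <- forced_at
      level <- level[seq_len(len)]
      win <- win[seq_len(len)]
      rounds <- rounds[seq_len(len)]
    }
    if (len == 0L) { .pool_consume(pool, 0L); next }
    .pool_consume(pool, len)
    stake_cents <- stakes[level]
    win_cents <- ifelse(win,
                        round(rounds$total_points * prize_rate * stake_cents), 0)
    prev_loss <- c(FALSE, !win[-len])  # first round has no prior outcome
    rt <- exp(stats::rnorm(len, p$rt_log_mean + p$delta * prev_loss, p$rt_log_sd))
    gap <- exp(stats::rnorm(len, p$gap_log_mean, p$gap_log_sd))
    if (len > 1L && p$break_prob > 0) {
      br <- which(c(FALSE, stats::runif(len - 1L) < p$break_prob))
      if (length(br))
        gap[br] <- exp(stats::rnorm(length(br), p$break_log_mean, p$break_log_sd))
    }
    ses <- data.table::data.table(
      session_index = s, round_in_session = seq_len(len),
      stake_cents = as.integer(stake_cents),
      win_cents = as.integer(win_cents),
      start_latency_ms = gap, first_column_rt_ms = rt,
      bonus = rounds$bonus_triggered)
    if (isTRUE(config$later_columns)) {
      lc <- matrix(exp(stats::rnorm(len * 11L, log(400), 0.3)), nrow = len)
      colnames(lc) <- paste0("column_rt_", 2:12, "_ms")
      ses <- cbind(ses, data.table::as.data.table(lc))
    }
    acc[[s]] <- ses
  }
  data.table::rbindlist(acc[!vapply(acc, is.null, logical(1))])
}

#' Generate a full synthetic tracking data set
#'
#' Seeds the global RNG from the config, draws profiles and simulates all
#' players' rounds, assigning globally unique player, session and round
#' IDs. The profile table is the ground truth for parameter-recovery
#' tests.
#'
#' @param config a [sim_config()].
#' @return list with `rounds` (a validated tracking `data.table`, see
#'   [read_rounds()] for the schema) and `profiles`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  profiles <- sample_profiles(config)
  pool <- .round_pool(config$game)
  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    dt <- simulate_player(profiles[i], config, pool)
    if (nrow(dt)) dt[, player_id := profiles$player_id[i]]
    out[[i]] <- dt
  }
  rounds <- data.table::rbindlist(out[vapply(out, nrow, integer(1)) > 0L])
  rounds[, session_id := data.table::rleid(player_id, session_index)]
  rounds[, round_id := seq_len(.N)]
  rounds[, session_index := NULL]
  data.table::setcolorder(rounds, c("player_id", "session_id", "round_id",
                                    "round_in_session", "stake_cents",
                                    "win_cents", "start_latency_ms",
                                    "first_column_rt_ms", "bonus"))
  list(rounds = rounds[], profiles = profiles)
}
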