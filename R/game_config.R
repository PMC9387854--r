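#' Point table of the dice game
#'
#' The game draws dice from a set of 10 faces with equal probability. Nine
#' faces are worth a fixed number of points when a line of three identical
#' faces is formed; one face is the bonus face (three of them on a line
#' trigger the bonus mini-game). The commercial game does not publish its
#' point values, so the shipped defaults are invented and fully
#' configurable.
#'
#' @param values numeric vector of point values for the non-bonus faces.
#'   Must be non-negative. Default `c(5, 10, 15, 20, 25, 30, 40, 50, 100)`.
#' @param n_bonus_faces number of bonus faces (default 1; the total number
#'   of faces must be 10).
#' @param win_threshold points needed for a round to count as a win
#'   (default 100).
#' @param slot_bonus_points extra points when all nine dice in a slot are
#'   identical (default 200).
#' @param multiplier_3slots,multiplier_4slots multipliers applied to the
#'   summed slot points when exactly 3 (resp. all 4) slots scored points.
#' @param prize_rate euro of gross prize per point per euro of stake
#'   (default 1/100: 100 points returns the stake).
#' @param bonus_points_fun function drawing `n` extra point totals awarded
#'   by the bonus mini-game (its internals are not observable in tracking
#'   data; default: a fixed 150 points).
#' @param slot_bonus_after_multiplier logical; if `TRUE` (default) the
#'   200-point all-nine bonus is added after the slot-count multiplier.
#' @return an object of class `point_table`.
#' @export
point_table <- function(values = c(5, 10, 15, 20, 25, 30, 40, 50, 100),
                        n_bonus_faces = 1L,
                        win_threshold = 100,
                        slot_bonus_points = 200,
                        multiplier_3slots = 1.5,
                        multiplier_4slots = 2.0,
                        prize_rate = 1 / 100,
                        bonus_points_fun = function(n) rep(150, n),
                        slot_bonus_after_multiplier = TRUE) {
  values <- as.numeric(values)
  n_bonus_faces <- as.integer(n_bonus_faces)
  if (length(values) + n_bonus_faces != 10L)
    stop("a point table must have exactly 10 faces (values + bonus faces)")
  if (n_bonus_faces < 0L) stop("n_bonus_faces must be >= 0")
  if (any(!is.finite(values)) || any(values < 0))
    stop("face point values must be finite and non-negative")
  stopifnot(is.function(bonus_points_fun), win_threshold > 0,
            slot_bonus_points >= 0, prize_rate > 0,
            multiplier_3slots > 0, multiplier_4slots > 0)
  # faces are integers 1..10; bonus faces occupy the top indices
  face_value <- c(values, rep(NA_real_, n_bonus_faces))
  structure(
    list(faces = seq_len(10L),
         face_value = face_value,
         bonus_faces = if (n_bonus_faces > 0L)
           seq.int(length(values) + 1L, 10L) else integer(0),
         win_threshold = win_threshold,
         slot_bonus_points = slot_bonus_points,
         multiplier_3slots = multiplier_3slots,
         multiplier_4slots = multiplier_4slots,
         prize_rate = prize_rate,
         bonus_points_fun = bonus_points_fun,
         slot_bonus_after_multiplier = slot_bonus_after_multiplier),
    class = "point_table")
}

#' Stake ladder
#'
#' The stake can be set to one of ten fixed levels between 0.25 and 20
#' euro. Only the endpoints and the number of levels are known for the
#' commercial game; the interior defaults are invented and configurable.
#' Stakes are stored as integer euro cents so stake-change analyses are
#' exact.
#'
#' @param levels_eur strictly increasing stake levels in euro; must start
#'   at 0.25, end at 20 and have length 10.
#' @return integer vector of class `stake_schedule` (euro cents).
#' @export
stake_schedule <- function(levels_eur = c(0.25, 0.50, 0.75, 1, 1.50, 2, 3, 5, 10, 20)) {
  cents <- round(levels_eur * 100)
  if (any(abs(levels_eur * 100 - cents) > 1e-6))
    stop("stake levels must be representable in euro cents")
  cents <- as.integer(cents)
  if (length(cents) != 10L) stop("the stake ladder has exactly 10 levels")
  if (any(diff(cents) <= 0L)) stop("stake levels must be strictly increasing")
  if (cents[1L] != 25L || cents[10L] != 2000L)
    stop("the stake ladder runs from 0.25 to 20 euro")
  structure(cents, class = "stake_schedule")
}

#' Game configuration
#'
#' Bundles the point table, stake ladder and column-placement policy used
#' by the round simulator.
#'
#' @param table a [point_table()].
#' @param stakes a [stake_schedule()].
#' @param policy column placement policy: `"random"` (uniform over
#'   non-full slots, emulating undirected mouse play) or `"greedy"`
#'   (maximize immediate completed-line points, emulating keyboard
#'   auto-placement).
#' @return an object of class `game_config`.
#' @export
game_config <- function(table = point_table(), stakes = stake_schedule(),
                        policy = c("random", "greedy")) {
  stopifnot(inherits(table, "point_table"), inherits(stakes, "stake_schedule"))
  policy <- match.arg(policy)
  structure(list(table = table, stakes = stakes, policy = policy),
            class = "game_config")
}

#' Read a game configuration from a JSON file
#'
#' Recognized keys (all optional): `face_values`, `n_bonus_faces`,
#' `win_threshold`, `slot_bonus_points`, `multiplier_3slots`,
#' `multiplier_4slots`, `prize_rate`, `bonus_points_fixed`,
#' `slot_bonus_after_multiplier`, `stake_levels_eur`, `policy`.
#'
#' @param path path to a JSON file.
#' @return a [game_config()].
#' @export
read_game_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab_args <- list()
  if (!is.null(cfg$face_values)) tab_args$values <- cfg$face_values
  for (k in c("n_bonus_faces", "win_threshold", "slot_bonus_points",
              "multiplier_3slots", "multiplier_4slots", "prize_rate",
              "slot_bonus_after_multiplier"))
    if (!is.null(cfg[[k]])) tab_args[[k]] <- cfg[[k]]
  if (!is.null(cfg$bonus_points_fixed)) {
    fixed <- cfg$bonus_points_fixed
    tab_args$bonus_points_fun <- function(n) rep(fixed, n)
  }
  table <- do.call(point_table, tab_args)
  stakes <- if (is.null(cfg$stake_levels_eur)) stake_schedule()
            else stake_schedule(cfg$stake_levels_eur)
  policy <- if (is.null(cfg$policy)) "random" else cfg$policy
  game_config(table = table, stakes = stakes, policy = policy)
}
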