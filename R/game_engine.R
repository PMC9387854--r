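# Round mechanics: a round deals 12 columns of 3 dice (faces i.i.d. uniform
# over the 10 faces); the player files them into 4 slots, 3 columns each.
# A slot scores on each of its 3 rows and 2 diagonals holding 3 identical
# non-bonus faces; 3 bonus faces on a line trigger the bonus mini-game.

# The five scored lines of a 3x3 slot, as (row, column) index pairs.
.slot_lines <- list(
  cbind(r = c(1L, 1L, 1L), c = c(1L, 2L, 3L)),
  cbind(r = c(2L, 2L, 2L), c = c(1L, 2L, 3L)),
  cbind(r = c(3L, 3L, 3L), c = c(1L, 2L, 3L)),
  cbind(r = c(1L, 2L, 3L), c = c(1L, 2L, 3L)),
  cbind(r = c(3L, 2L, 1L), c = c(1L, 2L, 3L)))

#' Score one slot
#'
#' A fully filled slot is a 3x3 grid of faces (each column of the grid is
#' one placed column of dice). Points are awarded for every row or diagonal
#' whose three faces are identical and not the bonus face; the points of a
#' matching line equal the repeated face's value.
#'
#' @param grid 3x3 integer matrix of face identifiers (1..10), columns in
#'   placement order.
#' @param table a [point_table()].
#' @return list with `points`, `bonus_line_count` (lines of three bonus
#'   faces) and `all_nine_same`.
#' @export
score_slot <- function(grid, table = point_table()) {
  if (!is.matrix(grid) || !all(dim(grid) == c(3L, 3L)) || anyNA(grid))
    stop("score_slot() requires a fully filled 3x3 grid")
  pts <- 0
  bonus_lines <- 0L
  for (ln in .slot_lines) {
    f <- grid[ln]
    if (f[1L] == f[2L] && f[2L] == f[3L]) {
      if (f[1L] %in% table$bonus_faces) bonus_lines <- bonus_lines + 1L
      else pts <- pts + table$face_value[f[1L]]
    }
  }
  list(points = pts, bonus_line_count = bonus_lines,
       all_nine_same = length(unique(as.vector(grid))) == 1L)
}

#' Score a full round from its four filled slots
#'
#' Slot points are summed, multiplied by 1.5 when exactly three slots
#' scored points and by 2 when all four did, and the 200-point all-nine
#' bonus is added (by default after the multiplier; the published rules do
#' not fix the order).
#'
#' @param slots list of four filled 3x3 grids.
#' @param table a [point_table()].
#' @return list with `slot_points` (length 4), `total_points`,
#'   `bonus_line_count` and `bonus_triggered`.
#' @export
score_round <- function(slots, table = point_table()) {
  if (!is.list(slots) || length(slots) != 4L)
    stop("score_round() requires a list of 4 slots")
  sc <- lapply(slots, score_slot, table = table)
  slot_points <- vapply(sc, `[[`, numeric(1), "points")
  n_winning <- sum(slot_points > 0)
  mult <- if (n_winning == 4L) table$multiplier_4slots
          else if (n_winning == 3L) table$multiplier_3slots else 1
  any9 <- any(vapply(sc, `[[`, logical(1), "all_nine_same"))
  total <- if (table$slot_bonus_after_multiplier)
    sum(slot_points) * mult + table$slot_bonus_points * any9
  else (sum(slot_points) + table$slot_bonus_points * any9) * mult
  bl <- sum(vapply(sc, `[[`, integer(1), "bonus_line_count"))
  list(slot_points = slot_points, total_points = total,
       bonus_line_count = bl, bonus_triggered = bl > 0L)
}

#' Convert round points into a monetary outcome
#'
#' The stake acts as a multiplier on the point prizes. A round is a win
#' when the total points reach the win threshold; otherwise the gross
#' prize is 0 and the whole stake is lost. The conversion is exact (gross
#' prize is strictly linear in the stake at fixed points); tracking logs
#' record amounts rounded to whole cents.
#'
#' @param total_points total round points (after multipliers and bonuses).
#' @param stake stake in euro; must lie on the stake ladder.
#' @param table a [point_table()].
#' @param stakes a [stake_schedule()].
#' @return list with `gross_prize`, `net_win` (euro) and `is_win`.
#' @export
points_to_prize <- function(total_points, stake, table = point_table(),
                            stakes = stake_schedule()) {
  stake_cents <- round(stake * 100)
  if (length(stake) != 1L || !stake_cents %in% as.integer(stakes))
    stop("stake ", stake, " is not on the stake ladder")
  is_win <- total_points >= table$win_threshold
  gross <- if (is_win) total_points * table$prize_rate * stake else 0
  list(gross_prize = gross, net_win = gross - stake, is_win = is_win)
}

.slot_fill <- function(grid) sum(!is.na(grid[1L, ]))

#' Choose a slot for the next column
#'
#' `"random"` places the column uniformly over the slots that still have
#' room. `"greedy"` (emulating the keyboard auto-placement) picks the slot
#' maximizing the points of lines completed immediately by this placement
#' (a line can only complete when the slot receives its third column), with
#' ties broken by the lowest slot index.
#'
#' @param policy `"random"` or `"greedy"`.
#' @param partial_slots list of four 3x3 grids with `NA` columns for empty
#'   positions.
#' @param column integer vector of 3 faces.
#' @param table a [point_table()] (used by the greedy policy).
#' @return slot index in 1..4.
#' @export
place_column <- function(policy = c("random", "greedy"), partial_slots, column,
                         table = point_table()) {
  policy <- match.arg(policy)
  fill <- vapply(partial_slots, .slot_fill, integer(1))
  open <- which(fill < 3L)
  if (length(open) == 0L) stop("all slots are full")
  if (policy == "random")
    return(open[floor(stats::runif(1) * length(open)) + 1L])
  gain <- vapply(open, function(s) {
    g <- partial_slots[[s]]
    g[, fill[s] + 1L] <- column
    if (anyNA(g)) 0 else score_slot(g, table)$points
  }, numeric(1))
  open[which.max(gain)]  # which.max takes the first maximum: lowest index
}

# Vectorized scorer for n rounds. faces: n x 36 matrix, entry
# (i, (j-1)*3 + r) = face of die r in dealt column j of round i.
# assign: n x 12 matrix, entry (i, (s-1)*3 + c) = dealt column placed as
# c-th column of slot s. Returns per-round slot points and flags.
score_boards <- function(faces, assign, table = point_table()) {
  n <- nrow(faces)
  idx <- seq_len(n)
  value <- table$face_value
  value[table$bonus_faces] <- 0  # bonus lines score no points directly
  is_bonus <- seq_len(10L) %in% table$bonus_faces
  slot_points <- matrix(0, n, 4L)
  bonus_lines <- matrix(0L, n, 4L)
  all_nine <- matrix(FALSE, n, 4L)
  for (s in 1:4) {
    colj <- assign[, (s - 1L) * 3L + (1:3), drop = FALSE]
    face_at <- function(r, cpos) faces[cbind(idx, (colj[, cpos] - 1L) * 3L + r)]
    row_eq <- vector("list", 3L)
    row_face <- vector("list", 3L)
    for (li in seq_along(.slot_lines)) {
      ln <- .slot_lines[[li]]
      f1 <- face_at(ln[1L, "r"], ln[1L, "c"])
      f2 <- face_at(ln[2L, "r"], ln[2L, "c"])
      f3 <- face_at(ln[3L, "r"], ln[3L, "c"])
      eq <- (f1 == f2) & (f2 == f3)
      bl <- eq & is_bonus[f1]
      slot_points[, s] <- slot_points[, s] + eq * value[f1]
      bonus_lines[, s] <- bonus_lines[, s] + bl
      if (li <= 3L) { row_eq[[li]] <- eq; row_face[[li]] <- f1 }
    }
    all_nine[, s] <- row_eq[[1L]] & row_eq[[2L]] & row_eq[[3L]] &
      (row_face[[1L]] == row_face[[2L]]) & (row_face[[2L]] == row_face[[3L]])
  }
  n_winning <- rowSums(slot_points > 0)
  mult <- 1 + (n_winning == 3L) * (table$multiplier_3slots - 1) +
    (n_winning == 4L) * (table$multiplier_4slots - 1)
  base <- rowSums(slot_points)
  any9 <- rowSums(all_nine) > 0
  total <- if (table$slot_bonus_after_multiplier)
    base * mult + table$slot_bonus_points * any9
  else (base + table$slot_bonus_points * any9) * mult
  list(slot_points = slot_points, total_points = total,
       bonus_triggered = rowSums(bonus_lines) > 0L, all_nine = any9)
}

# Draw n rounds' dice and placements under the configured policy.
# Random: sequential uniform choice among non-full slots, vectorized over
# rounds. Greedy from an empty board degenerates to filling the slots left
# to right (a placement can only complete lines on a slot's third column,
# and zero-gain ties resolve to the lowest index), so no RNG is used for
# greedy placement.
.deal_rounds <- function(n, policy = "random") {
  faces <- matrix(sample.int(10L, n * 36L, replace = TRUE), nrow = n)
  if (policy == "greedy") {
    assign <- matrix(rep(seq_len(12L), each = n), nrow = n)
    return(list(faces = faces, assign = assign))
  }
  idx <- seq_len(n)
  cnt <- matrix(0L, n, 4L)
  assign <- matrix(0L, n, 12L)
  for (j in seq_len(12L)) {
    av <- cnt < 3L
    k <- rowSums(av)
    r <- floor(stats::runif(n) * k) + 1L
    cs1 <- av[, 1L]; cs2 <- cs1 + av[, 2L]; cs3 <- cs2 + av[, 3L]
    slot <- 1L + (r > cs1) + (r > cs2) + (r > cs3)
    flat <- (slot - 1L) * n + idx  # linear index into n x 4 matrices
    pos <- (slot - 1L) * 3L + cnt[flat] + 1L
    assign[(pos - 1L) * n + idx] <- j
    cnt[flat] <- cnt[flat] + 1L
  }
  list(faces = faces, assign = assign)
}

#' Simulate a batch of independent rounds
#'
#' Deals and places `n` rounds under the configured policy and scores
#' them. When a round triggers the bonus mini-game, extra points drawn
#' from the table's bonus distribution are added before the win/loss
#' classification. Uses the global RNG; seed with [set.seed()] for
#' reproducible streams.
#'
#' @param n number of rounds.
#' @param config a [game_config()].
#' @return a `data.table` with columns `total_points` (including any
#'   bonus-game points), `bonus_triggered` and `is_win`.
#' @export
simulate_rounds <- function(n, config = game_config()) {
  n <- as.integer(n)
  stopifnot(n >= 0L, inherits(config, "game_config"))
  if (n == 0L)
    return(data.table::data.table(total_points = numeric(0),
                                  bonus_triggered = logical(0),
                                  is_win = logical(0)))
  dealt <- .deal_rounds(n, config$policy)
  sc <- score_boards(dealt$faces, dealt$assign, config$table)
  total <- sc$total_points
  btrig <- sc$bonus_triggered
  if (any(btrig))
    total[btrig] <- total[btrig] + config$table$bonus_points_fun(sum(btrig))
  data.table::data.table(total_points = total, bonus_triggered = btrig,
                         is_win = total >= config$table$win_threshold)
}

#' Simulate a single round end to end
#'
#' @param stake stake in euro, on the stake ladder.
#' @param config a [game_config()].
#' @return list with `slot_points`, `total_points`, `gross_prize`,
#'   `net_win`, `is_win` and `bonus_triggered`.
#' @export
simulate_round <- function(stake, config = game_config()) {
  dealt <- .deal_rounds(1L, config$policy)
  sc <- score_boards(dealt$faces, dealt$assign, config$table)
  total <- sc$total_points[1L]
  btrig <- sc$bonus_triggered[1L]
  if (btrig) total <- total + config$table$bonus_points_fun(1L)
  prize <- points_to_prize(total, stake, config$table, config$stakes)
  list(slot_points = sc$slot_points[1L, ], total_points = total,
       gross_prize = prize$gross_prize, net_win = prize$net_win,
       is_win = prize$is_win, bonus_triggered = btrig)
}
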