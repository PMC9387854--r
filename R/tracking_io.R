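# Round-level tracking log IO. The on-disk contract is a UTF-8 CSV with
# "." decimals and columns player_id, session_id, round_id,
# round_in_session, stake (euro), win_amount (euro, 0 on a loss),
# start_latency_ms, first_column_rt_ms, bonus (0/1), plus optional
# column_rt_2_ms .. column_rt_12_ms. In memory, money is held as integer
# euro cents (stake_cents, win_cents) so stake-change arithmetic is exact.

.mandatory_csv_cols <- c("player_id", "session_id", "round_id",
                         "round_in_session", "stake", "win_amount",
                         "start_latency_ms", "first_column_rt_ms", "bonus")

.parse_cents <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(v))
  if (length(bad))
    stop(sprintf("column '%s', row %d: non-numeric value '%s'",
                 col, bad[1L], x[bad[1L]]))
  cents <- round(v * 100)
  off <- which(abs(v * 100 - cents) > 1e-6)
  if (length(off))
    stop(sprintf("column '%s', row %d: amount %s is not a whole number of euro cents",
                 col, off[1L], x[off[1L]]))
  as.integer(cents)
}

#' Read a tracking CSV
#'
#' Monetary columns are parsed as exact euro cents; amounts that are not
#' whole cents are rejected. Duplicate (player, session, round-index) keys
#' are rejected.
#'
#' @param path path to a tracking CSV.
#' @return a `data.table` with `stake_cents`/`win_cents` instead of the
#'   euro columns.
#' @export
read_rounds <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("stake", "win_amount")),
                          encoding = "UTF-8")
  missing_cols <- setdiff(.mandatory_csv_cols, names(dt))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) {
    dt[, `:=`(stake_cents = integer(0), win_cents = integer(0))]
    dt[, c("stake", "win_amount") := NULL]
    data.table::setcolorder(dt, c("player_id", "session_id", "round_id",
                                  "round_in_session", "stake_cents", "win_cents"))
    return(dt[])
  }
  dt[, stake_cents := .parse_cents(stake, "stake")]
  dt[, win_cents := .parse_cents(win_amount, "win_amount")]
  dt[, c("stake", "win_amount") := NULL]
  dt[, bonus := as.logical(bonus)]
  dup <- duplicated(dt, by = c("player_id", "session_id", "round_in_session"))
  if (any(dup))
    stop(sprintf("duplicate (player_id, session_id, round_in_session) key at row %d",
                 which(dup)[1L]))
  data.table::setcolorder(dt, c("player_id", "session_id", "round_id",
                                "round_in_session", "stake_cents", "win_cents",
                                "start_latency_ms", "first_column_rt_ms", "bonus"))
  dt[]
}

#' Write a tracking CSV
#'
#' Inverse of [read_rounds()]; cent columns are rendered as euro with two
#' decimals so the write-read round trip is lossless.
#'
#' @param records tracking `data.table` (cents representation).
#' @param path output path.
#' @export
write_rounds <- function(records, path) {
  dt <- data.table::copy(data.table::as.data.table(records))
  dt[, stake := sprintf("%.2f", stake_cents / 100)]
  dt[, win_amount := sprintf("%.2f", win_cents / 100)]
  dt[, c("stake_cents", "win_cents") := NULL]
  dt[, bonus := as.integer(bonus)]
  front <- c("player_id", "session_id", "round_id", "round_in_session",
             "stake", "win_amount", "start_latency_ms", "first_column_rt_ms",
             "bonus")
  data.table::setcolorder(dt, c(front, setdiff(names(dt), front)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Validate tracking records
#'
#' Checks every record-level invariant (positive stakes, non-negative win
#' amounts and latencies, unique keys, strictly increasing round order
#' within sessions) and reports violations instead of throwing.
#'
#' @param records tracking `data.table`.
#' @return a `data.table` report with columns `row`, `column`, `problem`;
#'   zero rows on clean data.
#' @export
validate_rounds <- function(records) {
  dt <- data.table::as.data.table(records)
  rep_rows <- list()
  flag <- function(rows, column, problem) {
    if (length(rows))
      rep_rows[[length(rep_rows) + 1L]] <<-
        data.table::data.table(row = rows, column = column, problem = problem)
  }
  flag(which(is.na(dt$stake_cents) | dt$stake_cents <= 0L),
       "stake_cents", "stake must be > 0")
  flag(which(is.na(dt$win_cents) | dt$win_cents < 0L),
       "win_cents", "win amount must be >= 0")
  flag(which(!is.na(dt$start_latency_ms) & dt$start_latency_ms < 0),
       "start_latency_ms", "latency must be >= 0")
  flag(which(!is.na(dt$first_column_rt_ms) & dt$first_column_rt_ms < 0),
       "first_column_rt_ms", "latency must be >= 0")
  dup <- duplicated(dt, by = c("player_id", "session_id", "round_in_session"))
  flag(which(dup), "round_in_session",
       "duplicate (player_id, session_id, round_in_session) key")
  ooo <- dt[, .I[c(FALSE, diff(round_in_session) <= 0L)],
            by = .(player_id, session_id)]$V1
  flag(ooo, "round_in_session",
       "round order within session must be strictly increasing")
  if (length(rep_rows)) data.table::rbindlist(rep_rows)[order(row)]
  else data.table::data.table(row = integer(0), column = character(0),
                              problem = character(0))
}

#' Split sessions at long response breaks
#'
#' Gamblers may pause without logging off, so operator-defined sessions
#' can span breaks. Any round whose start latency exceeds the threshold
#' (strictly) begins a new session; operator boundaries are preserved
#' (resegmentation only splits, never merges) and round indices are
#' recomputed. Rounds with a missing start latency cannot be assessed and
#' are flagged with a warning (treated as no break).
#'
#' @param records tracking `data.table`.
#' @param gap_threshold_ms break threshold in milliseconds (default
#'   600000, i.e. more than 10 minutes).
#' @return records with new `session_id` (old id plus a `.k` suffix for
#'   the k-th segment, k > 1) and recomputed `round_in_session`.
#' @export
resegment_sessions <- function(records, gap_threshold_ms = 600000) {
  dt <- data.table::copy(data.table::as.data.table(records))
  data.table::setorder(dt, player_id, session_id, round_in_session)
  na_lat <- dt[round_in_session > 1L & is.na(start_latency_ms), which = TRUE]
  if (length(na_lat))
    warning(length(na_lat),
            " round(s) with missing start latency could not be assessed for breaks")
  dt[, `:=`(.new_seg = round_in_session > 1L &
              !is.na(start_latency_ms) & start_latency_ms > gap_threshold_ms)]
  dt[, .seg := cumsum(.new_seg) + 1L, by = .(player_id, session_id)]
  dt[, session_id := ifelse(.seg > 1L,
                            paste0(as.character(session_id), ".", .seg),
                            as.character(session_id))]
  dt[, round_in_session := seq_len(.N), by = .(player_id, session_id)]
  dt[, c(".new_seg", ".seg") := NULL]
  dt[]
}
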