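# End-to-end entry points: simulate a cohort to a tracking CSV, analyze a
# tracking CSV into metric tables and a battery report, or both. Every
# artifact records the seed and a hash of the effective configuration.

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"`, `"analyze"` or `"full"`.
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] (required for simulate/full).
#' @param tracking_path input tracking CSV (required for analyze).
#' @param groups_path CSV with `player_id,group` labels (required for
#'   analyze; simulate writes one).
#' @param min_count,rt_max_ms,gap_threshold_ms facet filter parameters
#'   (defaults 5, 5000 ms, 600000 ms).
#' @param alpha significance level (default 0.05).
#' @param bf_r Bayes-factor prior scale (default `sqrt(2) / 2`).
#' @param resegment apply the break resegmentation to the sessions before
#'   the primary analysis (default `FALSE`).
#' @param sensitivity also rerun the stopping facet on break-resegmented
#'   sessions alongside the primary analysis (default `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir = ".",
                       sim = NULL, tracking_path = NULL, groups_path = NULL,
                       min_count = 5L, rt_max_ms = 5000,
                       gap_threshold_ms = 600000, alpha = 0.05,
                       bf_r = sqrt(2) / 2, resegment = FALSE,
                       sensitivity = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_count > 0, rt_max_ms > 0, gap_threshold_ms > 0,
            alpha > 0, alpha < 1, bf_r > 0)
  if (mode %in% c("simulate", "full") && !inherits(sim, "sim_config"))
    stop("mode '", mode, "' requires a sim_config")
  if (mode == "analyze" && (is.null(tracking_path) || is.null(groups_path)))
    stop("mode 'analyze' requires tracking_path and groups_path")
  structure(list(mode = mode, out_dir = out_dir, sim = sim,
                 tracking_path = tracking_path, groups_path = groups_path,
                 min_count = as.integer(min_count), rt_max_ms = rt_max_ms,
                 gap_threshold_ms = gap_threshold_ms, alpha = alpha,
                 bf_r = bf_r, resegment = isTRUE(resegment),
                 sensitivity = isTRUE(sensitivity)),
            class = "run_config")
}

.write_log <- function(config, path, lines) {
  writeLines(c(paste0("config_hash: ", .config_hash(config)),
               paste0("seed: ", if (!is.null(config$sim)) config$sim$seed else NA),
               paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               lines), path)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Writes `tracking.csv`, `ground_truth.csv`, `groups.csv` and
#' `simulate.log` into the output directory.
#'
#' @param config a [run_config()] with a `sim` component.
#' @return invisibly, a named list of output paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"), inherits(config$sim, "sim_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config$sim)
  paths <- list(tracking = file.path(config$out_dir, "tracking.csv"),
                ground_truth = file.path(config$out_dir, "ground_truth.csv"),
                groups = file.path(config$out_dir, "groups.csv"),
                log = file.path(config$out_dir, "simulate.log"))
  write_rounds(ds$rounds, paths$tracking)
  data.table::fwrite(ds$profiles, paths$ground_truth)
  data.table::fwrite(ds$profiles[, .(player_id, group)], paths$groups)
  .write_log(config, paths$log,
             c(paste0("players: ", nrow(ds$profiles)),
               paste0("rounds: ", nrow(ds$rounds))))
  invisible(paths)
}

#' Analyze a tracking CSV
#'
#' Validates the input (aborting with the validation report on failure),
#' computes the per-player facet tables, the play-behavior summary and
#' the full comparison battery, and writes CSVs plus a markdown report.
#' With `sensitivity = TRUE` the stopping facet is recomputed on sessions
#' resegmented at the break threshold and reported alongside.
#'
#' @param config a [run_config()] with `tracking_path` and `groups_path`.
#' @return invisibly, a list with `metrics`, `batteries`, `summary` and
#'   output paths.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"),
            !is.null(config$tracking_path), !is.null(config$groups_path))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rounds <- read_rounds(config$tracking_path)
  report <- validate_rounds(rounds)
  if (nrow(report)) {
    print(report)
    stop("tracking data failed validation (", nrow(report), " problem(s)); see report above")
  }
  groups <- data.table::fread(config$groups_path,
                              colClasses = list(character = "player_id"))
  if (config$resegment)
    rounds <- resegment_sessions(rounds, config$gap_threshold_ms)
  metrics <- cohort_metrics(rounds, groups, min_count = config$min_count,
                            rt_max_ms = config$rt_max_ms)
  summary_tbl <- play_summary(rounds, groups)
  batteries <- chasing_batteries(metrics, conf = 1 - config$alpha,
                                 bf_r = config$bf_r)
  paths <- list(report = file.path(config$out_dir, "battery_report.md"),
                summary = file.path(config$out_dir, "play_summary.csv"),
                log = file.path(config$out_dir, "analyze.log"))
  for (facet in c("stop", "stake", "speed")) {
    p <- file.path(config$out_dir, paste0("metrics_", facet, ".csv"))
    data.table::fwrite(metrics[[facet]], p)
    paths[[paste0("metrics_", facet)]] <- p
  }
  cmp_all <- data.table::rbindlist(
    lapply(names(batteries),
           function(nm) cbind(facet = nm, batteries[[nm]]$comparisons)))
  data.table::fwrite(cmp_all, file.path(config$out_dir, "battery_comparisons.csv"))
  paths$comparisons <- file.path(config$out_dir, "battery_comparisons.csv")
  data.table::fwrite(summary_tbl, paths$summary)
  md <- c("# Within-session chasing battery", "",
          paste0("Config hash: ", .config_hash(config)), "",
          format_batteries_md(batteries))
  sens <- NULL
  if (config$sensitivity) {
    reseg <- resegment_sessions(rounds, config$gap_threshold_ms)
    sens_metrics <- cohort_metrics(reseg, groups, min_count = config$min_count,
                                   rt_max_ms = config$rt_max_ms)
    sens <- comparison_battery(.facet_tables(sens_metrics)$stop,
                               conf = 1 - config$alpha, bf_r = config$bf_r)
    md <- c(md, "",
            format_batteries_md(
              structure(list(stop_resegmented = sens),
                        class = "chasing_batteries"),
              labels = c(stop_resegmented = "When to stop, sessions split at breaks (sensitivity)")))
  }
  writeLines(md, paths$report)
  .write_log(config, paths$log,
             c(paste0("rounds: ", nrow(rounds)),
               paste0("players: ", length(unique(rounds$player_id)))))
  invisible(list(metrics = metrics, batteries = batteries,
                 summary = summary_tbl, sensitivity = sens, paths = paths))
}

#' Simulate and analyze in one call
#'
#' @param config a [run_config()] with a `sim` component.
#' @return invisibly, the [run_analyze()] result.
#' @export
run_full <- function(config) {
  paths <- run_simulate(config)
  config$tracking_path <- paths$tracking
  config$groups_path <- paths$groups
  run_analyze(config)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `analyze`, `full`; flags `--config` (JSON run
#' configuration; see [read_sim_config()] for the `sim` block), `--seed`,
#' `--out`, `--resegment`, `--sensitivity`. Flags override the config
#' file.
#'
#' @param args character vector (default: the command line).
#' @return invisibly, the subcommand's result.
#' @export
chase_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("chase_cli() requires the optparse package")
  if (length(args) < 1L || !args[1] %in% c("simulate", "analyze", "full"))
    stop("usage: simulate|analyze|full [--config FILE] [--seed N] [--out DIR] ",
         "[--tracking FILE] [--groups FILE] [--sensitivity]")
  mode <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--tracking", type = "character", default = NULL),
    optparse::make_option("--groups", type = "character", default = NULL),
    optparse::make_option("--resegment", action = "store_true", default = FALSE),
    optparse::make_option("--sensitivity", action = "store_true", default = FALSE)))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg_json <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  sim <- NULL
  if (mode %in% c("simulate", "full")) {
    sim_args <- list()
    if (!is.null(opt$config) && !is.null(cfg_json$sim)) {
      tmp <- tempfile(fileext = ".json")
      on.exit(unlink(tmp), add = TRUE)
      jsonlite::write_json(cfg_json$sim, tmp, auto_unbox = TRUE)
      sim <- read_sim_config(tmp)
    } else {
      if (is.null(opt$seed)) stop("simulate/full needs --seed or a config file")
      sim <- sim_config(seed = opt$seed)
    }
    if (!is.null(opt$seed)) sim$seed <- as.integer(opt$seed)
  }
  rc <- run_config(
    mode = mode, out_dir = opt$out, sim = sim,
    tracking_path = opt$tracking %||% cfg_json$tracking_path,
    groups_path = opt$groups %||% cfg_json$groups_path,
    min_count = cfg_json$min_count %||% 5L,
    rt_max_ms = cfg_json$rt_max_ms %||% 5000,
    gap_threshold_ms = cfg_json$gap_threshold_ms %||% 600000,
    alpha = cfg_json$alpha %||% 0.05,
    bf_r = cfg_json$bf_r %||% (sqrt(2) / 2),
    resegment = opt$resegment || isTRUE(cfg_json$resegment),
    sensitivity = opt$sensitivity || isTRUE(cfg_json$sensitivity))
  res <- switch(mode, simulate = run_simulate(rc), analyze = run_analyze(rc),
                full = run_full(rc))
  invisible(res)
}
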