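#' Build and validate a run configuration
#'
#' A single structured configuration drives both pipeline entry points.
#' Accepts a YAML file path or a named list; unspecified fields take the
#' defaults below. Scenario fields (under `scenario:`) are passed to
#' [sim_scenario()] by `cmd_simulate`.
#'
#' @param x YAML file path, named list, or nothing (all defaults).
#' @param ... Named overrides applied after `x`.
#' @return A validated `run_config` list with fields `tweets_csv`,
#'   `records_csv`, `out_dir`, `percentile` (default 95), `denoise_window`
#'   (default 7), `lags` (default 3 and 7), `mode`, `characteristics`,
#'   `correct`, `conf_level`, `seed`, `scenario`.
#' @export
run_config <- function(x = list(), ...) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  cfg <- list(tweets_csv = NULL, records_csv = NULL, out_dir = ".",
              percentile = 95, denoise_window = 7, lags = c(3L, 7L),
              mode = "suicide", characteristics = NULL, correct = FALSE,
              conf_level = 0.95, seed = 1L, scenario = list())
  user <- utils::modifyList(x, list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(cfg, user)
  if (length(cfg$lags) == 0L || any(cfg$lags < 0))
    stop("config: 'lags' must be non-empty, each >= 0", call. = FALSE)
  if (cfg$percentile <= 0 || cfg$percentile >= 100)
    stop("config: 'percentile' must be strictly between 0 and 100", call. = FALSE)
  if (!cfg$mode %in% c("suicide", "unexpected"))
    stop("config: 'mode' must be \"suicide\" or \"unexpected\"", call. = FALSE)
  if (is.null(cfg$characteristics)) cfg$characteristics <- default_characteristics()
  cfg$lags <- as.integer(cfg$lags)
  structure(cfg, class = "run_config")
}

read_tweets_csv <- function(path) {
  if (!file.exists(path)) stop("tweet series file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  miss <- setdiff(c("date", "count"), names(d))
  if (length(miss))
    stop("tweet series CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tweet_series(as.Date(d$date), d$count)
}

#' Simulate a study and write its input files
#'
#' Runs the synthetic-data generator under the configuration's scenario and
#' writes, into `out_dir`: `tweets.csv` (`date,count`), `deaths.csv`
#' (`date,age,sex,occupation,marital_status,area,icd10`; empty fields are
#' missing), and `ground_truth.json` (scenario parameters, injected spike
#' dates, and the true interaction OR per characteristic level). Deaths are
#' generated against the exposure calendar built with the configuration's
#' percentile and denoise window, so a subsequent `cmd_analyze` with the
#' same settings sees the generating exposure.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config = run_config()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  scen_args <- cfg$scenario
  if (!is.null(cfg$seed)) scen_args$seed <- cfg$seed
  scenario <- do.call(sim_scenario, scen_args)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tw <- simulate_tweet_series(scenario)
  calendar <- build_exposure_calendar(tw$series, cfg$percentile, cfg$denoise_window)
  deaths <- simulate_deaths(scenario, calendar)
  paths <- file.path(cfg$out_dir, c(tweets = "tweets.csv", deaths = "deaths.csv",
                                    truth = "ground_truth.json"))
  names(paths) <- c("tweets", "deaths", "truth")
  utils::write.csv(data.frame(date = format(tw$series$date), count = tw$series$count),
                   paths[["tweets"]], row.names = FALSE, quote = FALSE)
  out <- deaths
  out$date <- format(out$death_date)
  out$death_date <- NULL
  out <- out[c("date", "age", "sex", "occupation", "marital_status", "area", "icd10")]
  utils::write.csv(out, paths[["deaths"]], row.names = FALSE, na = "")
  truth <- list(
    scenario = scenario[setdiff(names(scenario), "characteristics")],
    characteristics = lapply(scenario$characteristics, unclass),
    spike_dates = format(tw$spike_dates),
    interaction_or = lapply(ground_truth(scenario), as.list),
    n_tweets = sum(tw$series$count), n_deaths = nrow(deaths))
  truth$scenario$start_date <- format(truth$scenario$start_date)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stopifnot(nrow(utils::read.csv(paths[["deaths"]])) == nrow(deaths))
  message("cmd_simulate: wrote ", nrow(deaths), " death records and ",
          scenario$n_days, " tweet days to ", cfg$out_dir)
  invisible(as.list(paths))
}

# Wide per-lag layout of a run_analysis result (one row per level,
# estimate/CI/significance columns per lag).
estimates_wide <- function(res) {
  lags <- sort(unique(res$lag))
  base <- unique(res[c("characteristic", "level", "reference")])
  for (lag in lags) {
    sub <- res[res$lag == lag, ]
    i <- match(paste(base$characteristic, base$level),
               paste(sub$characteristic, sub$level))
    for (col in c("estimate", "ci_lower", "ci_upper", "p_value", "significant"))
      base[[paste0(col, "_lag", lag)]] <- sub[[col]][i]
  }
  rownames(base) <- NULL
  base
}

#' Plot a count series with surge days marked
#'
#' Line of daily counts with exposed (surge) days overplotted as points.
#'
#' @param series A [tweet_series()].
#' @param calendar Matching exposure calendar.
#' @return A ggplot object.
#' @export
plot_series <- function(series, calendar) {
  d <- data.frame(date = series$date, count = series$count,
                  exposed = calendar_exposure(calendar, series$date))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::geom_point(data = d[!is.na(d$exposed) & d$exposed, ],
                        colour = "red", size = 1) +
    ggplot2::labs(x = NULL, y = "daily count",
                  title = "Daily counts with surge days marked") +
    ggplot2::theme_minimal()
}

#' Analyze tweet and death-record files end to end
#'
#' Reads the configured tweet and records CSVs, builds the exposure
#' calendar, runs the case-only analysis at every configured lag, and
#' writes into `out_dir`: `exposure_summary.csv` (distribution of counts,
#' previous-day differences and ratios), `estimates.csv` (one row per
#' characteristic level, per-lag OR/RRR with CI and significance flag),
#' `run_log.json` (record accounting per reduction step, the ratio
#' threshold, surge-day count), and `series.png` (the series with surge
#' days marked). Every data-reducing step is accounted for: parsed = kept +
#' rejected, cause-selected = analyzed + excluded + merge-dropped, asserted
#' at run time.
#'
#' @param config A [run_config()] with `tweets_csv` and `records_csv` set.
#' @return Invisibly, a list with the estimates (long and wide), the run
#'   log, and output paths.
#' @export
cmd_analyze <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(cfg$tweets_csv) || is.null(cfg$records_csv))
    stop("config must set 'tweets_csv' and 'records_csv'", call. = FALSE)
  series <- read_tweets_csv(cfg$tweets_csv)
  records <- parse_records(cfg$records_csv)
  parse_report <- attr(records, "parse_report")
  calendar <- build_exposure_calendar(series, cfg$percentile, cfg$denoise_window)
  denoised <- denoise(series, cfg$denoise_window)
  res <- run_analysis(records, calendar, lags = cfg$lags,
                      characteristics = cfg$characteristics, mode = cfg$mode,
                      correct = cfg$correct, conf_level = cfg$conf_level)
  alog <- attr(res, "analysis_log")
  # exclusion accounting: every parsed record is analyzed or counted dropped
  for (lag in names(alog$merge)) {
    m <- alog$merge[[lag]]
    stopifnot(alog$n_cause ==
                m$n_kept + m$n_dropped + sum(alog$exclusions$dropped))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(cfg$out_dir, c("exposure_summary.csv", "estimates.csv",
                                    "run_log.json", "series.png"))
  names(paths) <- c("summary", "estimates", "log", "plot")
  utils::write.csv(summarize_series(denoised), paths[["summary"]], row.names = FALSE)
  wide <- estimates_wide(res)
  utils::write.csv(wide, paths[["estimates"]], row.names = FALSE)
  log <- list(
    records_read = parse_report$n_read,
    records_parsed = parse_report$n_ok,
    records_rejected = parse_report$n_read - parse_report$n_ok,
    mode = alog$mode,
    records_in_cause = alog$n_cause,
    excluded = as.list(alog$exclusions$dropped),
    merge = alog$merge,
    ratio_threshold = attr(calendar, "threshold"),
    percentile = attr(calendar, "percentile"),
    surge_days = sum(calendar$exposed, na.rm = TRUE),
    undefined_days = sum(is.na(calendar$exposed)))
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p <- plot_series(series, calendar)
  ggplot2::ggsave(paths[["plot"]], p, width = 9, height = 3.2, dpi = 150)
  message("cmd_analyze: ", log$records_in_cause, " ", alog$mode, " records, ",
          "threshold ", format(log$ratio_threshold, digits = 4), ", ",
          log$surge_days, " surge days; wrote ", cfg$out_dir)
  invisible(list(estimates = res, estimates_wide = wide, log = log,
                 paths = as.list(paths)))
}
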