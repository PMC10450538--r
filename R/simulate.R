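#' Simulate a daily exposure-post count series
#'
#' Draws one count per day as `round(tweet_baseline * lognormal noise *
#' spike multiplier)`, where a day is an injected spike with probability
#' `spike_prob` and its multiplier is uniform on `spike_multiplier_range`.
#' The set of injected spike dates is returned as ground truth for
#' surge-recall checks.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed for the tweet substream; defaults to the scenario's
#'   master seed.
#' @return List with `series` (a [tweet_series()] of `date`, `count`) and
#'   `spike_dates` (Date vector of injected spikes).
#' @export
simulate_tweet_series <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- scenario$n_days
  dates <- scenario$start_date + seq_len(n) - 1L
  set.seed(substream_seed(seed, 1L))
  spiked <- stats::runif(n) < scenario$spike_prob
  mult <- rep(1, n)
  if (any(spiked))
    mult[spiked] <- stats::runif(sum(spiked), scenario$spike_multiplier_range[1],
                                 scenario$spike_multiplier_range[2])
  noise <- exp(stats::rnorm(n, 0, scenario$tweet_noise_sd))
  counts <- pmax(0, round(scenario$tweet_baseline * noise * mult))
  list(series = tweet_series(dates, counts), spike_dates = dates[spiked])
}

# Joint strata over all characteristics: level labels per characteristic plus
# the summed log proportion, main effect and interaction of each stratum.
stratum_grid <- function(characteristics) {
  if (length(characteristics) == 0L)
    return(list(labels = data.frame(row.names = 1L), log_p = 0, b2 = 0, b3 = 0))
  idx <- expand.grid(lapply(characteristics, function(ch) seq_along(ch$levels)),
                     KEEP.OUT.ATTRS = FALSE)
  names(idx) <- vapply(characteristics, `[[`, character(1), "name")
  labels <- as.data.frame(Map(function(ch, i) ch$levels[i], characteristics, idx),
                          optional = TRUE)
  names(labels) <- names(idx)
  pick <- function(field) {
    rowSums(mapply(function(ch, i) ch[[field]][i], characteristics, idx))
  }
  lp <- rowSums(mapply(function(ch, i) log(ch$proportions)[i], characteristics, idx))
  list(labels = labels, log_p = lp, b2 = pick("beta2"), b3 = pick("beta3"))
}

# Shared day-level log-rate components (no stratum terms): seasonal sinusoid,
# weekday offsets, and the lagged surge exposure indicator (NA exposure -> 0,
# which only affects the first exposure_lag + 1 days of the span).
day_terms <- function(scenario, calendar) {
  dates <- scenario$start_date + seq_len(scenario$n_days) - 1L
  missing <- setdiff(as.character(dates), as.character(calendar$date))
  if (length(missing))
    stop("exposure calendar does not cover the scenario span; missing dates: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
         call. = FALSE)
  t0 <- seq_len(scenario$n_days) - 1L
  seasonal <- scenario$seasonal_amplitude *
    sin(2 * pi * t0 / scenario$seasonal_period_days)
  wd <- scenario$weekday_effects[as.POSIXlt(dates)$wday + 1L]
  e <- calendar_exposure(calendar, dates - scenario$exposure_lag)
  e[is.na(e)] <- FALSE
  list(dates = dates, shared = seasonal + wd, exposure = as.numeric(e))
}

#' Simulate individual death records from the Poisson interaction model
#'
#' For each day t and joint characteristic stratum j, a death count is drawn
#' from Poisson with log mean
#' `beta0 + log p_j + beta2_j + seasonal(t) + weekday(t) + (beta1 + beta3_j) E(t)`,
#' then exploded into one record per death carrying the stratum's attributes
#' and an ICD-10 code drawn uniformly from the suicide range (X60-X84). If
#' the scenario enables `sensitivity_stream`, a parallel stream of
#' non-suicide external-cause deaths (codes in W00-X59 and Y01-Y59) is drawn
#' from the same model with every `beta3` forced to 0 — the null stream used
#' by the sensitivity analysis. `E(t)` is the calendar's exposure at
#' `exposure_lag` days before t (undefined exposure treated as unexposed).
#'
#' Characteristics not present in the scenario are filled with fixed default
#' values so every record has the full column set. The `age_group`
#' characteristic is materialized as an integer `age` (young: 10-40, old:
#' 41-98); age and occupation are set to missing with the scenario's small
#' missingness probabilities.
#'
#' @param scenario A [sim_scenario()].
#' @param calendar An [exposure_calendar][classify_surge] covering the span.
#' @param seed Seed for the death substream; defaults to the master seed.
#' @return Data frame of records: `death_date`, `age`, `sex`, `occupation`,
#'   `marital_status`, `area`, `icd10` (written to CSV with the date column
#'   named `date`, the layout [parse_records()] reads back).
#' @export
simulate_deaths <- function(scenario, calendar, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  day <- day_terms(scenario, calendar)
  grid <- stratum_grid(scenario$characteristics)
  set.seed(substream_seed(seed, 2L))
  out <- draw_stream(scenario, day, grid, scenario$beta0, null_interaction = FALSE,
                     icd_prefixes = icd10_prefixes("X60-X84"))
  if (scenario$sensitivity_stream) {
    sens <- draw_stream(scenario, day, grid, scenario$sensitivity_beta0,
                        null_interaction = TRUE,
                        icd_prefixes = icd10_prefixes(c("W00-X59", "Y01-Y59")))
    out <- rbind(out, sens)
  }
  rownames(out) <- NULL
  out
}

draw_stream <- function(scenario, day, grid, beta0, null_interaction, icd_prefixes) {
  n <- scenario$n_days
  s <- length(grid$log_p)
  b3 <- if (null_interaction) rep(0, s) else grid$b3
  log_mu <- (beta0 + day$shared + scenario$beta1 * day$exposure) +
    rep(grid$log_p + grid$b2, each = n) + outer(day$exposure, b3)
  counts <- stats::rpois(n * s, exp(log_mu))
  idx <- rep.int(seq_len(n * s), counts)
  di <- (idx - 1L) %% n + 1L
  si <- (idx - 1L) %/% n + 1L
  m <- length(idx)
  rec <- data.frame(death_date = day$dates[di])
  defaults <- list(sex = "female", occupation = "corporate",
                   marital_status = "married", area = "urban")
  for (col in c("sex", "occupation", "marital_status", "area")) {
    rec[[col]] <- if (col %in% names(grid$labels))
      grid$labels[[col]][si] else rep(defaults[[col]], m)
  }
  rec$age <- if ("age_group" %in% names(grid$labels)) {
    young <- grid$labels$age_group[si] == "young"
    ifelse(young, sample(10:40, m, replace = TRUE), sample(41:98, m, replace = TRUE))
  } else rep(50L, m)
  if (scenario$missing_age_prob > 0)
    rec$age[stats::runif(m) < scenario$missing_age_prob] <- NA_integer_
  if (scenario$missing_occupation_prob > 0)
    rec$occupation[stats::runif(m) < scenario$missing_occupation_prob] <- NA_character_
  prefix <- sample(icd_prefixes, m, replace = TRUE)
  fourth <- ifelse(stats::runif(m) < 0.3, as.character(sample(0:9, m, replace = TRUE)), "")
  rec$icd10 <- paste0(prefix, fourth)
  rec[c("death_date", "age", "sex", "occupation", "marital_status", "area", "icd10")]
}

#' Analytic expected total deaths of a scenario
#'
#' Sums `exp(log mean)` over every day and stratum of the suicide stream:
#' the exact expectation of the simulated total, used to validate the
#' generator by Monte Carlo.
#'
#' @inheritParams simulate_deaths
#' @return Expected total number of suicide records.
#' @export
expected_total_deaths <- function(scenario, calendar) {
  day <- day_terms(scenario, calendar)
  grid <- stratum_grid(scenario$characteristics)
  n <- scenario$n_days
  log_mu <- (scenario$beta0 + day$shared + scenario$beta1 * day$exposure) +
    rep(grid$log_p + grid$b2, each = n) + outer(day$exposure, grid$b3)
  sum(exp(log_mu))
}
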