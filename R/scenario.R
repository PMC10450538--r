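#' Define a personal characteristic for the generating model
#'
#' A characteristic is a categorical attribute of a death record (sex, area,
#' occupation, ...) with a designated reference level, population level
#' proportions, and per-level coefficients of the Poisson generating model:
#' `beta2` (log rate ratio of the level's main effect) and `beta3` (log ratio
#' of the level x surge interaction, the quantity the case-only design
#' estimates).
#'
#' @param name Character scalar; also the column name in generated records
#'   (the special name `"age_group"` is written out as an integer `age`
#'   column instead, see [simulate_deaths()]).
#' @param levels Character vector of level labels, length >= 2.
#' @param reference Reference level; must be one of `levels`. Its `beta2` and
#'   `beta3` are fixed at 0.
#' @param proportions Population proportions per level, summing to 1.
#' @param beta2,beta3 Named numeric vectors of coefficients for non-reference
#'   levels (missing levels default to 0), or a single 0.
#' @return An object of class `surge_characteristic`.
#' @examples
#' characteristic("sex", c("female", "male"), reference = "female",
#'                proportions = c(0.5, 0.5), beta3 = c(male = log(1.25)))
#' @export
characteristic <- function(name, levels, reference = levels[1],
                           proportions = rep(1 / length(levels), length(levels)),
                           beta2 = 0, beta3 = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(levels) || length(levels) < 2L || anyDuplicated(levels))
    stop("characteristic '", name, "': 'levels' must be >= 2 distinct labels", call. = FALSE)
  if (length(reference) != 1L || !reference %in% levels)
    stop("characteristic '", name, "': 'reference' must be exactly one of 'levels'", call. = FALSE)
  if (length(proportions) != length(levels) || any(proportions < 0))
    stop("characteristic '", name, "': 'proportions' must be non-negative, one per level", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("characteristic '", name, "': 'proportions' must sum to 1 (got ",
         format(sum(proportions), digits = 15), ")", call. = FALSE)
  expand_beta <- function(b, what) {
    out <- stats::setNames(rep(0, length(levels)), levels)
    if (identical(b, 0) || length(b) == 0L) return(out)
    if (is.null(names(b)) || !all(names(b) %in% levels))
      stop("characteristic '", name, "': '", what, "' must be named by level", call. = FALSE)
    if (any(names(b) == reference) && any(b[names(b) == reference] != 0))
      stop("characteristic '", name, "': '", what, "' of the reference level must be 0", call. = FALSE)
    out[names(b)] <- b
    out
  }
  structure(
    list(name = name, levels = levels, reference = reference,
         proportions = stats::setNames(as.numeric(proportions), levels),
         beta2 = expand_beta(beta2, "beta2"),
         beta3 = expand_beta(beta3, "beta3")),
    class = "surge_characteristic")
}

#' Study-scale default characteristic set for simulation
#'
#' Five characteristics emulating the structure of Japanese vital-statistics
#' suicide records: binary age group (40 or younger vs older), sex, a
#' five-level occupation, marital status (including a small "other" class
#' that the analysis excludes), and urban/rural area. Interaction
#' coefficients default to plausible effect-modification magnitudes of the
#' order reported in case-only studies of media-linked suicide (ORs between
#' 0.83 and 1.26).
#'
#' @return List of [characteristic()] objects.
#' @export
study_characteristics <- function() {
  list(
    characteristic("age_group", c("old", "young"), reference = "old",
                   proportions = c(0.65, 0.35),
                   beta3 = c(young = log(1.09))),
    characteristic("sex", c("female", "male"), reference = "female",
                   proportions = c(0.5, 0.5),
                   beta2 = c(male = log(2.0)),
                   beta3 = c(male = log(1.12))),
    characteristic("occupation",
                   c("self-employed", "agriculture", "corporate", "other", "unemployed"),
                   reference = "self-employed",
                   proportions = c(0.10, 0.05, 0.35, 0.20, 0.30),
                   beta3 = c(unemployed = log(1.12))),
    characteristic("marital_status",
                   c("married", "unmarried", "widowed", "divorced", "other"),
                   reference = "married",
                   proportions = c(0.44, 0.30, 0.10, 0.13, 0.03),
                   beta3 = c(widowed = log(0.83), divorced = log(1.11))),
    characteristic("area", c("rural", "urban"), reference = "rural",
                   proportions = c(0.4, 0.6),
                   beta3 = c(urban = log(1.26)))
  )
}

#' Parameterize a synthetic study scenario
#'
#' Bundles every parameter of the generating model: the Poisson death-count
#' model (baseline, surge main effect, per-characteristic main effects and
#' interactions, a shared sinusoidal seasonal term plus weekday offsets), the
#' tweet-count process (lognormal multiplicative noise with injected spike
#' days), and bookkeeping (span, lag at which deaths respond to exposure,
#' seed). Defaults emulate the 2011-2014 study span: 1461 days, ~159,000
#' suicide deaths (~109/day), ~115,000 other unexpected deaths, and ~1920
#' exposure-related posts per day.
#'
#' The daily death count in stratum j is Poisson with log mean
#' `beta0 + log p_j + beta2_j + seasonal(t) + weekday(t) + (beta1 + beta3_j) E(t)`,
#' where `E(t)` is surge exposure at lag `exposure_lag` before day t and
#' `p_j` the stratum's population proportion, so `exp(beta0)` is the expected
#' total daily count at baseline.
#'
#' @param n_days Number of calendar days (>= 2).
#' @param start_date First calendar date.
#' @param beta0 Baseline log expected total daily suicide count.
#' @param beta1 Log rate ratio of the surge main effect.
#' @param characteristics List of [characteristic()] definitions.
#' @param seasonal_amplitude Amplitude of the shared sinusoid on the log scale.
#' @param seasonal_period_days Period of the sinusoid in days.
#' @param weekday_effects Numeric length 7, log-scale offsets Sunday..Saturday.
#' @param tweet_baseline Mean daily tweet count.
#' @param tweet_noise_sd Lognormal multiplicative noise SD (log scale).
#' @param spike_prob Per-day probability of an injected spike.
#' @param spike_multiplier_range Length-2 range of multiplicative spike sizes.
#' @param exposure_lag Days between a surge day and the deaths it modifies.
#' @param sensitivity_stream If `TRUE`, [simulate_deaths()] also emits a
#'   non-suicide death stream with all interactions set to 0.
#' @param sensitivity_beta0 Baseline log expected daily count of that stream.
#' @param missing_age_prob,missing_occupation_prob Per-record probabilities
#'   of missing age/occupation, exercising the exclusion rules downstream.
#' @param seed Integer master seed; independent substreams are derived from
#'   it for the tweet and death processes.
#' @return An object of class `sim_scenario`.
#' @seealso [simulate_tweet_series()], [simulate_deaths()], [ground_truth()]
#' @export
sim_scenario <- function(n_days = 1461L,
                         start_date = as.Date("2011-01-01"),
                         beta0 = log(159490 / 1461),
                         beta1 = log(1.05),
                         characteristics = study_characteristics(),
                         seasonal_amplitude = 0.2,
                         seasonal_period_days = 365.25,
                         weekday_effects = c(0.02, 0.04, 0, -0.01, -0.02, 0, -0.03),
                         tweet_baseline = 1920,
                         tweet_noise_sd = 0.15,
                         spike_prob = 0.02,
                         spike_multiplier_range = c(3, 6),
                         exposure_lag = 3L,
                         sensitivity_stream = FALSE,
                         sensitivity_beta0 = log(115072 / 1461),
                         missing_age_prob = 0.002,
                         missing_occupation_prob = 0.002,
                         seed = 1L) {
  fail <- function(field, why) stop("invalid scenario: '", field, "' ", why, call. = FALSE)
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 2) fail("n_days", "must be >= 2")
  start_date <- as.Date(start_date)
  if (is.na(start_date)) fail("start_date", "must be a valid date")
  for (f in c("beta0", "beta1", "seasonal_amplitude", "seasonal_period_days",
              "sensitivity_beta0"))
    if (!is.numeric(get(f)) || length(get(f)) != 1L || !is.finite(get(f)))
      fail(f, "must be a finite number")
  if (seasonal_period_days <= 0) fail("seasonal_period_days", "must be positive")
  if (length(weekday_effects) != 7L || !is.numeric(weekday_effects))
    fail("weekday_effects", "must be numeric of length 7 (Sunday..Saturday)")
  if (!is.numeric(tweet_baseline) || tweet_baseline <= 0) fail("tweet_baseline", "must be positive")
  if (!is.numeric(tweet_noise_sd) || tweet_noise_sd < 0) fail("tweet_noise_sd", "must be >= 0")
  if (!is.numeric(spike_prob) || spike_prob < 0 || spike_prob > 1)
    fail("spike_prob", "must be in [0, 1]")
  if (length(spike_multiplier_range) != 2L || any(spike_multiplier_range <= 0) ||
      diff(spike_multiplier_range) < 0)
    fail("spike_multiplier_range", "must be two positive values, low <= high")
  if (!is.numeric(exposure_lag) || exposure_lag < 0) fail("exposure_lag", "must be >= 0")
  for (f in c("missing_age_prob", "missing_occupation_prob"))
    if (!is.numeric(get(f)) || get(f) < 0 || get(f) > 1) fail(f, "must be in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) fail("seed", "must be an integer")
  if (!is.list(characteristics) ||
      !all(vapply(characteristics, inherits, logical(1), "surge_characteristic")))
    fail("characteristics", "must be a list of characteristic() objects")
  nm <- vapply(characteristics, `[[`, character(1), "name")
  if (anyDuplicated(nm)) fail("characteristics", "must have distinct names")
  structure(
    list(n_days = as.integer(n_days), start_date = start_date,
         beta0 = beta0, beta1 = beta1, characteristics = characteristics,
         seasonal_amplitude = seasonal_amplitude,
         seasonal_period_days = seasonal_period_days,
         weekday_effects = as.numeric(weekday_effects),
         tweet_baseline = tweet_baseline, tweet_noise_sd = tweet_noise_sd,
         spike_prob = spike_prob,
         spike_multiplier_range = as.numeric(spike_multiplier_range),
         exposure_lag = as.integer(exposure_lag),
         sensitivity_stream = isTRUE(sensitivity_stream),
         sensitivity_beta0 = sensitivity_beta0,
         missing_age_prob = missing_age_prob,
         missing_occupation_prob = missing_occupation_prob,
         seed = as.integer(seed)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Synthetic case-only scenario\n")
  cat("  span: ", x$n_days, " days from ", format(x$start_date), "\n", sep = "")
  cat("  baseline exp(beta0): ", format(exp(x$beta0), digits = 4),
      " deaths/day; surge main effect exp(beta1): ",
      format(exp(x$beta1), digits = 4), "\n", sep = "")
  cat("  characteristics:",
      paste(vapply(x$characteristics, `[[`, character(1), "name"), collapse = ", "), "\n")
  cat("  exposure lag for generation:", x$exposure_lag, "days\n")
  if (x$sensitivity_stream) cat("  plus a null-interaction non-suicide stream\n")
  invisible(x)
}

#' True interaction odds ratios of a scenario
#'
#' Returns `exp(beta3)` for every level of every characteristic (1 for the
#' reference level): the ground truth the case-only estimator targets.
#'
#' @param scenario A [sim_scenario()].
#' @return Named list (one element per characteristic) of named numeric
#'   vectors of interaction ORs per level.
#' @examples
#' sc <- sim_scenario(characteristics = list(
#'   characteristic("sex", c("female", "male"), beta3 = c(male = log(1.25)))))
#' ground_truth(sc)$sex[["male"]]  # 1.25
#' @export
ground_truth <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  out <- lapply(scenario$characteristics, function(ch) exp(ch$beta3))
  stats::setNames(out, vapply(scenario$characteristics, `[[`, character(1), "name"))
}

# Deterministic substream seeds: one master seed drives independent streams
# for tweets and deaths, so toggling one component does not perturb the other.
substream_seed <- function(seed, stream) {
  (abs(as.numeric(seed)) %% 65011 * 33013 + stream * 7919 + 104729) %% 2147483647
}
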