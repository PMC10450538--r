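# Shared fixture builders. Everything is generated in code at test time.

# Single binary characteristic (sex) at study scale: 1461 days, ~159k
# records; exposure applied at lag 0 so estimation and generation use the
# same dates unless a lag is requested.
binary_scenario <- function(or = 1.25, seed = 1, ...) {
  args <- list(
    characteristics = list(
      characteristic("sex", c("female", "male"), reference = "female",
                     proportions = c(0.5, 0.5), beta3 = c(male = log(or)))),
    exposure_lag = 0L, missing_age_prob = 0, missing_occupation_prob = 0,
    seed = seed)
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

# Small, fast scenario for file-level and smoke tests.
small_scenario_args <- function(...) {
  utils::modifyList(
    list(n_days = 240L, beta0 = log(40), tweet_baseline = 500,
         spike_prob = 0.03, seed = 7L),
    list(...))
}

# One simulated replicate of the binary scenario pushed through the
# case-only pipeline; returns the binary interaction estimate row.
sim_binary_estimate <- function(scenario, lag = scenario$exposure_lag,
                                percentile = 95, denoise_window = 0) {
  tw <- simulate_tweet_series(scenario)
  cal <- build_exposure_calendar(tw$series, percentile, denoise_window)
  deaths <- simulate_deaths(scenario, cal)
  rows <- merge_with_lag(deaths, cal, lag)
  tab <- crosstab(rows, char_spec("sex", c("female", "male"), reference = "female"))
  caseonly_or_binary(tab)
}

# Random all-positive 2 x J case-only table.
random_table <- function(J, lo = 5, hi = 5000) {
  counts <- matrix(stats::rpois(2 * J, exp(stats::runif(2 * J, log(lo), log(hi)))) + 1,
                   nrow = 2, dimnames = list(NULL, paste0("L", seq_len(J))))
  caseonly_table(counts, name = "x", reference = "L1")
}

# Exact nearest-rank index via integer arithmetic (independent of the
# implementation's rounding guards).
exact_rank <- function(p, n) (p * n + 99L) %/% 100L
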