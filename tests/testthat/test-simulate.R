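test_that("noise-free spikeless tweet series is constant at baseline", {
  sc <- binary_scenario(n_days = 50L, tweet_noise_sd = 0, spike_prob = 0)
  tw <- simulate_tweet_series(sc)
  expect_equal(tw$series$count, rep(sc$tweet_baseline, 50))
  expect_length(tw$spike_dates, 0)
})

test_that("identical scenario and seed give identical outputs", {
  sc <- binary_scenario(seed = 11, n_days = 120L, beta0 = log(30))
  a <- simulate_tweet_series(sc)
  b <- simulate_tweet_series(sc)
  expect_identical(a, b)
  cal <- build_exposure_calendar(a$series)
  expect_identical(simulate_deaths(sc, cal), simulate_deaths(sc, cal))
})

test_that("tweet substream is independent of the death substream", {
  sc <- binary_scenario(seed = 11, n_days = 120L, beta0 = log(30))
  cal <- build_exposure_calendar(simulate_tweet_series(sc)$series)
  invisible(simulate_deaths(sc, cal))  # consuming death RNG ...
  expect_identical(simulate_tweet_series(sc),  # ... leaves tweets unchanged
                   simulate_tweet_series(sc))
})

test_that("spike-day count concentrates around spike_prob * n_days", {
  # Binomial(1000, 0.05): [30, 70] holds for all but ~1e-3 of seeds
  sc <- binary_scenario(seed = 5, n_days = 1000L, spike_prob = 0.05)
  tw <- simulate_tweet_series(sc)
  expect_gte(length(tw$spike_dates), 30)
  expect_lte(length(tw$spike_dates), 70)
})

test_that("with all betas zero, equal strata split evenly", {
  sc <- binary_scenario(or = 1, seed = 2, beta1 = 0)
  tw <- simulate_tweet_series(sc)
  cal <- build_exposure_calendar(tw$series)
  d <- simulate_deaths(sc, cal)
  m <- sum(d$sex == "male")
  expect_gt(stats::binom.test(m, nrow(d), 0.5)$p.value, 0.001)
})

test_that("without exposed days, beta1 and beta3 never matter", {
  sc1 <- binary_scenario(or = 4, seed = 9, n_days = 90L, beta0 = log(20),
                         beta1 = log(3))
  sc2 <- binary_scenario(or = 1, seed = 9, n_days = 90L, beta0 = log(20),
                         beta1 = 0)
  cal <- build_exposure_calendar(simulate_tweet_series(sc1)$series)
  cal$exposed[] <- FALSE
  expect_identical(simulate_deaths(sc1, cal), simulate_deaths(sc2, cal))
})

test_that("a calendar gap is a fatal error listing missing dates", {
  sc <- binary_scenario(seed = 3, n_days = 60L)
  cal <- build_exposure_calendar(simulate_tweet_series(sc)$series)
  expect_error(simulate_deaths(sc, cal[-c(30, 31), ]), "2011-01-30")
})

test_that("simulated totals match the analytic expectation", {
  sc0 <- binary_scenario(seed = 1, n_days = 150L, beta0 = log(25),
                         seasonal_amplitude = 0.3, beta1 = log(1.3))
  cal <- build_exposure_calendar(simulate_tweet_series(sc0)$series)
  mu <- expected_total_deaths(sc0, cal)
  totals <- vapply(1:100, function(i) {
    nrow(simulate_deaths(binary_scenario(seed = 1000 + i, n_days = 150L,
                                         beta0 = log(25),
                                         seasonal_amplitude = 0.3,
                                         beta1 = log(1.3)), cal))
  }, numeric(1))
  # total is Poisson(mu): compare the MC mean within 3 MC standard errors
  expect_lt(abs(mean(totals) - mu), 3 * sqrt(mu / 100))
})

test_that("realized cross-product OR centers on exp(beta3)", {
  log_ors <- vapply(1:200, function(i) {
    sc <- binary_scenario(or = 1.25, seed = 2000 + i, n_days = 400L,
                          beta0 = log(60))
    log(sim_binary_estimate(sc)$estimate)
  }, numeric(1))
  se <- stats::sd(log_ors) / sqrt(200)
  expect_lt(abs(mean(log_ors) - log(1.25)), 3 * se + 0.005)
})

test_that("sensitivity stream has null interactions and non-suicide codes", {
  log_ors <- vapply(1:100, function(i) {
    sc <- binary_scenario(or = 1.25, seed = 3000 + i,
                          sensitivity_stream = TRUE)
    tw <- simulate_tweet_series(sc)
    cal <- build_exposure_calendar(tw$series)
    d <- simulate_deaths(sc, cal)
    sens <- select_cause(d, "unexpected")
    expect_false(any(icd10_in_range(sens$icd10, "X60-X84")))
    rows <- merge_with_lag(sens, cal, 0)
    tab <- crosstab(rows, char_spec("sex", c("female", "male")))
    log(caseonly_or_binary(tab)$estimate)
  }, numeric(1))
  expect_lt(abs(mean(log_ors)), 0.02)
})
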