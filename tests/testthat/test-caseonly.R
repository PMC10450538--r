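rows_from_cells <- function(counts, levels) {
  # explode a 2 x J count matrix into analysis rows
  e <- rep(c(FALSE, TRUE), ncol(counts))
  l <- rep(levels, each = 2)
  n <- as.vector(counts)
  data.frame(exposed = rep(e, n), lvl = rep(l, n))
}

test_that("crosstab counts cells exactly and conserves the total", {
  spec <- char_spec("sex", c("female", "male"), column = "lvl")
  rows <- data.frame(exposed = c(FALSE, FALSE, TRUE, TRUE),
                     lvl = c("female", "male", "female", "male"))
  tab <- crosstab(rows, spec)
  expect_true(all(tab$counts == 1))

  empty <- crosstab(rows[0, ], spec)
  expect_true(all(empty$counts == 0))

  spec3 <- char_spec("occ", c("a", "b", "c"), column = "lvl")
  counts <- matrix(c(7, 2, 11, 3, 5, 1), 2)
  rows <- rows_from_cells(counts, c("a", "b", "c"))
  tab <- crosstab(rows[sample(nrow(rows)), ], spec3)
  expect_equal(unname(tab$counts), counts)
  expect_equal(sum(tab$counts), nrow(rows))

  expect_error(crosstab(data.frame(exposed = TRUE, lvl = "x"), spec3), "not in spec")
  expect_error(crosstab(data.frame(exposed = NA, lvl = "a"), spec3), "defined")
})

test_that("binary case-only OR matches the cross-product and hand Wald CI", {
  tab <- caseonly_table(matrix(c(40, 5, 20, 10), 2,
                               dimnames = list(NULL, c("female", "male"))))
  est <- caseonly_or_binary(tab)
  expect_equal(est$estimate, 4.0)
  se <- sqrt(1 / 40 + 1 / 20 + 1 / 5 + 1 / 10)
  z <- qnorm(0.975)
  expect_equal(est$se_log, se)
  expect_equal(est$ci_lower, exp(log(4) - z * se))
  expect_equal(est$ci_upper, exp(log(4) + z * se))
  expect_lt(est$ci_lower, est$estimate)
  expect_gt(est$ci_upper, est$estimate)

  flat <- caseonly_table(matrix(rep(25, 4), 2, dimnames = list(NULL, c("f", "m"))))
  est <- caseonly_or_binary(flat)
  expect_equal(est$estimate, 1.0)
  expect_true(est$ci_lower < 1 && est$ci_upper > 1)
})

test_that("zero cells fail loudly unless continuity correction is requested", {
  tab <- caseonly_table(matrix(c(40, 0, 20, 10), 2,
                               dimnames = list(NULL, c("f", "m"))))
  expect_error(caseonly_or_binary(tab), "zero cell")
  est <- caseonly_or_binary(tab, correct = TRUE)
  expect_equal(est$estimator, "closed_form_corrected")
  expect_equal(est$estimate, (10.5 * 40.5) / (0.5 * 20.5))
  expect_error(caseonly_rrr_multinomial(tab), "zero cell")
  expect_equal(caseonly_rrr_multinomial(tab, correct = TRUE)$estimate,
               est$estimate)
})

test_that("multinomial RRRs match hand cross-products and reduce to the OR", {
  tab <- caseonly_table(
    matrix(c(100, 100, 50, 60, 80, 40), 2,
           dimnames = list(NULL, c("self-employed", "A", "B"))))
  est <- caseonly_rrr_multinomial(tab)
  expect_equal(est$level, c("A", "B"))
  expect_equal(est$estimate, c(1.2, 0.5))
  expect_equal(est$se_log[1], sqrt(1 / 60 + 1 / 50 + 1 / 100 + 1 / 100))

  # J = 2 collapses to the binary case-only OR
  set.seed(3)
  t2 <- random_table(2)
  expect_equal(caseonly_rrr_multinomial(t2)$estimate,
               caseonly_or_binary(t2)$estimate)

  # proportional columns mean independence: every RRR is 1
  prop <- caseonly_table(matrix(c(100, 10, 250, 25, 40, 4), 2,
                                dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(caseonly_rrr_multinomial(prop)$estimate, c(1, 1))

  expect_error(caseonly_rrr_multinomial(tab, base_level = "nope"), "base level")
})

test_that("closed forms agree with an independent multinomial ML fitter", {
  set.seed(8)
  for (i in 1:20) {
    tab <- random_table(sample(2:5, 1))
    est <- caseonly_rrr_multinomial(tab)
    lv <- c(tab$reference, est$level)
    d <- data.frame(lvl = factor(rep(lv, each = 2), levels = lv),
                    e = rep(c(0, 1), length(lv)),
                    w = as.vector(tab$counts[, lv]))
    d$w <- d$w / sum(d$w) * 1e4  # MLE is invariant to weight scale
    fit <- nnet::multinom(lvl ~ e, data = d, weights = d$w, trace = FALSE,
                          maxit = 5000, reltol = 1e-14)
    co <- coef(fit)
    ml <- if (is.matrix(co)) co[est$level, "e"] else co[["e"]]
    expect_equal(log(est$estimate), unname(ml), tolerance = 1e-4)
  }
})

test_that("the saturated Poisson oracle reproduces the case-only OR", {
  tab <- caseonly_table(matrix(c(40, 5, 20, 10), 2,
                               dimnames = list(NULL, c("f", "m"))))
  est <- poisson_oracle(tab)
  expect_equal(est$estimate, 4.0, tolerance = 1e-8)
  expect_equal(est$estimator, "poisson_oracle")

  rows <- rows_from_cells(matrix(c(12, 3, 30, 17), 2), c("f", "m"))
  names(rows)[2] <- "sex"
  spec <- char_spec("sex", c("f", "m"))
  direct <- poisson_oracle(rows, spec)
  closed <- caseonly_or_binary(crosstab(rows, spec))
  expect_equal(log(direct$estimate), log(closed$estimate), tolerance = 1e-8)
})

test_that("run_analysis produces the per-lag, per-level estimate table", {
  sc <- do.call(sim_scenario, small_scenario_args(sensitivity_stream = TRUE))
  tw <- simulate_tweet_series(sc)
  cal <- build_exposure_calendar(tw$series, 95, 7)
  d <- simulate_deaths(sc, cal)

  res <- run_analysis(d, cal, lags = c(3, 7))
  expect_equal(nrow(res), 2 * 10)  # (3 binary + 4 occupation + 3 marital) x 2 lags
  expect_setequal(unique(res$lag), c(3, 7))
  expect_true(all(res$ci_lower <= res$estimate & res$estimate <= res$ci_upper))
  expect_equal(res$significant, res$p_value < 0.05)
  log <- attr(res, "analysis_log")
  expect_equal(log$n_cause + 0, sum(icd10_in_range(d$icd10, "X60-X84")))

  # estimates should sit near their generating values (single seeded run,
  # so allow a generous 4-SE band)
  gt <- ground_truth(sc)
  at_lag <- res[res$lag == sc$exposure_lag, ]
  for (i in seq_len(nrow(at_lag))) {
    truth <- gt[[at_lag$characteristic[i]]][[at_lag$level[i]]]
    expect_lt(abs(log(at_lag$estimate[i]) - log(truth)), 4 * at_lag$se_log[i])
  }

  one <- run_analysis(d, cal, lags = 0,
                      characteristics = list(char_spec("sex", c("female", "male"))))
  expect_equal(nrow(one), 1)

  none <- run_analysis(d, cal, lags = 3, characteristics = list())
  expect_equal(nrow(none), 0)
  expect_true(all(c("characteristic", "estimate", "lag") %in% names(none)))

  sens <- run_analysis(d, cal, lags = 3, mode = "unexpected")
  expect_false(any(icd10_in_range("X60", cause_ranges("unexpected"))))
  expect_equal(nrow(sens), 10)
})
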