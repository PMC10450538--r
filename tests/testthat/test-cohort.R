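write_records_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "date,age,sex,occupation,marital_status,area,icd10"
  writeLines(c(header, rows), path)
  path
}

test_that("well-formed records parse; bad fields are rejected with row numbers", {
  path <- write_records_csv(c(
    "2011-02-01,35,male,corporate,married,urban,X60",
    "2011-02-02,,female,unemployed,divorced,rural,X700",
    "2011-02-03,50,male,,widowed,urban,Y20"))
  rec <- parse_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$death_date, as.Date("2011-02-01") + 0:2)
  expect_true(is.na(rec$age[2]))          # empty age is missing, not invalid
  expect_true(is.na(rec$occupation[3]))   # empty occupation likewise

  path <- write_records_csv(c(
    "2011-02-01,35,male,corporate,married,urban,ZZZ",
    "2011-02-02,200,female,corporate,married,urban,X60",
    "2011-02-03,40,male,corporate,married,urban,X61"))
  expect_message(rec <- parse_records(path), "rejected 2")
  expect_equal(nrow(rec), 1)
  rep <- attr(rec, "parse_report")
  expect_equal(rep$n_read, 3)
  expect_setequal(rep$rejected$row, c(1, 2))
  expect_setequal(rep$rejected$field, c("icd10", "age"))
})

test_that("a missing required column is fatal and named", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("date,age,sex", "2011-01-01,40,male"), path)
  expect_error(parse_records(path), "occupation")
})

test_that("ICD-10 range membership compares 3-character prefixes", {
  expect_true(icd10_in_range("X60", "X60-X84"))
  expect_true(icd10_in_range("X84", "X60-X84"))
  expect_false(icd10_in_range("X85", "X60-X84"))
  expect_true(icd10_in_range("X709", "X60-X84"))  # 4th character ignored
  unexpected <- cause_ranges("unexpected")
  expect_true(icd10_in_range("Y01", unexpected))
  expect_false(icd10_in_range("Y00", unexpected))
  expect_true(icd10_in_range("W00", unexpected))
  expect_false(icd10_in_range("Y60", unexpected))
  expect_error(icd10_in_range("X60", "X6-X84"), "malformed")
  expect_error(icd10_in_range("X60", "X84-X60"), "out of order")
  expect_error(icd10_in_range("6X0", "X60-X84"), "malformed")
})

test_that("cause selection partitions suicide from unexpected deaths", {
  rec <- data.frame(death_date = as.Date("2011-01-01") + 1:5,
                    icd10 = c("X60", "X84", "X85", "W10", "Y01"))
  expect_equal(select_cause(rec, "suicide")$icd10, c("X60", "X84"))
  expect_equal(select_cause(rec, "unexpected")$icd10, c("W10", "Y01"))
  expect_equal(nrow(select_cause(rec[0, ], "suicide")), 0)

  # property: the two modes never overlap and cover only input rows
  set.seed(14)
  codes <- paste0(sample(c("V", "W", "X", "Y"), 300, TRUE),
                  sprintf("%02d", sample(0:99, 300, TRUE)))
  rec <- data.frame(icd10 = codes)
  s <- select_cause(rec, "suicide")$icd10
  u <- select_cause(rec, "unexpected")$icd10
  expect_length(intersect(s, u), 0)
  expect_true(all(c(s, u) %in% codes))
})

test_that("exclusion rules drop exactly missing age/occupation and marital 'other'", {
  rec <- data.frame(
    age = c(30, NA, 40, 50, NA),
    occupation = c("corporate", "corporate", NA, "unemployed", NA),
    marital_status = c("married", "widowed", "married", "other", "other"))
  kept <- apply_exclusions(rec)
  expect_equal(nrow(kept), 1)
  log <- attr(kept, "exclusion_log")
  expect_equal(log$n_in, 5)
  expect_equal(sum(log$dropped), 4)
  expect_equal(log$n_kept + sum(log$dropped), log$n_in)
  expect_equal(unname(log$dropped["missing_age"]), 2)
})

test_that("age binarizes at the 40-or-younger boundary", {
  expect_equal(derive_age_group(c(0, 40, 41, 95)),
               c("young", "young", "old", "old"))
  expect_error(derive_age_group(c(30, NA)), "missing")
})

test_that("lagged merge reads exposure at exactly death date minus lag", {
  ratios <- c(NA, 0.9 + (1:29) * 0.001)  # distinct, one clear surge day
  ratios[22] <- 5
  cal <- classify_surge(ratios, percentile = 97,
                        dates = as.Date("2011-01-01") + 0:29)
  surge_day <- cal$date[which(!is.na(cal$exposed) & cal$exposed)]
  expect_equal(surge_day, as.Date("2011-01-22"))

  rec <- data.frame(death_date = surge_day + c(0, 3, 7, 4),
                    icd10 = "X60")
  m0 <- merge_with_lag(rec, cal, 0)
  expect_equal(m0$exposed, c(TRUE, FALSE, FALSE, FALSE))
  m3 <- merge_with_lag(rec, cal, 3)
  expect_equal(m3$exposed, c(FALSE, TRUE, FALSE, FALSE))
  m7 <- merge_with_lag(rec, cal, 7)
  expect_equal(m7$exposed[3], TRUE)

  # lagged dates before the calendar, or with undefined exposure, are dropped
  early <- data.frame(death_date = as.Date(c("2011-01-02", "2011-01-04",
                                             "2011-01-05")),
                      icd10 = "X60")
  m <- merge_with_lag(early, cal, 3)
  # 01-02 lags outside the calendar; 01-04 lags to day one (undefined ratio)
  expect_equal(nrow(m), 1)
  expect_equal(m$death_date, as.Date("2011-01-05"))
  none <- merge_with_lag(early[1, , drop = FALSE], cal, 3)
  expect_equal(nrow(none), 0)
  log <- attr(m, "merge_log")
  expect_equal(log$n_kept + log$n_dropped, log$n_in)
  expect_error(merge_with_lag(early, cal, -1))
})
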