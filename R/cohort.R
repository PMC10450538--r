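sex_levels <- c("male", "female")
occupation_levels <- c("agriculture", "self-employed", "corporate", "other", "unemployed")
marital_levels <- c("married", "unmarried", "widowed", "divorced", "other")
area_levels <- c("urban", "rural")
icd10_pattern <- "^[A-Z][0-9]{2}[0-9]?$"

#' Parse a death-record CSV into typed records
#'
#' Expects a header with columns `date, age, sex, occupation,
#' marital_status, area, icd10` (dates ISO-8601; empty age/occupation are
#' missing values). Rows with an unparseable field are rejected and listed
#' with their row number in the parse report attached as attribute
#' `parse_report`; a missing required column is a fatal error naming it.
#'
#' @param path CSV file path (or a data frame already in that layout).
#' @return Data frame of records with `death_date` (Date), integer `age`
#'   (NA allowed), and validated character columns; attribute
#'   `parse_report` holds `n_read`, `n_ok` and a `rejected` data frame of
#'   row/field/value triples.
#' @export
parse_records <- function(path) {
  raw <- if (is.data.frame(path)) {
    as.data.frame(lapply(path, as.character))
  } else {
    if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
    utils::read.csv(path, colClasses = "character")
  }
  required <- c("date", "age", "sex", "occupation", "marital_status", "area", "icd10")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("records input is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  death_date <- as.Date(raw$date, format = "%Y-%m-%d")
  age <- suppressWarnings(as.integer(raw$age))
  bad <- list(
    date = is.na(death_date),
    age = !blank(raw$age) & (is.na(age) | age < 0 | age > 130),
    sex = !raw$sex %in% sex_levels,
    occupation = !blank(raw$occupation) & !raw$occupation %in% occupation_levels,
    marital_status = !raw$marital_status %in% marital_levels,
    area = !raw$area %in% area_levels,
    icd10 = !grepl(icd10_pattern, raw$icd10))
  rejected <- do.call(rbind, lapply(names(bad), function(f) {
    i <- which(bad[[f]])
    if (!length(i)) return(NULL)
    data.frame(row = i, field = f, value = raw[[f]][i])
  }))
  if (is.null(rejected))
    rejected <- data.frame(row = integer(), field = character(), value = character())
  ok <- !Reduce(`|`, bad)
  out <- data.frame(
    death_date = death_date[ok],
    age = ifelse(blank(raw$age[ok]), NA_integer_, age[ok]),
    sex = raw$sex[ok],
    occupation = ifelse(blank(raw$occupation[ok]), NA_character_, raw$occupation[ok]),
    marital_status = raw$marital_status[ok],
    area = raw$area[ok],
    icd10 = raw$icd10[ok])
  report <- list(n_read = n, n_ok = sum(ok),
                 rejected = rejected[order(rejected$row), , drop = FALSE])
  if (nrow(rejected))
    message("parse_records: rejected ", length(unique(rejected$row)), " of ", n,
            " rows with invalid fields")
  structure(out, parse_report = report)
}

# "X60-X84" -> list(c(lo_key, hi_key)); keys order codes by letter then number.
icd10_key <- function(prefix) {
  match(substr(prefix, 1, 1), LETTERS) * 100L +
    as.integer(substr(prefix, 2, 3))
}

parse_icd10_ranges <- function(range_spec) {
  lapply(range_spec, function(r) {
    parts <- strsplit(gsub("\\s", "", r), "-", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, parts)
    if (length(parts) != 2L || !all(grepl("^[A-Z][0-9]{2}$", parts)))
      stop("malformed ICD-10 range: '", r,
           "' (expected e.g. \"X60-X84\")", call. = FALSE)
    k <- icd10_key(parts)
    if (k[1] > k[2]) stop("ICD-10 range out of order: '", r, "'", call. = FALSE)
    k
  })
}

#' Test ICD-10 codes against inclusive 3-character ranges
#'
#' Comparison uses the 3-character prefix only (letter, then two-digit
#' number); any 4th character is ignored. Ranges are inclusive at both ends.
#'
#' @param code Character vector of ICD-10 codes.
#' @param range_spec Character vector of ranges such as `"X60-X84"` (a bare
#'   prefix denotes a single-code range).
#' @return Logical vector: is each code inside any of the ranges?
#' @examples
#' icd10_in_range(c("X60", "X709", "X85"), "X60-X84")  # TRUE TRUE FALSE
#' @export
icd10_in_range <- function(code, range_spec) {
  if (!all(grepl(icd10_pattern, code)))
    stop("malformed ICD-10 code(s): ",
         paste(utils::head(code[!grepl(icd10_pattern, code)], 5L), collapse = ", "),
         call. = FALSE)
  ranges <- parse_icd10_ranges(range_spec)
  key <- icd10_key(substr(code, 1, 3))
  Reduce(`|`, lapply(ranges, function(k) key >= k[1] & key <= k[2]))
}

#' Cause-of-death ranges of the two analysis modes
#'
#' `"suicide"` is intentional self-harm, X60-X84. `"unexpected"` is the
#' sensitivity set of other external causes, W00-X59 and Y01-Y59 (note this
#' stated set omits X85-Y00, assault and undetermined-intent codes).
#'
#' @param mode `"suicide"` or `"unexpected"`.
#' @return Character vector of inclusive ICD-10 ranges.
#' @export
cause_ranges <- function(mode = c("suicide", "unexpected")) {
  switch(match.arg(mode),
         suicide = "X60-X84",
         unexpected = c("W00-X59", "Y01-Y59"))
}

# All 3-character prefixes inside a range spec (used by the simulator).
icd10_prefixes <- function(range_spec) {
  unlist(lapply(parse_icd10_ranges(range_spec), function(k) {
    keys <- k[1]:k[2]
    paste0(LETTERS[keys %/% 100L], sprintf("%02d", keys %% 100L))
  }))
}

#' Keep records of one cause-of-death mode
#'
#' @param records Parsed death records.
#' @param mode `"suicide"` (X60-X84) or `"unexpected"` (W00-X59, Y01-Y59).
#' @return The subset of records whose `icd10` falls in the mode's ranges.
#' @export
select_cause <- function(records, mode = c("suicide", "unexpected")) {
  if (nrow(records) == 0L) return(records)
  records[icd10_in_range(records$icd10, cause_ranges(mode)), , drop = FALSE]
}

#' Apply the analysis exclusion rules
#'
#' Drops records with missing age, missing occupation, or marital status
#' "other". Drop counts per reason (assigned in that order, mutually
#' exclusively, so they sum to the total dropped) are attached as attribute
#' `exclusion_log`.
#'
#' @param records Parsed death records.
#' @return The retained records, with an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$marital_status) | records$marital_status == "other"] <- "marital_other"
  reason[is.na(records$occupation)] <- "missing_occupation"
  reason[is.na(records$age)] <- "missing_age"
  keep <- is.na(reason)
  log <- list(n_in = nrow(records), n_kept = sum(keep),
              dropped = c(missing_age = sum(reason == "missing_age", na.rm = TRUE),
                          missing_occupation = sum(reason == "missing_occupation", na.rm = TRUE),
                          marital_other = sum(reason == "marital_other", na.rm = TRUE)))
  stopifnot(log$n_in == log$n_kept + sum(log$dropped))
  structure(records[keep, , drop = FALSE], exclusion_log = log)
}

#' Binarize age into young (40 or younger) vs old
#'
#' The cut reflects the age group assumed most exposed to the platform.
#'
#' @param age Integer ages (no missing values; exclusions run first).
#' @return Character vector, `"young"` (age <= 40) or `"old"`.
#' @export
derive_age_group <- function(age) {
  if (anyNA(age)) stop("derive_age_group: age must not be missing", call. = FALSE)
  ifelse(age <= 40, "young", "old")
}

#' Date-keyed merge of records with the exposure calendar at a lag
#'
#' A record dying on day d receives the exposure status of day `d -
#' lag_days`. Records whose lagged date is outside the calendar or has
#' undefined exposure are dropped and counted in the `merge_log` attribute.
#'
#' @param records Parsed death records.
#' @param calendar An exposure calendar with dates ([classify_surge()]).
#' @param lag_days Non-negative integer lag.
#' @return The retained records with logical `exposed` and `lag_days`
#'   columns added; attribute `merge_log` holds `n_in`, `n_kept`,
#'   `n_dropped`.
#' @export
merge_with_lag <- function(records, calendar, lag_days) {
  stopifnot(is.numeric(lag_days), length(lag_days) == 1L, lag_days >= 0)
  exposed <- calendar_exposure(calendar, records$death_date - lag_days)
  keep <- !is.na(exposed)
  out <- records[keep, , drop = FALSE]
  out$exposed <- exposed[keep]
  out$lag_days <- rep(as.integer(lag_days), nrow(out))
  log <- list(n_in = nrow(records), n_kept = sum(keep), n_dropped = sum(!keep))
  stopifnot(log$n_in == log$n_kept + log$n_dropped)
  structure(out, merge_log = log)
}
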