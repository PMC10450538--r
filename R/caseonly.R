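#' Specify a characteristic for analysis
#'
#' The analysis-side description of a characteristic: which record column to
#' read, the ordered levels to keep, and the reference (base) level that
#' contrasts are formed against.
#'
#' @param name Characteristic name (used in output tables).
#' @param levels Ordered levels; rows with other values are an error at
#'   cross-tabulation time.
#' @param reference Base level for OR/RRR contrasts.
#' @param column Record column holding the level; defaults to `name`.
#' @return A `char_spec` list.
#' @export
char_spec <- function(name, levels, reference = levels[1], column = name) {
  stopifnot(length(levels) >= 2L, reference %in% levels)
  structure(list(name = name, column = column, levels = levels,
                 reference = reference), class = "char_spec")
}

#' Default analysis characteristics
#'
#' Age group (40 or younger vs older, base old), sex (base female), area
#' (base rural) as binary characteristics; occupation (base self-employed)
#' and marital status (base married, the excluded "other" class omitted) as
#' multi-level characteristics.
#'
#' @return List of [char_spec()] objects.
#' @export
default_characteristics <- function() {
  list(
    char_spec("age_group", c("old", "young"), reference = "old"),
    char_spec("sex", c("female", "male"), reference = "female"),
    char_spec("occupation",
              c("self-employed", "agriculture", "corporate", "other", "unemployed"),
              reference = "self-employed"),
    char_spec("marital_status", c("married", "unmarried", "widowed", "divorced"),
              reference = "married"),
    char_spec("area", c("rural", "urban"), reference = "rural")
  )
}

#' Cross-tabulate exposure by characteristic level among cases
#'
#' Builds the 2 x J table of case counts (rows: non-surge day, surge day;
#' columns: characteristic levels) that the case-only estimators operate on.
#'
#' @param rows Analysis rows with a defined logical `exposed` and a defined
#'   level in the spec's column.
#' @param spec A [char_spec()].
#' @return Object of class `caseonly_table`: the spec plus a 2 x J integer
#'   `counts` matrix (rownames `unexposed`, `exposed`).
#' @export
crosstab <- function(rows, spec) {
  stopifnot(inherits(spec, "char_spec"))
  lvl <- rows[[spec$column]]
  if (is.null(lvl)) stop("no column '", spec$column, "' in analysis rows", call. = FALSE)
  if (anyNA(rows$exposed) || anyNA(lvl))
    stop("crosstab: exposure and level must be defined for every row", call. = FALSE)
  unknown <- setdiff(unique(lvl), spec$levels)
  if (length(unknown))
    stop("crosstab: level(s) not in spec for '", spec$name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  counts <- table(factor(ifelse(rows$exposed, "exposed", "unexposed"),
                         c("unexposed", "exposed")),
                  factor(lvl, spec$levels))
  counts <- matrix(as.integer(counts), nrow = 2L,
                   dimnames = list(c("unexposed", "exposed"), spec$levels))
  structure(list(name = spec$name, levels = spec$levels,
                 reference = spec$reference, counts = counts),
            class = "caseonly_table")
}

#' Build a case-only table directly from cell counts
#'
#' @param counts 2 x J matrix (row 1 non-surge, row 2 surge days).
#' @param name Characteristic name.
#' @param reference Base level (a column name of `counts`).
#' @return A `caseonly_table`.
#' @export
caseonly_table <- function(counts, name = "characteristic",
                           reference = colnames(counts)[1]) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L, ncol(counts) >= 2L, all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("level", seq_len(ncol(counts)))
  rownames(counts) <- c("unexposed", "exposed")
  stopifnot(reference %in% colnames(counts))
  structure(list(name = name, levels = colnames(counts),
                 reference = reference, counts = counts),
            class = "caseonly_table")
}

#' @export
print.caseonly_table <- function(x, ...) {
  cat("Case-only 2 x ", length(x$levels), " table for '", x$name,
      "' (reference: ", x$reference, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

est_row <- function(name, level, reference, log_est, se, conf_level, estimator) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(characteristic = name, level = level, reference = reference,
             estimate = exp(log_est), se_log = se,
             ci_lower = exp(log_est - z * se), ci_upper = exp(log_est + z * se),
             p_value = 2 * stats::pnorm(-abs(log_est / se)),
             estimator = estimator)
}

resolve_zero_cells <- function(counts, correct, involved = seq_len(ncol(counts))) {
  zero <- counts[, involved, drop = FALSE] == 0
  storage.mode(counts) <- "double"  # cross-products would overflow integers
  if (!any(zero)) return(list(counts = counts, corrected = FALSE))
  if (!correct)
    stop("zero cell(s) in the case-only table; rerun with correct = TRUE to ",
         "add 0.5 to every cell (continuity correction)", call. = FALSE)
  list(counts = counts + 0.5, corrected = TRUE)
}

check_ml_agreement <- function(log_closed, log_ml, what) {
  tol <- 1e-6 * pmax(1, abs(log_closed))
  if (any(abs(log_closed - log_ml) > tol))
    stop("internal check failed: ", what, " ML fit disagrees with the closed form (",
         "max |diff| = ", format(max(abs(log_closed - log_ml)), digits = 3), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Case-only odds ratio of a binary characteristic
#'
#' The closed-form cross-product ratio of the 2 x 2 surge-by-level table
#' among cases, `(n11 * n00) / (n10 * n01)`, which estimates the
#' multiplicative interaction `exp(beta3)` of the underlying Poisson model.
#' The Wald SE is `sqrt` of the summed reciprocal cells, with the CI formed
#' on the log scale. Every call also fits the equivalent one-predictor
#' binary logistic regression by maximum likelihood and verifies agreement
#' with the closed form to 1e-6 relative; the reported numbers come from
#' the closed form.
#'
#' @param tab A 2 x 2 [caseonly_table()] (or [crosstab()] output).
#' @param correct Add 0.5 to every cell when a cell is zero (otherwise a
#'   zero cell is an error). Corrected estimates skip the ML cross-check
#'   and are tagged `closed_form_corrected`.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data frame: level, estimate (OR), log-scale SE, CI
#'   bounds, two-sided Wald p-value, estimator tag.
#' @examples
#' tab <- caseonly_table(matrix(c(40, 5, 20, 10), 2,
#'                              dimnames = list(NULL, c("female", "male"))))
#' caseonly_or_binary(tab)  # OR 4.0
#' @export
caseonly_or_binary <- function(tab, correct = FALSE, conf_level = 0.95) {
  stopifnot(inherits(tab, "caseonly_table"))
  if (ncol(tab$counts) != 2L)
    stop("caseonly_or_binary needs a 2 x 2 table; use caseonly_rrr_multinomial ",
         "for ", ncol(tab$counts), " levels", call. = FALSE)
  ord <- c(tab$reference, setdiff(tab$levels, tab$reference))
  n <- tab$counts[, ord, drop = FALSE]
  rz <- resolve_zero_cells(n, correct)
  n <- rz$counts
  log_or <- log(n[2, 2] * n[1, 1] / (n[2, 1] * n[1, 2]))
  se <- sqrt(sum(1 / n))
  if (!rz$corrected) {
    d <- data.frame(y = c(0, 1, 0, 1), e = c(0, 0, 1, 1), w = as.vector(t(n)))
    fit <- stats::glm(y ~ e, family = stats::binomial(), data = d, weights = d$w,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    check_ml_agreement(log_or, stats::coef(fit)[["e"]], "binary logistic")
  }
  est_row(tab$name, ord[2], tab$reference, log_or, se, conf_level,
          if (rz$corrected) "closed_form_corrected" else "closed_form")
}

# Maximum-likelihood baseline-category (multinomial) logit fit to a 2 x J
# case-only table by full Newton-Raphson: level ~ exposure with the base
# level first. Quadratic convergence gives near machine-precision MLEs,
# which BFGS-based fitters do not reliably deliver at the 1e-6 agreement
# tolerance the cross-check demands. Returns the exposure log-RRR per
# non-base level.
ml_multinomial_logrrr <- function(counts, tol = 1e-12, max_iter = 50L) {
  J <- ncol(counts)
  k <- J - 1L
  theta <- numeric(2L * k)  # (intercepts, slopes) for non-base levels
  n_tot <- rowSums(counts)
  for (iter in seq_len(max_iter)) {
    g <- numeric(2L * k)
    H <- matrix(0, 2L * k, 2L * k)
    for (e in 0:1) {
      eta <- c(0, theta[seq_len(k)] + e * theta[k + seq_len(k)])
      p <- exp(eta - max(eta)); p <- p / sum(p)
      r <- counts[e + 1L, -1L] - n_tot[e + 1L] * p[-1L]
      w <- n_tot[e + 1L] * (diag(p[-1L], k) - tcrossprod(p[-1L]))
      g[seq_len(k)] <- g[seq_len(k)] + r
      g[k + seq_len(k)] <- g[k + seq_len(k)] + e * r
      H[seq_len(k), seq_len(k)] <- H[seq_len(k), seq_len(k)] + w
      H[seq_len(k), k + seq_len(k)] <- H[seq_len(k), k + seq_len(k)] + e * w
      H[k + seq_len(k), seq_len(k)] <- H[k + seq_len(k), seq_len(k)] + e * w
      H[k + seq_len(k), k + seq_len(k)] <- H[k + seq_len(k), k + seq_len(k)] + e * e * w
    }
    step <- solve(H, g)
    theta <- theta + step
    if (max(abs(g)) < tol * max(1, max(n_tot)) && max(abs(step)) < 1e-10) break
  }
  theta[k + seq_len(k)]
}

#' Case-only relative risk ratios of a multi-level characteristic
#'
#' For each non-base level j of a 2 x J table, the closed-form RRR is the
#' cross-product ratio against the base column,
#' `(n1j * n0b) / (n0j * n1b)`, with Wald SE `sqrt(1/n1j + 1/n0j + 1/n1b +
#' 1/n0b)` — the multinomial-logistic analogue of the case-only OR, each
#' level contrasted with the base level. Every call cross-checks the closed
#' forms against a maximum-likelihood multinomial (baseline-category logit)
#' fit, computed by Newton-Raphson, to 1e-6 relative; reported numbers come
#' from the closed forms.
#'
#' @param tab A 2 x J [caseonly_table()], J >= 2.
#' @param base_level Base (reference) level; defaults to the table's.
#' @inheritParams caseonly_or_binary
#' @return Data frame with one row per non-base level.
#' @examples
#' tab <- caseonly_table(
#'   matrix(c(100, 100, 50, 60, 80, 40), 2,
#'          dimnames = list(NULL, c("self-employed", "A", "B"))))
#' caseonly_rrr_multinomial(tab)  # RRR 1.2 and 0.5
#' @export
caseonly_rrr_multinomial <- function(tab, base_level = tab$reference,
                                     correct = FALSE, conf_level = 0.95) {
  stopifnot(inherits(tab, "caseonly_table"))
  if (!base_level %in% tab$levels)
    stop("base level '", base_level, "' is not a level of the table", call. = FALSE)
  rz <- resolve_zero_cells(tab$counts, correct)
  n <- rz$counts
  others <- setdiff(tab$levels, base_level)
  log_rrr <- log(n[2, others] * n[1, base_level] /
                   (n[1, others] * n[2, base_level]))
  se <- sqrt(1 / n[2, others] + 1 / n[1, others] +
               1 / n[2, base_level] + 1 / n[1, base_level])
  if (!rz$corrected) {
    ml <- ml_multinomial_logrrr(n[, c(base_level, others), drop = FALSE])
    check_ml_agreement(unname(log_rrr), unname(ml), "multinomial")
  }
  out <- do.call(rbind, lapply(seq_along(others), function(i)
    est_row(tab$name, others[i], base_level, log_rrr[i], se[i], conf_level,
            if (rz$corrected) "closed_form_corrected" else "closed_form")))
  rownames(out) <- NULL
  out
}

#' Poisson oracle for a binary characteristic
#'
#' Fits the saturated Poisson log-linear model `count ~ exposure * level` to
#' the four exposure-by-level case totals and returns `exp(beta3)` with its
#' Wald SE. Because the model is saturated, its interaction term equals the
#' case-only cross-product OR exactly — this is the estimator derived from
#' the underlying daily-count Poisson model, kept as an independent route to
#' the same quantity.
#'
#' @param x Analysis rows (with `exposed` and the spec's column) or a 2 x 2
#'   `caseonly_table`.
#' @param spec A [char_spec()]; required when `x` is a data frame of rows.
#' @inheritParams caseonly_or_binary
#' @return One-row data frame as in [caseonly_or_binary()], estimator tag
#'   `poisson_oracle`.
#' @export
poisson_oracle <- function(x, spec = NULL, correct = FALSE, conf_level = 0.95) {
  tab <- if (inherits(x, "caseonly_table")) x else crosstab(x, spec)
  if (ncol(tab$counts) != 2L)
    stop("poisson_oracle needs a binary characteristic", call. = FALSE)
  ord <- c(tab$reference, setdiff(tab$levels, tab$reference))
  rz <- resolve_zero_cells(tab$counts[, ord, drop = FALSE], correct)
  n <- rz$counts
  d <- data.frame(count = as.vector(n),
                  e = c(0, 1, 0, 1), lvl = c(0, 0, 1, 1))
  fit <- suppressWarnings( # corrected counts are non-integer by design
    stats::glm(count ~ e * lvl, family = stats::poisson(), data = d,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  b3 <- stats::coef(fit)[["e:lvl"]]
  se <- sqrt(diag(stats::vcov(fit)))[["e:lvl"]]
  est_row(tab$name, ord[2], tab$reference, b3, se, conf_level, "poisson_oracle")
}

#' Run the full case-only interaction analysis
#'
#' Filters records to the mode's cause-of-death ranges, applies the
#' exclusion rules (missing age or occupation, marital status "other"),
#' derives the binary age group, and, for every lag and characteristic,
#' merges with the exposure calendar and estimates the interaction: a
#' case-only OR for binary characteristics, RRRs against the base level for
#' multi-level ones. `significant` flags two-sided Wald p < .05 (no
#' multiple-testing adjustment — a deliberate mirror of common practice in
#' this design, noted as a limitation). No covariates enter the model: the
#' design assumes characteristic and exposure are independent in the base
#' population, and shared time-varying terms cancel among cases.
#'
#' @param records Parsed death records ([parse_records()] layout).
#' @param calendar Exposure calendar with dates.
#' @param lags Integer vector of lags in days (default 3 and 7).
#' @param characteristics List of [char_spec()]s.
#' @param mode `"suicide"` or `"unexpected"` (sensitivity analysis).
#' @param correct Continuity-correct zero cells instead of erroring.
#' @param conf_level Confidence level for all intervals.
#' @return Data frame with one row per characteristic level and lag
#'   (estimate, CI, p, significance flag); attribute `analysis_log` records
#'   the per-stage record accounting.
#' @export
run_analysis <- function(records, calendar, lags = c(3L, 7L),
                         characteristics = default_characteristics(),
                         mode = c("suicide", "unexpected"),
                         correct = FALSE, conf_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(length(lags) >= 1L, all(lags >= 0))
  cases <- select_cause(records, mode)
  kept <- apply_exclusions(cases)
  excl_log <- attr(kept, "exclusion_log")
  if (nrow(kept)) kept$age_group <- derive_age_group(kept$age)
  empty <- est_row("x", "x", "x", 0, 1, conf_level, "x")[0, ]
  merge_log <- list()
  out <- list()
  for (lag in lags) {
    rows <- merge_with_lag(kept, calendar, lag)
    merge_log[[as.character(lag)]] <- attr(rows, "merge_log")
    for (spec in characteristics) {
      est <- tryCatch({
        tab <- crosstab(rows, spec)
        if (length(spec$levels) == 2L)
          caseonly_or_binary(tab, correct = correct, conf_level = conf_level)
        else
          caseonly_rrr_multinomial(tab, correct = correct, conf_level = conf_level)
      }, error = function(e)
        stop("lag ", lag, ", characteristic '", spec$name, "': ",
             conditionMessage(e), call. = FALSE))
      est$lag <- as.integer(lag)
      out[[length(out) + 1L]] <- est
    }
  }
  res <- if (length(out)) do.call(rbind, out) else cbind(empty, lag = integer())
  if (nrow(res)) res$significant <- res$p_value < 0.05 else res$significant <- logical()
  rownames(res) <- NULL
  structure(res, analysis_log = list(
    mode = mode, n_records = nrow(records), n_cause = nrow(cases),
    exclusions = excl_log, merge = merge_log))
}
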