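#' Sickness-absence rate in days per year
#'
#' @param sa_days Count of absence days within follow-up.
#' @param followup_days Follow-up length `T` in days (> 0).
#' @return `sa_days * 365 / followup_days`.
#' @export
sa_rate <- function(sa_days, followup_days) {
  if (any(followup_days <= 0)) stopf("followup_days must be positive")
  sa_days * 365 / followup_days
}

#' Standardize a continuous variable by two standard deviations
#'
#' `(x - mean(x)) / (2 sd(x))` with the `n - 1` standard deviation, so a
#' one-unit change in the standardized variable is a two-SD change in the
#' original and its regression coefficient is comparable in magnitude to
#' that of an (approximately balanced) binary input.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return Standardized vector.
#' @export
standardize_2sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("cannot standardize a constant")
  (x - mean(x)) / (2 * s)
}

#' Poisson regression of sickness-absence days with follow-up offset
#'
#' Fits `sa_days ~ covariates` by maximum-likelihood Poisson regression
#' with offset `log(T / 365)`, so exponentiated coefficients are incidence
#' rate ratios (IRR) on the days-per-year scale. Cluster membership enters
#' as dummies against a reference cluster; continuous covariates (age,
#' risk scores, past SA rate) are standardized by two standard deviations
#' within the fitted sample. Confidence intervals are Wald:
#' `exp(coef +/- 1.96 SE)`.
#'
#' @param outcomes Data frame with columns `sa_days`, `followup_days`,
#'   `woman` (0/1), `age`, `cluster`, and -- as required -- the three risk
#'   score columns (`long_spell_score`, `night_shift_score`,
#'   `quick_return_score`) and `past_sa_rate`.
#' @param include_scores Add the three risk scores as covariates.
#' @param include_past_sa Add the standardized past SA rate.
#' @param reference_cluster Cluster label used as reference.
#' @param dispersion `"poisson"` (default) or `"quasipoisson"`.
#' @return An object of class `fit_result`: the `glm` fit and a `table`
#'   with one row per coefficient (`term`, `estimate`, `se`, `irr`,
#'   `ci_low`, `ci_high`).
#' @export
fit_poisson <- function(outcomes, include_scores = FALSE,
                        include_past_sa = FALSE,
                        reference_cluster = NULL,
                        dispersion = c("poisson", "quasipoisson")) {
  dispersion <- match.arg(dispersion)
  if (any(outcomes$sa_days > outcomes$followup_days)) {
    stopf("sa_days exceeds followup_days for some employee")
  }
  dat <- data.frame(sa_days = outcomes$sa_days,
                    off = log(outcomes$followup_days / 365))
  terms <- character(0)
  if (!is.null(outcomes$woman)) {
    dat$woman <- outcomes$woman
    terms <- c(terms, "woman")
  }
  if (!is.null(outcomes$age)) {
    dat$age <- standardize_2sd(outcomes$age)
    terms <- c(terms, "age")
  }
  cl <- factor(outcomes$cluster)
  if (!is.null(reference_cluster)) {
    if (!reference_cluster %in% levels(cl)) {
      stopf("reference cluster %s not present", reference_cluster)
    }
    cl <- stats::relevel(cl, ref = as.character(reference_cluster))
  }
  if (nlevels(cl) > 1) {
    dat$cluster <- cl
    terms <- c(terms, "cluster")
  }
  if (include_scores) {
    for (v in c("long_spell_score", "night_shift_score",
                "quick_return_score")) {
      if (is.null(outcomes[[v]])) stopf("missing score column %s", v)
      if (stats::sd(outcomes[[v]]) == 0) {
        message("dropping constant covariate ", v)
        next
      }
      dat[[v]] <- standardize_2sd(outcomes[[v]])
      terms <- c(terms, v)
    }
  }
  if (include_past_sa) {
    if (is.null(outcomes$past_sa_rate)) stopf("missing past_sa_rate")
    dat$past_sa_rate <- standardize_2sd(outcomes$past_sa_rate)
    terms <- c(terms, "past_sa_rate")
  }
  fml <- stats::reformulate(c(terms, "offset(off)"), response = "sa_days")
  fam <- if (dispersion == "poisson") stats::poisson()
         else stats::quasipoisson()
  fit <- stats::glm(fml, family = fam, data = dat,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) {
    stopf("Poisson fit did not converge in %d iterations", fit$iter)
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    irr = exp(sm[, 1]),
                    ci_low = exp(sm[, 1] - 1.96 * sm[, 2]),
                    ci_high = exp(sm[, 1] + 1.96 * sm[, 2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = fit, table = tab,
                 reference_cluster = reference_cluster),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> Poisson IRR table\n")
  print(transform(x$table, irr = round(irr, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3),
                  estimate = NULL, se = NULL))
  invisible(x)
}

#' Fit the three standard sickness-absence models
#'
#' Model 1 (cross-sectional): full-period SA on sex, age and full-data
#' cluster dummies. Model 2: Model 1 plus the three shift-ergonomics risk
#' scores. Model 3 (prospective): future-half SA on past-half covariates
#' -- past-assigned clusters, past risk scores and the standardized past
#' SA rate. Employees with less than one day of future follow-up are
#' excluded from Model 3 with a message.
#'
#' @param outcomes_full Outcome table over the full follow-up (see
#'   [fit_poisson()] for columns).
#' @param outcomes_future Outcome table with future-half `sa_days` and
#'   `followup_days`, past-derived `cluster`, scores and `past_sa_rate`.
#' @param reference_cluster Reference cluster label for all models.
#' @return Named list of three `fit_result`s (`model1`--`model3`).
#' @export
run_model_suite <- function(outcomes_full, outcomes_future,
                            reference_cluster = NULL) {
  m1 <- fit_poisson(outcomes_full, include_scores = FALSE,
                    reference_cluster = reference_cluster)
  m2 <- fit_poisson(outcomes_full, include_scores = TRUE,
                    reference_cluster = reference_cluster)
  short <- outcomes_future$followup_days < 1
  if (any(short)) {
    message(sum(short), " employee(s) with < 1 day of future follow-up",
            " excluded from the prospective model")
    outcomes_future <- outcomes_future[!short, , drop = FALSE]
  }
  m3 <- fit_poisson(outcomes_future, include_scores = TRUE,
                    include_past_sa = TRUE,
                    reference_cluster = reference_cluster)
  list(model1 = m1, model2 = m2, model3 = m3)
}

#' Assemble the per-employee outcome table
#'
#' Joins follow-up span and SA day counts (dates falling inside each
#' employee's follow-up window) with cluster labels, demographics and risk
#' scores into the table [fit_poisson()] consumes. Follow-up runs from the
#' first shift's start date to the last shift's end date, inclusive.
#'
#' @param series Named list of `work_series`.
#' @param sa_records SA log (`employee_id`, `date`), e.g. from
#'   [read_sa_log()].
#' @param labels Cluster labels named by employee id.
#' @param demographics Data frame `employee_id`, `woman`, `age`
#'   (optional).
#' @param scores Risk-score table from [cohort_risk_scores()] (optional).
#' @return Data frame with one row per employee in `series`.
#' @export
build_outcomes <- function(series, sa_records, labels,
                           demographics = NULL, scores = NULL) {
  rows <- lapply(names(series), function(id) {
    ws <- series[[id]]
    first <- ts_date(min(ws$start))
    last <- ts_date(max(ws$end))
    dates <- sa_records$date[sa_records$employee_id == id]
    data.frame(employee_id = id,
               sa_days = sum(dates >= first & dates <= last),
               followup_days = as.integer(last - first) + 1L,
               cluster = unname(labels[id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(demographics)) {
    out <- merge(out, demographics, by = "employee_id", sort = FALSE)
  }
  if (!is.null(scores)) {
    out <- merge(out, scores, by = "employee_id", sort = FALSE)
  }
  out
}
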