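#' Smooth log-linear rate curves
#'
#' Tabulated general mortality rates and mortality rate ratios enter the
#' least-squares step as smooth positive functions of age.  Both are
#' fitted log-linearly, `log y(a) = alpha + beta a` (a Gompertz-type form
#' for adult mortality), which guarantees positivity at every age.
#'
#' @param table A mortality table with columns `age` and `rate` (see
#'   [make_mortality_table()], [read_mortality_table()]); at least 3 ages
#'   with strictly positive rates.
#' @return An object of class `idm_rate_curve` with elements
#'   `coefficients` (`alpha`, `beta`), `age_range`, `kind`, `label`.
#' @name smooth_rate_curves
#' @export
fit_log_mortality <- function(table) {
  if (!all(c("age", "rate") %in% names(table))) {
    stop("mortality table needs columns 'age' and 'rate'", call. = FALSE)
  }
  if (nrow(table) < 3L) stop("need at least 3 tabulated ages", call. = FALSE)
  if (any(table$rate <= 0)) {
    stop("all tabulated mortality rates must be positive (log fit)",
         call. = FALSE)
  }
  co <- stats::lm.fit(cbind(1, table$age), log(table$rate))$coefficients
  structure(list(coefficients = c(alpha = unname(co[1]), beta = unname(co[2])),
                 age_range = range(table$age), kind = "mortality",
                 label = if ("sex" %in% names(table)) table$sex[1L] else NA_character_),
            class = "idm_rate_curve")
}

#' @rdname smooth_rate_curves
#' @param curve An MRR table with columns `age` and `ratio` (see
#'   [make_mrr_curve()], [read_mrr_curve()]); at least 2 ages with
#'   strictly positive ratios.
#' @export
fit_mrr <- function(curve) {
  if (!all(c("age", "ratio") %in% names(curve))) {
    stop("MRR table needs columns 'age' and 'ratio'", call. = FALSE)
  }
  if (nrow(curve) < 2L) stop("need at least 2 tabulated ages", call. = FALSE)
  if (any(curve$ratio <= 0)) {
    stop("all tabulated mortality rate ratios must be positive (log fit)",
         call. = FALSE)
  }
  co <- stats::lm.fit(cbind(1, curve$age), log(curve$ratio))$coefficients
  structure(list(coefficients = c(alpha = unname(co[1]), beta = unname(co[2])),
                 age_range = range(curve$age), kind = "mrr",
                 label = if ("condition" %in% names(curve)) curve$condition[1L] else NA_character_),
            class = "idm_rate_curve")
}

#' @export
print.idm_rate_curve <- function(x, ...) {
  cat(sprintf("Log-linear %s curve: log y = %.4g + %.4g * age on ages %g-%g\n",
              x$kind, x$coefficients["alpha"], x$coefficients["beta"],
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Evaluate a smooth rate curve
#'
#' @param object An `idm_rate_curve`.
#' @param age Ages in years; evaluation outside the tabulated range is
#'   returned with an extrapolation warning.
#' @param ... Unused.
#' @return Positive rates/ratios at `age`.
#' @export
predict.idm_rate_curve <- function(object, age, ...) {
  if (any(age < object$age_range[1] | age > object$age_range[2])) {
    warning("evaluating ", object$kind, " curve outside its tabulated range ",
            object$age_range[1], "-", object$age_range[2], " extrapolates",
            call. = FALSE)
  }
  exp(object$coefficients["alpha"] + object$coefficients["beta"] * age)
}

# rate inputs to the estimator may be fitted curves or plain functions
.eval_curve <- function(x, age) {
  if (is.function(x)) x(age) else unname(predict(x, age))
}

#' Multiply a mortality-rate-ratio curve by a constant factor
#'
#' The robustness analysis re-estimates the rates with the MRR scaled
#' uniformly across ages (default factors 0.85 and 1.15, i.e. +/-15%).
#'
#' @param curve An `idm_rate_curve` of kind `"mrr"`.
#' @param factor Positive multiplier.
#' @return The perturbed curve.
#' @export
perturb_mrr <- function(curve, factor) {
  stopifnot(inherits(curve, "idm_rate_curve"))
  if (!is.finite(factor) || factor <= 0) {
    stop("'factor' must be strictly positive", call. = FALSE)
  }
  curve$coefficients["alpha"] <- curve$coefficients["alpha"] + log(factor)
  curve
}
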