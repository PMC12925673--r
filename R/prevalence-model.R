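#' Aggregate participant records into binomial cells
#'
#' Complete-case filtering (records with missing case status for the
#' analyzed condition are dropped) followed by aggregation of survey
#' weights into weighted case and total sums per (center, sex, period,
#' age) cell.  Cells are the unit of the weighted binomial likelihood and
#' of leave-one-out cross-validation.
#'
#' @param records Participant data frame (see [sample_study()]).
#' @param condition Condition whose case column is analyzed
#'   (e.g. `"anxiety"`, `"depression"`).
#' @return A data frame with columns `center`, `sex`, `period`, `age`,
#'   `t` (calendar midpoint of the period), `wcase`, `wtot`, `n`.
#' @export
aggregate_cells <- function(records, condition = "anxiety") {
  col <- .case_column(records, condition)
  keep <- !is.na(records[[col]])
  if (!any(keep)) {
    stop("no complete cases for condition '", condition, "'", call. = FALSE)
  }
  rec <- records[keep, , drop = FALSE]
  key <- interaction(rec$center, rec$sex, rec$period, rec$age, drop = TRUE)
  wtot <- rowsum(rec$weight, key)
  wcase <- rowsum(rec$weight * rec[[col]], key)
  n <- rowsum(rep(1L, nrow(rec)), key)
  parts <- do.call(rbind, strsplit(rownames(wtot), ".", fixed = TRUE))
  mids <- period_midpoints()
  cells <- data.frame(
    center = parts[, 1L], sex = parts[, 2L],
    period = as.integer(parts[, 3L]), age = as.numeric(parts[, 4L]),
    wcase = as.numeric(wcase), wtot = as.numeric(wtot), n = as.integer(n),
    stringsAsFactors = FALSE
  )
  cells$t <- unname(mids[as.character(cells$period)])
  cells <- cells[order(cells$center, cells$sex, cells$period, cells$age), ]
  rownames(cells) <- NULL
  cells
}

# Metadata describing the linear predictor layout; shared by the design
# matrix, its directional derivative and prediction.
.pm_meta <- function(cells, df, age_sex_interaction) {
  stopifnot(df >= 1, df <= 6)
  list(
    df = as.integer(df),
    age_center = 46.5,
    time_center = 2017,
    sex_levels = sort(unique(cells$sex)),
    center_levels = sort(unique(cells$center)),
    has_time = length(unique(cells$period)) > 1L,
    age_sex = isTRUE(age_sex_interaction) && length(unique(cells$sex)) > 1L
  )
}

# Design matrix of the linear predictor eta(t, a, sex, center):
# intercept + raw polynomial in centered age + linear centered calendar
# time + sex and center indicators + optional (centered age) x sex term.
.pm_design <- function(meta, t, age, sex, center) {
  n <- length(age)
  t <- rep_len(t, n); sex <- rep_len(sex, n); center <- rep_len(center, n)
  ac <- age - meta$age_center
  cols <- list(`(Intercept)` = rep(1, n))
  for (j in seq_len(meta$df)) cols[[paste0("age", j)]] <- ac^j
  if (meta$has_time) cols[["time"]] <- t - meta$time_center
  for (lv in meta$sex_levels[-1L]) {
    cols[[paste0("sex", lv)]] <- as.numeric(sex == lv)
  }
  for (lv in meta$center_levels[-1L]) {
    cols[[paste0("center", lv)]] <- as.numeric(center == lv)
  }
  if (meta$age_sex) {
    for (lv in meta$sex_levels[-1L]) {
      cols[[paste0("age1:sex", lv)]] <- ac * (sex == lv)
    }
  }
  do.call(cbind, cols)
}

# Directional derivative (d/dt + d/da) of each design column.
.pm_design_deriv <- function(meta, t, age, sex, center) {
  n <- length(age)
  sex <- rep_len(sex, n)
  ac <- age - meta$age_center
  cols <- list(`(Intercept)` = rep(0, n))
  for (j in seq_len(meta$df)) {
    cols[[paste0("age", j)]] <- j * ac^(j - 1L)
  }
  if (meta$has_time) cols[["time"]] <- rep(1, n)
  for (lv in meta$sex_levels[-1L]) cols[[paste0("sex", lv)]] <- rep(0, n)
  for (lv in meta$center_levels[-1L]) cols[[paste0("center", lv)]] <- rep(0, n)
  if (meta$age_sex) {
    for (lv in meta$sex_levels[-1L]) {
      cols[[paste0("age1:sex", lv)]] <- as.numeric(sex == lv)
    }
  }
  do.call(cbind, cols)
}

.pm_glm <- function(X, wcase, wtot, start = NULL) {
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = wcase / wtot, weights = wtot,
    family = stats::quasibinomial(), start = start,
    control = stats::glm.control(maxit = 100)
  ))
  fit
}

#' Fit the survey-weighted logit-polynomial prevalence surface
#'
#' Maximizes the survey-weighted binomial log-likelihood of case status
#' with a logit link over a linear predictor containing a raw polynomial
#' in centered age (`df` terms), a linear calendar-time term (when both
#' periods are present), additive sex and center indicators and, by
#' default, an age-by-sex interaction.  Ages are centered at 46.5 years
#' and calendar time at 2017 for numerical conditioning.
#'
#' @inheritParams aggregate_cells
#' @param df Age-polynomial degrees of freedom, in 1..6 (df = 3 is a
#'   cubic).
#' @param age_sex_interaction Include the (centered age) x sex term?
#'   Default `TRUE`.
#' @param cells Optionally, a pre-aggregated [aggregate_cells()] table
#'   (then `records`/`condition` are ignored).
#' @return An object of class `idm_prevalence_fit` with elements
#'   `coefficients`, `meta`, `cells`, `converged`, `deviance`.
#' @export
fit_logit_polynomial <- function(records = NULL, condition = "anxiety", df = 3,
                                 age_sex_interaction = TRUE, cells = NULL) {
  if (is.null(cells)) cells <- aggregate_cells(records, condition)
  meta <- .pm_meta(cells, df, age_sex_interaction)
  X <- .pm_design(meta, cells$t, cells$age, cells$sex, cells$center)
  fit <- .pm_glm(X, cells$wcase, cells$wtot)
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta))) {
    stop("prevalence model did not converge (df = ", df,
         "; possible separation); deviance = ", format(fit$deviance),
         call. = FALSE)
  }
  structure(list(coefficients = beta, meta = meta, condition = condition,
                 cells = cells, converged = fit$converged,
                 deviance = fit$deviance),
            class = "idm_prevalence_fit")
}

#' @export
print.idm_prevalence_fit <- function(x, ...) {
  cat(sprintf("Logit-polynomial prevalence fit (%s): df = %d, %d cells, deviance %.4g\n",
              x$condition, x$meta$df, nrow(x$cells), x$deviance))
  invisible(x)
}

#' Prevalence and its directional derivative from a fitted surface
#'
#' Evaluates the fitted prevalence `p = logistic(eta)` and its directional
#' derivative along a cohort's life line,
#' `dp = p (1 - p) (d eta/dt + d eta/da)`, with the linear-predictor
#' derivatives taken analytically from the polynomial coefficients (chain
#' rule through the logistic link) - no finite differences.
#'
#' @param object A fitted `idm_prevalence_fit` (or a [truth_surface()]
#'   oracle).
#' @param t Calendar time(s).
#' @param age Age(s) in years; values outside 19-74 trigger an
#'   extrapolation warning.
#' @param sex,center Stratum at which to evaluate.
#' @param ... Unused.
#' @return A list with numeric vectors `p` and `dp`.
#' @export
prevalence_and_derivative <- function(object, t, age, sex = NULL, center = NULL,
                                      ...) {
  UseMethod("prevalence_and_derivative")
}

#' @rdname prevalence_and_derivative
#' @export
prevalence_and_derivative.idm_prevalence_fit <- function(object, t, age,
                                                         sex = NULL,
                                                         center = NULL, ...) {
  meta <- object$meta
  if (any(age < 19 | age > 74)) {
    warning("evaluating the prevalence surface outside ages 19-74 extrapolates",
            call. = FALSE)
  }
  if (is.null(sex)) sex <- meta$sex_levels[1L]
  if (is.null(center)) center <- meta$center_levels[1L]
  X <- .pm_design(meta, t, age, sex, center)
  dX <- .pm_design_deriv(meta, t, age, sex, center)
  eta <- drop(X %*% object$coefficients)
  p <- stats::plogis(eta)
  list(p = p, dp = p * (1 - p) * drop(dX %*% object$coefficients))
}

#' Select the age-polynomial degrees of freedom by cross-validation
#'
#' Leave-one-cell-out cross-validation on the aggregated binomial cells:
#' for each candidate df, every cell is predicted from a model refitted
#' without it and the squared error of the predicted cell prevalence (on
#' the probability scale) is averaged with the cells' weighted totals as
#' weights, so the criterion targets the same estimand as
#' participant-level leave-one-out at a fraction of the cost.
#'
#' The selected df is the smallest candidate whose CV mean squared error
#' lies within one standard error of the minimizing candidate's (the
#' standard cross-validation parsimony rule).  Plain minimization of the
#' CV error over-selects: adding a superfluous degree wins whenever it
#' happens to track noise, which occurs with substantial probability
#' however large the sample, whereas the one-standard-error rule is
#' selection-consistent for these nested fits.  Exact ties break toward
#' the smaller df.
#'
#' @inheritParams fit_logit_polynomial
#' @param candidate_dfs Candidate degrees of freedom (default 1:5).
#' @return The selected df (integer).  Per-candidate CV mean squared
#'   errors and their standard errors are attached as attributes
#'   `"cv_mse"` and `"cv_se"`.
#' @export
select_df_loocv <- function(records = NULL, condition = "anxiety",
                            candidate_dfs = 1:5, age_sex_interaction = TRUE,
                            cells = NULL) {
  if (length(candidate_dfs) == 0L) stop("empty candidate set", call. = FALSE)
  if (is.null(cells)) cells <- aggregate_cells(records, condition)
  if (nrow(cells) < 2L) stop("need at least 2 cells for cross-validation",
                             call. = FALSE)
  candidate_dfs <- sort(unique(as.integer(candidate_dfs)))
  mse <- se <- numeric(length(candidate_dfs))
  obs <- cells$wcase / cells$wtot
  w <- cells$wtot / sum(cells$wtot)
  for (ci in seq_along(candidate_dfs)) {
    df <- candidate_dfs[ci]
    meta <- .pm_meta(cells, df, age_sex_interaction)
    X <- .pm_design(meta, cells$t, cells$age, cells$sex, cells$center)
    full <- .pm_glm(X, cells$wcase, cells$wtot)
    pred <- numeric(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      f <- .pm_glm(X[-i, , drop = FALSE], cells$wcase[-i], cells$wtot[-i],
                   start = full$coefficients)
      pred[i] <- stats::plogis(drop(X[i, , drop = FALSE] %*% f$coefficients))
    }
    e2 <- (obs - pred)^2
    mse[ci] <- sum(w * e2)
    se[ci] <- sqrt(sum(w^2 * (e2 - mse[ci])^2))
  }
  i_min <- which.min(mse)
  sel <- candidate_dfs[which(mse <= mse[i_min] + se[i_min])[1L]]
  attr(sel, "cv_mse") <- stats::setNames(mse, candidate_dfs)
  attr(sel, "cv_se") <- stats::setNames(se, candidate_dfs)
  sel
}
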