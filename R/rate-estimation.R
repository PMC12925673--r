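#' Evaluation grid for the least-squares step
#'
#' The ages at which the balance-equation residuals are evaluated.  The
#' default integer ages 20-73 stay strictly inside the observable range
#' 19-74 so the prevalence derivative is interpolated, never
#' extrapolated.  Calendar time defaults to 2017.0, the midpoint between
#' the two cross-section midpoints.
#'
#' @param sex,center Stratum whose rates are being estimated.
#' @param ages Strictly increasing ages inside (19, 74).
#' @param t Calendar time at which the surface and its derivative are
#'   evaluated.
#' @return An object of class `idm_grid`.
#' @export
evaluation_grid <- function(sex, center, ages = 20:73, t = 2017) {
  if (any(diff(ages) <= 0)) stop("'ages' must be strictly increasing", call. = FALSE)
  if (any(ages < 19 | ages > 74)) {
    stop("'ages' must lie inside the observable range [19, 74]", call. = FALSE)
  }
  structure(list(sex = sex, center = center, ages = ages, t = t),
            class = "idm_grid")
}

# Everything the objective needs that does not depend on theta: the
# surface values p, dp and the precomputed excess-mortality term
# p(1-p) m (R-1) / (1 + p(R-1)).
.eq5_context <- function(prev, m_curve, mrr_curve, grid) {
  pd <- prevalence_and_derivative(prev, t = grid$t, age = grid$ages,
                                  sex = grid$sex, center = grid$center)
  m <- .eval_curve(m_curve, grid$ages)
  R <- .eval_curve(mrr_curve, grid$ages)
  if (any(R <= 0)) stop("MRR must be positive on the grid", call. = FALSE)
  p <- pd$p
  list(ages = grid$ages, p = p, dp = pd$dp,
       one_minus_p = 1 - p,
       excess = p * (1 - p) * m * (R - 1) / (1 + p * (R - 1)))
}

.eq5_value_theta <- function(theta, ctx) {
  i <- .gauss_eval(ctx$ages, theta[1L], theta[2L], exp(theta[3L]))
  r <- .gauss_eval(ctx$ages, theta[4L], theta[5L], exp(theta[6L]))
  resid <- ctx$dp - (ctx$one_minus_p * i - ctx$p * r - ctx$excess)
  sum(resid * resid)
}

#' Least-squares objective of the illness-death fit
#'
#' Sum over the evaluation ages of the squared difference between the
#' directional derivative of the fitted prevalence surface and the
#' balance-equation right-hand side implied by candidate Gaussian
#' incidence and remission curves:
#' \deqn{\sum_k \Big[ dp(a_k) - \big\{(1-p)\,i(a_k) - p\,r(a_k)
#'   - \tfrac{p(1-p)\,m(a_k)(R(a_k)-1)}{1+p(R(a_k)-1)}\big\} \Big]^2.}
#' Residuals are unweighted.
#'
#' @param params A [rate_parameter_set()].
#' @param grid An [evaluation_grid()].
#' @param prev_fit A fitted prevalence surface ([fit_logit_polynomial()])
#'   or exact oracle surface ([truth_surface()]).
#' @param m_curve General mortality: an `idm_rate_curve` or a function of
#'   age.
#' @param mrr_curve Mortality rate ratio: an `idm_rate_curve` or a
#'   function of age.
#' @return Non-negative scalar.
#' @export
eq5_objective <- function(params, grid, prev_fit, m_curve, mrr_curve) {
  stopifnot(inherits(params, "rate_parameter_set"))
  if (params$incidence$width <= 0 || params$remission$width <= 0) {
    stop("Gaussian widths must be strictly positive", call. = FALSE)
  }
  ctx <- .eq5_context(prev_fit, m_curve, mrr_curve, grid)
  .eq5_value_theta(.theta_from_params(params), ctx)
}

# Deterministic multi-start grid: incidence/remission locations from
# {20, 45, 70} and both amplitude signs; widths start at 15 y.
.default_starts <- function() {
  locs <- rbind(c(20, 45), c(20, 70), c(45, 70), c(70, 20))
  out <- matrix(NA_real_, nrow = 8L, ncol = 6L)
  k <- 0L
  for (s in c(1, -1)) for (j in seq_len(nrow(locs))) {
    k <- k + 1L
    out[k, ] <- c(s * 0.005, locs[j, 1L], log(15), s * 0.02, locs[j, 2L], log(15))
  }
  colnames(out) <- c("inc_amp", "inc_loc", "inc_logw",
                     "rem_amp", "rem_loc", "rem_logw")
  out
}

#' Estimate Gaussian incidence and remission by least squares
#'
#' Minimizes [eq5_objective()] over the six Gaussian coefficients.  Each
#' start of a deterministic multi-start grid (8 starts varying the
#' Gaussian locations and amplitude signs) is run through Nelder-Mead and
#' polished with BFGS.  Because the inverse problem is weakly identified,
#' a mirror branch with negative amplitudes can fit the smooth derivative
#' about as well as the epidemiologically admissible one; the winner is
#' therefore the lowest-objective solution with both amplitudes positive,
#' falling back to the overall lowest objective when no start ends on the
#' admissible branch, with ties breaking toward the lowest start index.
#' Widths are optimized on the log scale so they stay positive without
#' explicit bounds.  The whole procedure is deterministic.
#'
#' @inheritParams eq5_objective
#' @param control List: `starts` (matrix of start vectors
#'   `c(inc_amp, inc_loc, log inc_width, rem_amp, rem_loc, log rem_width)`;
#'   default the 8-start grid), `maxit` (Nelder-Mead iteration cap,
#'   default 2000), `reltol` (default 1e-12), `polish` (run BFGS after
#'   Nelder-Mead, default `TRUE`).
#' @return An object of class `idm_rate_estimate`: the winning
#'   [rate_parameter_set()] in `$params`, raw `$theta`, final
#'   `$objective`, `$start_selected`, and a per-start `$report` data
#'   frame (objective, convergence code, function evaluations).
#' @export
estimate_rates <- function(prev_fit, m_curve, mrr_curve, grid,
                           control = list()) {
  ctrl <- utils::modifyList(
    list(starts = NULL, maxit = 2000, reltol = 1e-12, polish = TRUE,
         parscale = c(0.005, 25, 1, 0.02, 25, 1)),
    control
  )
  starts <- if (is.null(ctrl$starts)) .default_starts() else ctrl$starts
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1L)
  stopifnot(ncol(starts) == 6L)
  ctx <- .eq5_context(prev_fit, m_curve, mrr_curve, grid)
  fn <- function(theta) .eq5_value_theta(theta, ctx)

  fits <- vector("list", nrow(starts))
  report <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn, method = "Nelder-Mead",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                                  parscale = ctrl$parscale)),
      error = function(e) NULL
    )
    if (!is.null(fit) && isTRUE(ctrl$polish)) {
      pol <- tryCatch(
        stats::optim(fit$par, fn, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14,
                                    parscale = ctrl$parscale)),
        error = function(e) NULL
      )
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= fit$value) {
        fit <- pol
      }
    }
    ok <- !is.null(fit) && all(is.finite(fit$par)) && is.finite(fit$value)
    report[[s]] <- data.frame(
      start = s,
      objective = if (ok) fit$value else NA_real_,
      admissible = if (ok) fit$par[1L] > 0 && fit$par[4L] > 0 else NA,
      convergence = if (ok) fit$convergence else NA_integer_,
      fevals = if (ok) unname(fit$counts[1L]) else NA_integer_
    )
    if (ok) {
      fit$start <- s
      fits[[s]] <- fit
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1L))]
  if (length(fits) == 0L) {
    stop("rate estimation failed to converge from every start", call. = FALSE)
  }
  # The least-squares problem is only weakly identified: solutions with
  # negative amplitudes (incidence and remission swapping roles) can fit
  # the smooth derivative as well as the epidemiologically admissible
  # branch.  Among the multi-start solutions, prefer the best one with
  # both amplitudes positive; fall back to the overall best fit when no
  # start ends on the admissible branch.  Ties go to the lowest start
  # index (the iteration order below preserves it).
  objs <- vapply(fits, function(f) f$value, numeric(1L))
  adm <- vapply(fits, function(f) f$par[1L] > 0 && f$par[4L] > 0, logical(1L))
  pick <- if (any(adm)) which(adm)[which.min(objs[adm])] else which.min(objs)
  best <- fits[[pick]]
  structure(list(params = .params_from_theta(best$par),
                 theta = stats::setNames(best$par, colnames(.default_starts())),
                 objective = best$value,
                 start_selected = best$start,
                 report = do.call(rbind, report),
                 grid = grid),
            class = "idm_rate_estimate")
}

#' @export
print.idm_rate_estimate <- function(x, ...) {
  cat(sprintf("Illness-death rate estimate (%s, %s): objective %.3g, start %d\n",
              x$grid$sex, x$grid$center, x$objective, x$start_selected))
  print(x$params)
  invisible(x)
}

.rate_params_of <- function(params) {
  if (inherits(params, "idm_rate_estimate")) params$params else params
}

#' Reporting table of age-specific rates
#'
#' Converts the fitted Gaussian curves to the reporting convention:
#' incidence per 1,000 person-years, remission per 100 person-years.
#' Negative point estimates and confidence bounds are truncated to zero
#' with a truncation flag.
#'
#' @param params A [rate_parameter_set()] or [estimate_rates()] result.
#' @param ages Reporting ages within `[19, 74]` (default 20:73).
#' @param band Optional percentile band from [percentile_band()] (natural
#'   per-person-year units; converted here).
#' @return A data frame with columns `age`, `incidence_per_1000py`,
#'   `remission_per_100py`, optional `inc_lo`/`inc_hi`/`rem_lo`/`rem_hi`,
#'   and logical truncation flags `inc_truncated`, `rem_truncated`.
#' @export
rates_table <- function(params, ages = 20:73, band = NULL) {
  if (any(ages < 19 | ages > 74)) {
    stop("'ages' must lie within [19, 74]", call. = FALSE)
  }
  pp <- .rate_params_of(params)
  inc <- gaussian_rate(ages, pp$incidence) * 1000
  rem <- gaussian_rate(ages, pp$remission) * 100
  out <- data.frame(age = ages,
                    incidence_per_1000py = pmax(inc, 0),
                    remission_per_100py = pmax(rem, 0),
                    inc_truncated = inc < 0,
                    rem_truncated = rem < 0)
  if (!is.null(band)) {
    b <- band[match(ages, band$age), , drop = FALSE]
    out$inc_lo <- pmax(b$inc_lo * 1000, 0)
    out$inc_hi <- pmax(b$inc_hi * 1000, 0)
    out$rem_lo <- pmax(b$rem_lo * 100, 0)
    out$rem_hi <- pmax(b$rem_hi * 100, 0)
    out$inc_truncated <- out$inc_truncated | b$inc_lo < 0 | b$inc_hi < 0
    out$rem_truncated <- out$rem_truncated | b$rem_lo < 0 | b$rem_hi < 0
    out <- out[, c("age", "incidence_per_1000py", "inc_lo", "inc_hi",
                   "remission_per_100py", "rem_lo", "rem_hi",
                   "inc_truncated", "rem_truncated")]
  }
  out
}

#' Peak rates over the observable age range
#'
#' Argmax of each Gaussian rate over the closed observable range.  When a
#' Gaussian's location lies outside the range the boundary age is
#' reported: a study population bounded at 74 can only report the highest
#' *observable* value there even if the true peak lies beyond.
#'
#' @inheritParams rates_table
#' @param age_range Closed observable range, default `c(19, 74)`.
#' @return Data frame with one row per rate: `rate`, `age`, `value`
#'   (per person-year) and `at_boundary`.
#' @export
find_peaks <- function(params, age_range = c(19, 74)) {
  pp <- .rate_params_of(params)
  one <- function(g, nm) {
    if (g$amplitude > 0) {
      age <- min(max(g$location, age_range[1]), age_range[2])
    } else if (g$amplitude < 0) {
      # negative bump: the maximum sits at the boundary farther from the mode
      ends <- age_range
      age <- ends[which.max(gaussian_rate(ends, g))]
    } else {
      age <- age_range[1]
    }
    data.frame(rate = nm, age = age, value = gaussian_rate(age, g),
               at_boundary = age %in% age_range &&
                 (g$location < age_range[1] || g$location > age_range[2] ||
                    g$amplitude <= 0))
  }
  rbind(one(pp$incidence, "incidence"), one(pp$remission, "remission"))
}
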