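#' Illness-death model balance equation
#'
#' Rate of change of point prevalence along a birth cohort's life line
#' (the directional derivative in time and age) as a function of the
#' transition rates of the three-state illness-death model:
#' \deqn{(\partial_t + \partial_a)\,p =
#'   (1-p)\,i - p\,r - p(1-p)(m_1 - m_0),}
#' where \eqn{i} is the incidence rate among the susceptible, \eqn{r} the
#' remission rate among the diseased, and \eqn{m_0}, \eqn{m_1} the
#' mortality rates of the susceptible and diseased.  All rates are per
#' person-year.
#'
#' @param p Point prevalence, in `[0, 1]`.
#' @param incidence,remission,m0,m1 Transition rates per person-year.
#' @return Derivative of prevalence per year (vectorized).
#' @seealso [pde_rhs_mrr()] for the form using general mortality and the
#'   mortality rate ratio; [solve_cohort_prevalence()].
#' @export
pde_rhs <- function(p, incidence, remission, m0, m1) {
  if (any(p < 0 | p > 1)) {
    stop("prevalence 'p' must lie in [0, 1]", call. = FALSE)
  }
  (1 - p) * incidence - p * remission - p * (1 - p) * (m1 - m0)
}

#' Balance equation with general mortality and mortality rate ratio
#'
#' Mortality among the susceptible, \eqn{m_0}, is rarely observed.  It can
#' be replaced by the general (whole-population) mortality rate \eqn{m} and
#' the mortality rate ratio \eqn{R = m_1/m_0} via
#' \eqn{m = (1-p)m_0 + p m_1}, giving \eqn{m_0 = m / (1 + p(R-1))} and
#' \deqn{(\partial_t + \partial_a)\,p =
#'   (1-p)\,i - p\,r - \frac{p(1-p)\,m\,(R-1)}{1 + p(R-1)}.}
#' Agrees with [pde_rhs()] exactly whenever `m` and `mrr` are computed from
#' consistent `(m0, m1, p)`.
#'
#' @inheritParams pde_rhs
#' @param m General mortality rate per person-year, `>= 0`.
#' @param mrr Mortality rate ratio \eqn{m_1/m_0}, `> 0`.
#' @return Derivative of prevalence per year (vectorized).
#' @export
pde_rhs_mrr <- function(p, incidence, remission, m, mrr) {
  if (any(p < 0 | p > 1)) {
    stop("prevalence 'p' must lie in [0, 1]", call. = FALSE)
  }
  if (any(mrr <= 0)) {
    stop("mortality rate ratio 'mrr' must be strictly positive", call. = FALSE)
  }
  (1 - p) * incidence - p * remission -
    p * (1 - p) * m * (mrr - 1) / (1 + p * (mrr - 1))
}

#' Forward cohort prevalence solver
#'
#' Integrates the cohort prevalence ODE `dp/da = pde_rhs(...)` with a
#' classical fixed-step fourth-order Runge-Kutta scheme.  With
#' time-constant rates the directional derivative along a cohort line
#' reduces to `d/da`, so this solver is the exact forward model of the
#' balance equation and serves as the ground-truth oracle for the
#' synthetic-data generator and the estimator tests.
#'
#' Mortality can be supplied either as the pair `(m0, m1)` or as the pair
#' `(m, mrr)`; each rate argument may be a constant or a function of age.
#'
#' @param p_start Prevalence at `age_start`, in `[0, 1]`.
#' @param age_start Starting age in years.
#' @param age_grid Strictly increasing ages (years) at which to report the
#'   solution; the first element must equal `age_start`.
#' @param incidence,remission Rates per person-year: constants or
#'   functions of age.
#' @param m0,m1 Mortality among susceptible/diseased (constants or
#'   functions of age); supply together.
#' @param m,mrr General mortality and mortality rate ratio (constants or
#'   functions of age); supply together as an alternative to `m0`, `m1`.
#' @param step Maximum integration step in years (default 0.1).
#' @return Numeric vector of prevalences on `age_grid`, clamped to `[0, 1]`.
#' @examples
#' # pure growth: p(a) = 1 - (1 - p0) exp(-i (a - a0))
#' solve_cohort_prevalence(0, 19, c(19, 29), incidence = 0.01,
#'                         remission = 0, m0 = 0.01, m1 = 0.01)
#' @export
solve_cohort_prevalence <- function(p_start, age_start, age_grid,
                                    incidence, remission,
                                    m0 = NULL, m1 = NULL,
                                    m = NULL, mrr = NULL,
                                    step = 0.1) {
  stopifnot(length(p_start) == 1L, p_start >= 0, p_start <= 1,
            step > 0)
  if (length(age_grid) < 1L || any(diff(age_grid) <= 0)) {
    stop("'age_grid' must be strictly increasing", call. = FALSE)
  }
  if (abs(age_grid[1L] - age_start) > 1e-9) {
    stop("'age_grid' must start at 'age_start'", call. = FALSE)
  }
  as_fun <- function(x) if (is.function(x)) x else function(a) rep_len(x, length(a))
  i_f <- as_fun(incidence)
  r_f <- as_fun(remission)
  use_mrr <- is.null(m0)
  if (use_mrr) {
    if (is.null(m) || is.null(mrr)) {
      stop("supply either (m0, m1) or (m, mrr)", call. = FALSE)
    }
    m_f <- as_fun(m); R_f <- as_fun(mrr)
    rhs <- function(a, p) pde_rhs_mrr(min(max(p, 0), 1), i_f(a), r_f(a), m_f(a), R_f(a))
  } else {
    if (is.null(m1)) stop("supply either (m0, m1) or (m, mrr)", call. = FALSE)
    m0_f <- as_fun(m0); m1_f <- as_fun(m1)
    rhs <- function(a, p) pde_rhs(min(max(p, 0), 1), i_f(a), r_f(a), m0_f(a), m1_f(a))
  }

  out <- numeric(length(age_grid))
  out[1L] <- p_start
  p <- p_start
  for (k in seq_len(length(age_grid) - 1L)) {
    a0 <- age_grid[k]
    a1 <- age_grid[k + 1L]
    nsub <- max(1L, ceiling((a1 - a0) / step - 1e-12))
    h <- (a1 - a0) / nsub
    for (s in seq_len(nsub)) {
      a <- a0 + (s - 1L) * h
      k1 <- rhs(a, p)
      k2 <- rhs(a + h / 2, p + h / 2 * k1)
      k3 <- rhs(a + h / 2, p + h / 2 * k2)
      k4 <- rhs(a + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p <- min(max(p, 0), 1)
    }
    out[k + 1L] <- p
  }
  out
}

#' Misclassification-adjusted prevalence (Rogan-Gladen)
#'
#' Corrects an apparent (screener-based) prevalence for imperfect test
#' accuracy:
#' \deqn{p_{adj} = \frac{p_{obs} + sp - 1}{se + sp - 1}.}
#' Adjusted values can fall outside `[0, 1]` when the assumed sensitivity
#' and specificity do not hold in the study population (a common failure
#' mode of screening instruments); such values are flagged invalid and
#' should not be propagated into rate estimation.
#'
#' @param p_obs Observed prevalence(s) in `[0, 1]`.
#' @param sensitivity,specificity Instrument operating characteristics in
#'   `[0, 1]`; their sum must exceed 1 (an informative instrument).
#' @return A data frame with columns `adjusted` (may be negative) and
#'   `valid` (`TRUE` iff the adjusted value lies in `[0, 1]`).
#' @examples
#' adjust_prevalence(0.20, sensitivity = 0.89, specificity = 0.82)
#' @export
adjust_prevalence <- function(p_obs, sensitivity, specificity) {
  if (any(p_obs < 0 | p_obs > 1)) {
    stop("'p_obs' must lie in [0, 1]", call. = FALSE)
  }
  if (sensitivity + specificity <= 1) {
    stop("'sensitivity' + 'specificity' must exceed 1 (uninformative instrument)",
         call. = FALSE)
  }
  adjusted <- (p_obs + specificity - 1) / (sensitivity + specificity - 1)
  data.frame(adjusted = adjusted, valid = adjusted >= 0 & adjusted <= 1)
}
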