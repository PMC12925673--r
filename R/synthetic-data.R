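#' Default synthetic-truth configuration
#'
#' Parameters of the data-generating illness-death world used throughout
#' the test-bed: Gaussian incidence and remission per (condition, sex),
#' Gompertz mortality among the susceptible per sex, a constant (or
#' age-linear) mortality rate ratio per condition, and the prevalence at
#' the entry age 19.  Rates are time-constant, so both survey
#' cross-sections share one prevalence-by-age curve and the directional
#' derivative of prevalence equals its age derivative.
#'
#' The anxiety/female stratum is the reference scenario (incidence peaking
#' at the entry age, remission peaking near the upper age bound); the
#' other strata echo the qualitative pattern of community screening data:
#' lower incidence in men, a later incidence peak and higher baseline
#' prevalence for depressive symptoms.
#'
#' @return A nested list understood by [make_truth()].
#' @export
default_truth_config <- function() {
  list(
    age_range = c(19, 74),
    conditions = list(
      anxiety = list(
        female = list(incidence = c(amplitude = 0.004, location = 20, width = 18),
                      remission = c(amplitude = 0.04, location = 72, width = 20),
                      p_start = 0.05),
        male = list(incidence = c(amplitude = 0.0027, location = 20, width = 18),
                    remission = c(amplitude = 0.04, location = 72, width = 20),
                    p_start = 0.035)
      ),
      depression = list(
        female = list(incidence = c(amplitude = 0.0044, location = 30, width = 18),
                      remission = c(amplitude = 0.055, location = 74, width = 20),
                      p_start = 0.07),
        male = list(incidence = c(amplitude = 0.0033, location = 31, width = 18),
                    remission = c(amplitude = 0.055, location = 74, width = 20),
                    p_start = 0.05)
      )
    ),
    mortality = list(female = c(intercept = 1e-4, slope = 0.09),
                     male = c(intercept = 1e-4, slope = 0.09)),
    mrr = list(anxiety = c(base = 2, age_slope = 0),
               depression = c(base = 2, age_slope = 0))
  )
}

#' Build a synthetic ground truth
#'
#' Derives, for every (condition, sex) stratum of the configuration, the
#' prevalence-by-age curve implied by the configured rates, by running the
#' forward cohort solver [solve_cohort_prevalence()] on a 0.1-year grid
#' from the entry age.  The construction is deterministic given the
#' configuration.
#'
#' @param config A configuration list as returned by
#'   [default_truth_config()].
#' @return An object of class `idm_truth` holding, per stratum, the rate
#'   parameters, mortality and MRR functions, the fine-grid prevalence
#'   curve and the implied general mortality.
#' @export
make_truth <- function(config = default_truth_config()) {
  rng <- config$age_range
  stopifnot(length(rng) == 2L, rng[1] < rng[2])
  grid <- seq(rng[1], rng[2], by = 0.1)
  strata <- list()
  for (cond in names(config$conditions)) {
    mrr_cfg <- config$mrr[[cond]]
    if (is.null(mrr_cfg)) stop("no MRR configured for condition '", cond, "'")
    R_f <- local({
      base <- unname(mrr_cfg["base"]); sl <- unname(mrr_cfg["age_slope"])
      a0 <- rng[1]
      function(a) base + sl * (a - a0)
    })
    if (any(R_f(grid) <= 0)) {
      stop("configured MRR must stay positive over the age range", call. = FALSE)
    }
    for (sex in names(config$conditions[[cond]])) {
      blk <- config$conditions[[cond]][[sex]]
      mort <- config$mortality[[sex]]
      if (is.null(mort)) stop("no mortality configured for sex '", sex, "'")
      if (unname(mort["intercept"]) < 0) {
        stop("Gompertz intercept must be non-negative", call. = FALSE)
      }
      m0_f <- local({
        ic <- unname(mort["intercept"]); sl <- unname(mort["slope"]); a0 <- rng[1]
        function(a) ic * exp(sl * (a - a0))
      })
      params <- rate_parameter_set(
        do.call(gaussian_rate_params, as.list(blk$incidence)),
        do.call(gaussian_rate_params, as.list(blk$remission))
      )
      p0 <- blk$p_start
      if (p0 < 0 || p0 > 1) stop("p_start must lie in [0, 1]", call. = FALSE)
      i_f <- function(a) gaussian_rate(a, params$incidence)
      r_f <- function(a) gaussian_rate(a, params$remission)
      m1_f <- function(a) R_f(a) * m0_f(a)
      p <- solve_cohort_prevalence(p0, rng[1], grid, i_f, r_f,
                                   m0 = m0_f, m1 = m1_f)
      if (any(p < 0 | p > 1)) {
        stop("configuration produces prevalence outside [0, 1]", call. = FALSE)
      }
      strata[[paste(cond, sex, sep = ".")]] <- list(
        condition = cond, sex = sex,
        params = params, p_start = p0,
        m0 = m0_f, m1 = m1_f, mrr = R_f,
        ages = grid, p = p,
        # whole-population mortality implied by this stratum's prevalence
        m_general = (1 - p) * m0_f(grid) + p * m1_f(grid)
      )
    }
  }
  structure(list(config = config, age_range = rng, strata = strata),
            class = "idm_truth")
}

#' @export
print.idm_truth <- function(x, ...) {
  cat("Synthetic illness-death truth:", length(x$strata), "strata on ages",
      x$age_range[1], "-", x$age_range[2], "\n")
  invisible(x)
}

.truth_stratum <- function(truth, condition, sex) {
  key <- paste(condition, sex, sep = ".")
  st <- truth$strata[[key]]
  if (is.null(st)) {
    stop("truth has no stratum for condition '", condition, "', sex '", sex, "'",
         call. = FALSE)
  }
  st
}

#' True prevalence at given ages
#'
#' Linear interpolation of the stored fine-grid (0.1 y) truth curve.
#'
#' @param truth An [make_truth()] object.
#' @param age Ages in years within the truth's age range.
#' @param condition,sex Stratum selectors.
#' @export
truth_prevalence <- function(truth, age, condition, sex) {
  st <- .truth_stratum(truth, condition, sex)
  stats::approx(st$ages, st$p, xout = age, rule = 2)$y
}

#' Exact prevalence surface of a synthetic truth
#'
#' Wraps one truth stratum as a prevalence surface usable wherever a
#' fitted [fit_logit_polynomial()] surface is expected: `p` comes from a
#' spline through the fine-grid solution and the directional derivative is
#' evaluated exactly through the balance equation with the true rates
#' (rates are time-constant, so the time component is zero).  This is the
#' "no sampling" oracle used to validate the estimator.
#'
#' @inheritParams truth_prevalence
#' @return An object of class `idm_truth_surface`.
#' @export
truth_surface <- function(truth, condition, sex) {
  st <- .truth_stratum(truth, condition, sex)
  pfun <- stats::splinefun(st$ages, st$p, method = "natural")
  structure(list(condition = condition, sex = sex, stratum = st, pfun = pfun),
            class = "idm_truth_surface")
}

#' @rdname prevalence_and_derivative
#' @export
prevalence_and_derivative.idm_truth_surface <- function(object, t, age,
                                                        sex = NULL, center = NULL,
                                                        ...) {
  st <- object$stratum
  p <- pmin(pmax(object$pfun(age), 0), 1)
  dp <- pde_rhs(p,
                gaussian_rate(age, st$params$incidence),
                gaussian_rate(age, st$params$remission),
                st$m0(age), st$m1(age))
  list(p = p, dp = dp)
}

#' Tabulated Gompertz mortality fixture
#'
#' Life-table-style general mortality rates
#' `m(a) = intercept * exp(slope * (a - min(ages)))` at integer ages, the
#' shape of the national life tables the analysis consumes.
#'
#' @param intercept Rate per person-year at the youngest tabulated age;
#'   must be non-negative.
#' @param slope Log-linear increase per year of age.
#' @param ages Integer ages to tabulate (default 19:74).
#' @param sex Label stored with the table.
#' @return A data frame with columns `age`, `sex`, `rate`.
#' @export
make_mortality_table <- function(intercept, slope, ages = 19:74, sex = "female") {
  if (intercept < 0) stop("'intercept' must be non-negative", call. = FALSE)
  if (any(diff(ages) <= 0)) stop("'ages' must be strictly increasing", call. = FALSE)
  data.frame(age = ages, sex = sex,
             rate = intercept * exp(slope * (ages - ages[1L])))
}

#' Tabulated mortality-rate-ratio fixture
#'
#' Age-linear ratio `R(a) = base + age_slope * (a - min(ages))` at integer
#' ages, the shape of register-based disease-mortality atlases.
#'
#' @param base Ratio at the youngest tabulated age.
#' @param age_slope Change in the ratio per year of age.
#' @param ages Integer ages to tabulate (default 19:74).
#' @param condition Label stored with the curve.
#' @return A data frame with columns `age`, `condition`, `ratio`.
#' @export
make_mrr_curve <- function(base, age_slope = 0, ages = 19:74,
                           condition = "anxiety") {
  ratio <- base + age_slope * (ages - ages[1L])
  if (any(ratio <= 0)) {
    stop("configured MRR must be strictly positive at all ages", call. = FALSE)
  }
  data.frame(age = ages, condition = condition, ratio = ratio)
}

#' Survey period calendar midpoints
#'
#' The two recruitment windows are treated as cross-sections anchored at
#' their calendar midpoints.
#' @return Named numeric vector, midpoints of periods 1 and 2.
#' @export
period_midpoints <- function() c(`1` = 2015.5, `2` = 2018.5)

#' Draw a synthetic two-cross-section study
#'
#' Emulates the structure of a multicentre baseline survey analyzed as two
#' cross-sections: for each (center, sex, period) stratum, ages are drawn
#' uniformly on the integer age range, binary case status per condition is
#' Bernoulli with the truth's age-specific prevalence, correction weights
#' are Gamma-distributed with mean 1, and case status is set to missing
#' completely at random at the given rate.
#'
#' @param truth An [make_truth()] object.
#' @param n_per_stratum Participants per (center, sex, period) stratum.
#' @param centers Character vector of study-center labels (default the
#'   five-center layout).
#' @param sexes Subset of `c("female", "male")`.
#' @param periods Subset of `c(1, 2)`.
#' @param missingness Probability that a case indicator is missing, in
#'   `[0, 1)`, applied independently per condition.
#' @param weight_dispersion Variance of the mean-1 Gamma weights; 0 gives
#'   unit weights.
#' @param seed Integer seed; the draw is reproducible given it.
#' @return A participant data frame with columns `age`, `sex`, `center`,
#'   `period`, `weight`, and one `case_*` column per configured condition
#'   (`NA` = missing).
#' @export
sample_study <- function(truth, n_per_stratum,
                         centers = c("Augsburg", "Freiburg", "Muenster",
                                     "Berlin", "Hamburg"),
                         sexes = c("female", "male"),
                         periods = c(1, 2),
                         missingness = 0,
                         weight_dispersion = 0.2,
                         seed = 1L) {
  stopifnot(n_per_stratum >= 1, missingness >= 0, missingness < 1,
            weight_dispersion >= 0)
  if (length(centers) == 0L || length(sexes) == 0L || length(periods) == 0L) {
    stop("strata specification must be non-empty", call. = FALSE)
  }
  conds <- names(truth$config$conditions)
  rng <- truth$age_range
  ages_pool <- seq(ceiling(rng[1]), floor(rng[2]))
  set.seed(as.integer(seed))
  out <- vector("list", length(centers) * length(sexes) * length(periods))
  k <- 0L
  for (ct in centers) for (sx in sexes) for (pe in periods) {
    k <- k + 1L
    age <- sample(ages_pool, n_per_stratum, replace = TRUE)
    w <- if (weight_dispersion > 0) {
      stats::rgamma(n_per_stratum, shape = 1 / weight_dispersion,
                    scale = weight_dispersion)
    } else rep(1, n_per_stratum)
    df <- data.frame(age = age, sex = sx, center = ct, period = pe, weight = w)
    for (cond in conds) {
      p <- truth_prevalence(truth, age, cond, sx)
      cs <- stats::rbinom(n_per_stratum, 1L, p)
      if (missingness > 0) {
        cs[stats::runif(n_per_stratum) < missingness] <- NA_integer_
      }
      df[[paste0("case_", substr(cond, 1, 3))]] <- cs
    }
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.case_column <- function(records, condition) {
  col <- paste0("case_", substr(condition, 1, 3))
  if (!col %in% names(records)) {
    stop("records have no case column for condition '", condition, "'",
         call. = FALSE)
  }
  col
}

#' Read / write participant tables
#'
#' Participant records travel as headered CSV with columns
#' `age,sex,center,period,weight,case_anx,case_dep` (missing case status =
#' empty field).
#'
#' @param path File path.
#' @param records A participant data frame.
#' @name participants_io
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("age", "sex", "center", "period", "weight")
  if (!all(req %in% names(df))) {
    stop("participant file lacks required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname participants_io
#' @export
write_participants <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write mortality tables and MRR curves
#'
#' Life tables travel as CSV `age,sex,rate`; mortality-rate-ratio curves
#' as CSV `age,condition,ratio`.
#'
#' @param path File path.
#' @param table,curve Data frames as produced by [make_mortality_table()]
#'   and [make_mrr_curve()].
#' @name rates_io
#' @export
read_mortality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "rate") %in% names(df))) {
    stop("mortality file needs columns 'age' and 'rate'", call. = FALSE)
  }
  df
}

#' @rdname rates_io
#' @export
write_mortality_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname rates_io
#' @export
read_mrr_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "ratio") %in% names(df))) {
    stop("MRR file needs columns 'age' and 'ratio'", call. = FALSE)
  }
  df
}

#' @rdname rates_io
#' @export
write_mrr_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
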