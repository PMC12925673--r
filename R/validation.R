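#' Exact-prevalence cells from a synthetic truth
#'
#' Builds an [aggregate_cells()]-shaped table whose cell prevalences are
#' the truth's exact age-specific prevalences (no sampling), with a large
#' common weighted total.  Fitting the logit-polynomial surface to these
#' cells isolates the polynomial's approximation error from sampling
#' noise.
#'
#' @inheritParams truth_prevalence
#' @param center Center label to stamp on the cells.
#' @param wtot Weighted total per cell (default 1e6; only the relative
#'   weights matter for the fit).
#' @return A cell table with both survey periods at integer ages.
#' @export
exact_truth_cells <- function(truth, condition = "anxiety", sex = "female",
                              center = "Hamburg", wtot = 1e6) {
  ages <- seq(ceiling(truth$age_range[1]), floor(truth$age_range[2]))
  p <- truth_prevalence(truth, ages, condition, sex)
  mids <- period_midpoints()
  do.call(rbind, lapply(c(1L, 2L), function(pe) {
    data.frame(center = center, sex = sex, period = pe, age = ages,
               wcase = p * wtot, wtot = wtot, n = as.integer(wtot),
               t = unname(mids[as.character(pe)]),
               stringsAsFactors = FALSE)
  }))
}

#' Infinite-data surface scan over polynomial degrees
#'
#' The logit-polynomial surface is a nuisance model: the rate estimator
#' consumes its *derivative*, and a polynomial that predicts prevalence
#' well can still attenuate the derivative and bias the recovered
#' Gaussian peaks.  This scan quantifies that approximation bias free of
#' sampling noise: for each candidate df it fits the surface to the
#' truth's exact prevalences ([exact_truth_cells()]), runs the
#' least-squares rate estimation with the truth's exact mortality inputs,
#' and reports the error in the recovered incidence peak.
#'
#' The attribute `"recommended"` holds the smallest df whose
#' infinite-data peak-age error is at most `age_tol` years and whose peak
#' amplitude error is at most `amp_tol` (relative) - i.e. the most
#' parsimonious surface whose approximation bias is small against
#' sampling variability.  Recovery experiments should fit at that df.
#'
#' @inheritParams exact_truth_cells
#' @param candidate_dfs Degrees to scan (default 2:6).
#' @param age_tol,amp_tol Bias tolerances defining the recommended df
#'   (defaults 2 years and 10% relative).
#' @return Data frame with one row per df: recovered incidence peak age
#'   and amplitude, their errors against the truth, and the final
#'   objective; attribute `"recommended"` as described (NA when no
#'   scanned df qualifies).
#' @export
noiseless_df_scan <- function(truth, condition = "anxiety", sex = "female",
                              candidate_dfs = 2:6, age_tol = 2,
                              amp_tol = 0.1) {
  st <- .truth_stratum(truth, condition, sex)
  cells <- exact_truth_cells(truth, condition, sex)
  m_fun <- local({
    ages <- st$ages; mg <- st$m_general
    function(a) stats::approx(ages, mg, xout = a, rule = 2)$y
  })
  grid <- evaluation_grid(sex, cells$center[1L])
  true_pk <- find_peaks(st$params, age_range = truth$age_range)
  rows <- lapply(candidate_dfs, function(df) {
    fit <- fit_logit_polynomial(cells = cells, condition = condition, df = df)
    est <- estimate_rates(fit, m_fun, st$mrr, grid)
    pk <- find_peaks(est, age_range = truth$age_range)
    data.frame(df = df,
               peak_age = pk$age[1L],
               peak_amp = pk$value[1L],
               peak_age_error = pk$age[1L] - true_pk$age[1L],
               amp_rel_error = pk$value[1L] / true_pk$value[1L] - 1,
               objective = est$objective)
  })
  out <- do.call(rbind, rows)
  ok <- abs(out$peak_age_error) <= age_tol & abs(out$amp_rel_error) <= amp_tol
  attr(out, "recommended") <- if (any(ok)) out$df[which(ok)[1L]] else NA_integer_
  out
}
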