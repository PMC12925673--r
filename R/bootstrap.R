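#' Nonparametric bootstrap of the full estimation pipeline
#'
#' For each replicate, participants are resampled with replacement within
#' (center, period) strata - preserving the two-cross-section design -
#' carrying their survey weights; complete-case filtering, the prevalence
#' fit (at a fixed, not re-selected, df) and the least-squares rate
#' estimation are then re-run.  Replicate seeds are derived from the
#' master seed by a counter-based scheme, so replicates are mutually
#' independent and the result does not depend on execution order.
#'
#' By default each replicate's optimizer is warm-started at the point
#' estimate (a single start): replicates perturb the data only slightly,
#' and the warm start keeps them on the point estimate's solution branch
#' at a fraction of the multi-start cost.  Pass `control$starts = NULL`
#' explicitly via `control = list(starts = NULL)` to force the full
#' multi-start search per replicate.
#'
#' @param records Participant data frame.
#' @param condition Condition analyzed.
#' @param df Age-polynomial df, fixed across replicates.
#' @param m_curve,mrr_curve Smooth mortality and MRR inputs (curves or
#'   functions of age).
#' @param grid [evaluation_grid()] for the stratum of interest.
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param seed Master seed.
#' @param point Optional point estimate ([estimate_rates()] result) used
#'   for the warm start; computed internally when omitted.
#' @param age_sex_interaction Passed to [fit_logit_polynomial()].
#' @param control Optimizer control per replicate (see
#'   [estimate_rates()]); default warm start, `maxit = 500`.
#' @param max_fail Maximum tolerated fraction of non-converged replicates
#'   (default 0.2) before an error is raised.
#' @param resample_fn Internal hook: function `(n) -> indices` replacing
#'   the within-stratum resampler (used for identity-resample checks).
#' @return An object of class `idm_bootstrap`: matrices `incidence` and
#'   `remission` (`n_converged x length(ages)`, per person-year), `theta`
#'   per replicate, `ages`, counts and the master `seed`.
#' @export
bootstrap_rates <- function(records, condition, df, m_curve, mrr_curve, grid,
                            B = 200, seed = 1L, point = NULL,
                            age_sex_interaction = TRUE,
                            control = NULL, max_fail = 0.2,
                            resample_fn = NULL) {
  stopifnot(B >= 1)
  if (is.null(point)) {
    pf <- fit_logit_polynomial(records, condition, df,
                               age_sex_interaction = age_sex_interaction)
    point <- estimate_rates(pf, m_curve, mrr_curve, grid)
  }
  if (is.null(control)) {
    control <- list(starts = matrix(point$theta, nrow = 1L), maxit = 500)
  }
  strata <- split(seq_len(nrow(records)),
                  interaction(records$center, records$period, drop = TRUE))
  ages <- grid$ages

  # Precompute everything that is invariant across replicates: the cell
  # assignment of every record, the cell-level design matrix, the grid
  # design matrices feeding the objective, and the smooth mortality
  # inputs.  Per replicate only the weighted cell totals change.
  col <- .case_column(records, condition)
  case <- records[[col]]
  w_eff <- records$weight * !is.na(case)          # complete-case weight
  wcase_eff <- ifelse(is.na(case), 0, records$weight * case)
  cell_f <- interaction(records$center, records$sex, records$period,
                        records$age, drop = TRUE)
  lev <- do.call(rbind, strsplit(levels(cell_f), ".", fixed = TRUE))
  mids <- period_midpoints()
  cell_meta <- data.frame(center = lev[, 1L], sex = lev[, 2L],
                          period = as.integer(lev[, 3L]),
                          age = as.numeric(lev[, 4L]),
                          stringsAsFactors = FALSE)
  cell_meta$t <- unname(mids[as.character(cell_meta$period)])
  meta <- .pm_meta(cell_meta, df, age_sex_interaction)
  X_cells <- .pm_design(meta, cell_meta$t, cell_meta$age, cell_meta$sex,
                        cell_meta$center)
  X_grid <- .pm_design(meta, grid$t, ages, grid$sex, grid$center)
  dX_grid <- .pm_design_deriv(meta, grid$t, ages, grid$sex, grid$center)
  m_g <- .eval_curve(m_curve, ages)
  R_g <- .eval_curve(mrr_curve, ages)
  beta0 <- NULL    # GLM warm start, refreshed each converged replicate
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12,
                                 parscale = c(0.005, 25, 1, 0.02, 25, 1)),
                            control[setdiff(names(control), "starts")])
  starts <- control$starts

  inc <- matrix(NA_real_, nrow = B, ncol = length(ages))
  rem <- matrix(NA_real_, nrow = B, ncol = length(ages))
  theta <- matrix(NA_real_, nrow = B, ncol = 6L)
  ok <- logical(B)
  for (b in seq_len(B)) {
    set.seed(.replicate_seed(seed, b))
    idx <- if (is.null(resample_fn)) {
      unlist(lapply(strata, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    } else {
      resample_fn(nrow(records))
    }
    est <- tryCatch({
      wtot_b <- rowsum(w_eff[idx], cell_f[idx])
      wcase_b <- rowsum(wcase_eff[idx], cell_f[idx])
      keep <- match(rownames(wtot_b), levels(cell_f))
      keep <- keep[wtot_b > 0]
      yb <- wcase_b[wtot_b > 0] / wtot_b[wtot_b > 0]
      glm_b <- .pm_glm(X_cells[keep, , drop = FALSE], yb * wtot_b[wtot_b > 0],
                       wtot_b[wtot_b > 0], start = beta0)
      if (!glm_b$converged || any(!is.finite(glm_b$coefficients))) {
        stop("replicate prevalence fit did not converge")
      }
      eta <- drop(X_grid %*% glm_b$coefficients)
      p <- stats::plogis(eta)
      ctx <- list(ages = ages, p = p,
                  dp = p * (1 - p) * drop(dX_grid %*% glm_b$coefficients),
                  one_minus_p = 1 - p,
                  excess = p * (1 - p) * m_g * (R_g - 1) / (1 + p * (R_g - 1)))
      fn <- function(th) .eq5_value_theta(th, ctx)
      th0 <- if (is.null(starts)) point$theta else starts[1L, ]
      opt <- stats::optim(th0, fn, method = "Nelder-Mead",
                          control = list(maxit = ctrl$maxit,
                                         reltol = ctrl$reltol,
                                         parscale = ctrl$parscale))
      list(theta = opt$par, beta = glm_b$coefficients)
    }, error = function(e) NULL)
    if (!is.null(est) && all(is.finite(est$theta))) {
      ok[b] <- TRUE
      beta0 <- est$beta
      theta[b, ] <- est$theta
      inc[b, ] <- .gauss_eval(ages, est$theta[1L], est$theta[2L], exp(est$theta[3L]))
      rem[b, ] <- .gauss_eval(ages, est$theta[4L], est$theta[5L], exp(est$theta[6L]))
    }
  }
  n_conv <- sum(ok)
  if ((B - n_conv) / B > max_fail) {
    stop(sprintf("bootstrap: %d of %d replicates failed to converge",
                 B - n_conv, B), call. = FALSE)
  }
  structure(list(ages = ages,
                 incidence = inc[ok, , drop = FALSE],
                 remission = rem[ok, , drop = FALSE],
                 theta = theta[ok, , drop = FALSE],
                 n_requested = B, n_converged = n_conv,
                 seed = seed, point = point),
            class = "idm_bootstrap")
}

# counter-based replicate seed; independent of execution order, < 2^31
.replicate_seed <- function(seed, b) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(b)) %% 2147483647)
}

#' @export
print.idm_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d/%d converged replicates on %d ages (seed %d)\n",
              x$n_converged, x$n_requested, length(x$ages), x$seed))
  invisible(x)
}

#' Percentile confidence band from a bootstrap ensemble
#'
#' Per age, the empirical `(1-level)/2` and `1-(1-level)/2` quantiles of
#' the replicate incidence and remission rates (quantile type 7, R's
#' default continuous-sample quantile).  Negative bounds are truncated to
#' zero after the percentile computation; the untruncated band is kept in
#' attribute `"raw"`.
#'
#' @param ensemble An [bootstrap_rates()] ensemble with at least 2
#'   converged replicates.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return Data frame `age`, `inc_lo`, `inc_hi`, `rem_lo`, `rem_hi` in
#'   per-person-year units.
#' @export
percentile_band <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "idm_bootstrap"))
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)", call. = FALSE)
  if (ensemble$n_converged < 2L) {
    stop("need at least 2 converged replicates", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- function(mat) apply(mat, 2L, stats::quantile, probs = probs,
                            names = FALSE, type = 7)
  qi <- qs(ensemble$incidence)
  qr <- qs(ensemble$remission)
  raw <- data.frame(age = ensemble$ages,
                    inc_lo = qi[1L, ], inc_hi = qi[2L, ],
                    rem_lo = qr[1L, ], rem_hi = qr[2L, ])
  out <- raw
  for (cl in c("inc_lo", "inc_hi", "rem_lo", "rem_hi")) {
    out[[cl]] <- pmax(out[[cl]], 0)
  }
  attr(out, "raw") <- raw
  out
}
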