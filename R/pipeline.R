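#' Default analysis configuration
#'
#' A single configuration list drives the whole analysis.  Exactly one of
#' `synthetic` (generate a study with known truth) or `input` (paths to
#' participant, mortality and MRR files) must be present.
#'
#' @param seed Master seed; every random draw in the run flows from it.
#' @return A configuration list for [run_study_analysis()].
#' @export
default_analysis_config <- function(seed = 1L) {
  list(
    synthetic = list(
      truth_config = default_truth_config(),
      n_per_stratum = 2000,
      centers = c("Augsburg", "Freiburg", "Muenster", "Berlin", "Hamburg"),
      sexes = c("female", "male"),
      missingness = 0.06,
      weight_dispersion = 0.2
    ),
    input = NULL,
    conditions = c("anxiety", "depression"),
    df = NULL,                 # NULL = select by LOOCV
    df_candidates = 1:5,
    age_sex_interaction = TRUE,
    grid_ages = 20:73,
    eval_time = 2017,
    B = 0,                     # 0 = no confidence bands
    mrr_perturb = NULL,        # e.g. c(0.85, 1.15)
    seed = as.integer(seed)
  )
}

#' Run the full incidence/remission analysis
#'
#' Orchestrates the pipeline end to end: obtain participant records
#' (synthetic draw or file input), fit the smooth mortality and MRR
#' curves, then per condition select/fix the age-polynomial df, fit the
#' prevalence surface, and per (sex, center) stratum estimate the
#' Gaussian rates, extract peaks, build the reporting table, optionally
#' bootstrap confidence bands, and optionally re-estimate under MRR
#' perturbation factors.  The run log records the seed, the selected df,
#' convergence and truncation counts, and replicate failures.
#'
#' @param config Configuration list (see [default_analysis_config()]).
#' @return An output bundle (class `idm_bundle`): `config`, `results` (a
#'   nested list per condition and stratum), and `log` (character).
#' @export
run_study_analysis <- function(config = default_analysis_config()) {
  if (is.null(config$synthetic) == is.null(config$input)) {
    stop("exactly one of 'synthetic' or 'input' must be configured",
         call. = FALSE)
  }
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    invisible(msg)
  }
  say("seed: %d", config$seed)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    truth <- make_truth(sy$truth_config)
    records <- sample_study(truth, sy$n_per_stratum, centers = sy$centers,
                            sexes = sy$sexes,
                            missingness = sy$missingness,
                            weight_dispersion = sy$weight_dispersion,
                            seed = config$seed)
    say("synthetic study: %d records (%d per stratum)", nrow(records),
        sy$n_per_stratum)
  } else {
    records <- read_participants(config$input$participants)
    say("loaded %d participant records", nrow(records))
  }

  sexes <- sort(unique(records$sex))
  centers <- sort(unique(records$center))
  conditions <- config$conditions

  # smooth mortality input per (condition, sex); MRR per condition
  m_curves <- list()
  mrr_curves <- list()
  for (cond in conditions) {
    if (!is.null(truth)) {
      mrr_cfg <- truth$config$mrr[[cond]]
      mrr_tab <- make_mrr_curve(unname(mrr_cfg["base"]),
                                unname(mrr_cfg["age_slope"]),
                                condition = cond)
    } else {
      mrr_tab <- read_mrr_curve(config$input$mrr[[cond]])
    }
    mrr_curves[[cond]] <- fit_mrr(mrr_tab)
    for (sx in sexes) {
      if (!is.null(truth)) {
        st <- .truth_stratum(truth, cond, sx)
        ia <- st$ages %in% 19:74
        m_tab <- data.frame(age = st$ages[ia], sex = sx,
                            rate = st$m_general[ia])
      } else {
        m_tab <- read_mortality_table(config$input$mortality[[sx]])
        if ("sex" %in% names(m_tab)) m_tab <- m_tab[m_tab$sex == sx, ]
      }
      m_curves[[paste(cond, sx, sep = ".")]] <- fit_log_mortality(m_tab)
    }
  }

  results <- list()
  for (cond in conditions) {
    cells <- aggregate_cells(records, cond)
    if (is.null(config$df)) {
      df <- select_df_loocv(cells = cells, candidate_dfs = config$df_candidates,
                            age_sex_interaction = config$age_sex_interaction)
      say("%s: LOOCV selected df = %d", cond, df)
    } else {
      df <- config$df
      say("%s: df fixed at %d", cond, df)
    }
    fit <- fit_logit_polynomial(cells = cells, condition = cond, df = df,
                                age_sex_interaction = config$age_sex_interaction)
    strata_out <- list()
    for (sx in sexes) for (ct in centers) {
      grid <- evaluation_grid(sx, ct, ages = config$grid_ages,
                              t = config$eval_time)
      m_curve <- m_curves[[paste(cond, sx, sep = ".")]]
      mrr_curve <- mrr_curves[[cond]]
      est <- estimate_rates(fit, m_curve, mrr_curve, grid)
      say("%s %s/%s: objective %.3g (start %d)", cond, sx, ct,
          est$objective, est$start_selected)
      band <- NULL
      if (config$B > 0) {
        ens <- bootstrap_rates(records, cond, df, m_curve, mrr_curve, grid,
                               B = config$B, seed = config$seed, point = est,
                               age_sex_interaction = config$age_sex_interaction)
        say("%s %s/%s: bootstrap %d/%d replicates converged", cond, sx, ct,
            ens$n_converged, ens$n_requested)
        band <- percentile_band(ens)
      }
      tab <- rates_table(est, ages = config$grid_ages, band = band)
      say("%s %s/%s: %d incidence / %d remission ages truncated", cond, sx, ct,
          sum(tab$inc_truncated), sum(tab$rem_truncated))
      sens <- NULL
      if (length(config$mrr_perturb)) {
        rows <- list(cbind(factor = 1, rates_table(est, ages = config$grid_ages)))
        warm <- list(starts = matrix(est$theta, nrow = 1L), maxit = 1000)
        for (fc in config$mrr_perturb) {
          est_f <- estimate_rates(fit, m_curve, perturb_mrr(mrr_curve, fc),
                                  grid, control = warm)
          rows[[length(rows) + 1L]] <-
            cbind(factor = fc, rates_table(est_f, ages = config$grid_ages))
        }
        sens <- do.call(rbind, rows)
        say("%s %s/%s: MRR sensitivity run for factors %s", cond, sx, ct,
            paste(config$mrr_perturb, collapse = ", "))
      }
      strata_out[[paste(sx, ct, sep = "|")]] <- list(
        sex = sx, center = ct, estimate = est,
        peaks = find_peaks(est), table = tab, band = band, sensitivity = sens
      )
    }
    results[[cond]] <- list(df = df, prevalence_fit = fit, strata = strata_out)
  }
  structure(list(config = config, results = results, log = log),
            class = "idm_bundle")
}

#' @export
print.idm_bundle <- function(x, ...) {
  cat("Illness-death analysis bundle:",
      paste(names(x$results), collapse = ", "), "\n")
  for (ln in x$log) cat(" ", ln, "\n")
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Emits a deterministic file set into `dir`:
#' `rates_<condition>_<sex>_<center>.csv` (reporting table, with CI
#' columns when bootstrapped), `params_<condition>_<sex>_<center>.json`
#' (the six Gaussian coefficients, objective and df),
#' `sensitivity_<condition>_<sex>_<center>.csv` (when MRR perturbation
#' factors were configured), `run_log.txt` and `config_echo.yaml`.
#' An already-populated directory is refused unless `force = TRUE`.
#'
#' @param bundle A [run_study_analysis()] bundle.
#' @param dir Output directory (created if absent).
#' @param force Overwrite a previous run's outputs?
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(bundle, dir, force = FALSE) {
  stopifnot(inherits(bundle, "idm_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sentinel <- file.path(dir, "run_log.txt")
  if (file.exists(sentinel) && !force) {
    stop("output directory already holds a run; use force = TRUE to overwrite",
         call. = FALSE)
  }
  paths <- character()
  emit <- function(path) paths <<- c(paths, path)
  for (cond in names(bundle$results)) {
    res <- bundle$results[[cond]]
    for (st in res$strata) {
      stem <- paste(cond, st$sex, st$center, sep = "_")
      p <- file.path(dir, paste0("rates_", stem, ".csv"))
      utils::write.csv(st$table, p, row.names = FALSE); emit(p)
      p <- file.path(dir, paste0("params_", stem, ".json"))
      jsonlite::write_json(
        list(condition = cond, sex = st$sex, center = st$center,
             df = res$df,
             incidence = st$estimate$params$incidence[c("amplitude", "location", "width")],
             remission = st$estimate$params$remission[c("amplitude", "location", "width")],
             objective = st$estimate$objective),
        p, auto_unbox = TRUE, digits = NA)
      emit(p)
      if (!is.null(st$sensitivity)) {
        p <- file.path(dir, paste0("sensitivity_", stem, ".csv"))
        utils::write.csv(st$sensitivity, p, row.names = FALSE); emit(p)
      }
    }
  }
  writeLines(bundle$log, sentinel); emit(sentinel)
  p <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(bundle$config, p); emit(p)
  invisible(paths)
}
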