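# Shared fixtures: built once per test run, all generated in code.

# default synthetic world (the reference study conditions)
truth_default <- make_truth()

# a constant-prevalence world: no flows, no excess mortality
flat_truth <- function(p0 = 0.10) {
  cfg <- default_truth_config()
  cfg$conditions <- list(anxiety = list(
    female = list(incidence = c(amplitude = 0, location = 40, width = 10),
                  remission = c(amplitude = 0, location = 40, width = 10),
                  p_start = p0),
    male = list(incidence = c(amplitude = 0, location = 40, width = 10),
                remission = c(amplitude = 0, location = 40, width = 10),
                p_start = p0)
  ))
  cfg$mrr <- list(anxiety = c(base = 1, age_slope = 0))
  make_truth(cfg)
}

# smooth mortality/MRR inputs for one truth stratum, as the pipeline
# would fit them from tabulated inputs
stratum_mortality_curve <- function(truth, condition = "anxiety",
                                    sex = "female") {
  st <- truth$strata[[paste(condition, sex, sep = ".")]]
  fit_log_mortality(data.frame(
    age = 19:74, sex = sex,
    rate = stats::approx(st$ages, st$m_general, 19:74)$y
  ))
}

# exact (not fitted) general-mortality function of one truth stratum
stratum_m_fun <- function(truth, condition = "anxiety", sex = "female") {
  st <- truth$strata[[paste(condition, sex, sep = ".")]]
  local({
    ages <- st$ages; mg <- st$m_general
    function(a) stats::approx(ages, mg, xout = a, rule = 2)$y
  })
}

# binomial cells drawn from an exactly polynomial logit-age truth
# (single stratum); used for the cross-validation selection checks
cells_from_logit_poly <- function(seed, beta, n_per_age = 900) {
  set.seed(seed)
  ages <- 19:74
  ac <- ages - 46.5
  eta <- beta[1] + beta[2] * ac + beta[3] * ac^2 + beta[4] * ac^3
  p <- stats::plogis(eta)
  data.frame(center = "A", sex = "female", period = 1L, age = ages,
             wcase = stats::rbinom(length(ages), n_per_age, p),
             wtot = n_per_age, n = n_per_age, t = 2015.5,
             stringsAsFactors = FALSE)
}
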