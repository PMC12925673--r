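test_that("evaluation grid validates its ages", {
  expect_error(evaluation_grid("female", "Berlin", ages = c(30, 25)),
               "increasing")
  expect_error(evaluation_grid("female", "Berlin", ages = c(10, 30)),
               "observable")
})

test_that("the objective vanishes at the generating truth", {
  st <- truth_default$strata[["anxiety.female"]]
  surf <- truth_surface(truth_default, "anxiety", "female")
  grid <- evaluation_grid("female", "Hamburg")
  obj <- eq5_objective(st$params, grid, surf,
                       stratum_m_fun(truth_default), st$mrr)
  expect_lt(obj, 1e-20)
  # perturbing the true incidence amplitude strictly raises the objective
  for (fac in c(0.9, 1.1, 1.5)) {
    pert <- rate_parameter_set(
      gaussian_rate_params(st$params$incidence$amplitude * fac,
                           st$params$incidence$location,
                           st$params$incidence$width),
      st$params$remission)
    expect_gt(eq5_objective(pert, grid, surf,
                            stratum_m_fun(truth_default), st$mrr), obj)
  }
})

test_that("the objective is exactly zero for a flat no-flow configuration", {
  cells <- exact_truth_cells(flat_truth(0.5), "anxiety", "female")
  fit <- fit_logit_polynomial(cells = cells, condition = "anxiety", df = 1)
  fit$coefficients[] <- 0          # logit p = 0 everywhere: p = 1/2, dp = 0
  zero <- rate_parameter_set(gaussian_rate_params(0, 40, 10),
                             gaussian_rate_params(0, 40, 10))
  grid <- evaluation_grid("female", "Hamburg")
  expect_identical(eq5_objective(zero, grid, fit, function(a) 0.01 + 0 * a,
                                 function(a) 1 + 0 * a), 0)
})

test_that("estimation is deterministic and honours warm starts", {
  rec <- sample_study(truth_default, 3000, centers = "Hamburg",
                      sexes = "female", seed = 13)
  fit <- fit_logit_polynomial(rec, "anxiety", df = 3)
  grid <- evaluation_grid("female", "Hamburg")
  m_curve <- stratum_mortality_curve(truth_default)
  mrr_curve <- fit_mrr(make_mrr_curve(2, 0))
  e1 <- estimate_rates(fit, m_curve, mrr_curve, grid)
  e2 <- estimate_rates(fit, m_curve, mrr_curve, grid)
  expect_identical(e1$theta, e2$theta)
  expect_identical(e1$start_selected, e2$start_selected)
  expect_equal(nrow(e1$report), 8L)
  # restarting at the found optimum cannot worsen the objective, and on a
  # well-identified (exact-surface) problem it stays at the solution
  e3 <- estimate_rates(fit, m_curve, mrr_curve, grid,
                       control = list(starts = matrix(e1$theta, nrow = 1)))
  expect_lte(e3$objective, e1$objective * (1 + 1e-8) + 1e-20)
  cells <- exact_truth_cells(truth_default)
  fitx <- fit_logit_polynomial(cells = cells, condition = "anxiety", df = 4)
  x1 <- estimate_rates(fitx, stratum_m_fun(truth_default),
                       truth_default$strata[["anxiety.female"]]$mrr, grid)
  x2 <- estimate_rates(fitx, stratum_m_fun(truth_default),
                       truth_default$strata[["anxiety.female"]]$mrr, grid,
                       control = list(starts = matrix(x1$theta, nrow = 1)))
  expect_equal(gaussian_rate(grid$ages, x2$params$incidence),
               gaussian_rate(grid$ages, x1$params$incidence),
               tolerance = 1e-2)
  expect_equal(gaussian_rate(grid$ages, x2$params$remission),
               gaussian_rate(grid$ages, x1$params$remission),
               tolerance = 1e-2)
})

test_that("estimated curves reproduce the truth's sign pattern on exact data", {
  cells <- exact_truth_cells(truth_default)
  fit <- fit_logit_polynomial(cells = cells, condition = "anxiety", df = 4)
  est <- estimate_rates(fit, stratum_m_fun(truth_default),
                        truth_default$strata[["anxiety.female"]]$mrr,
                        evaluation_grid("female", "Hamburg"))
  inc <- gaussian_rate(30:74, est$params$incidence)
  rem <- gaussian_rate(19:65, est$params$remission)
  expect_true(all(diff(inc) < 0))   # incidence declines beyond age 30
  expect_true(all(diff(rem) > 0))   # remission rises until old age
})

test_that("rates_table converts units and truncates negatives with flags", {
  params <- rate_parameter_set(gaussian_rate_params(0.004, 30, 15),
                               gaussian_rate_params(0.03, 72, 20))
  tab <- rates_table(params, ages = c(30, 72))
  expect_equal(tab$incidence_per_1000py[1], 4)
  expect_equal(tab$remission_per_100py[2], 3)
  expect_false(any(tab$inc_truncated))

  neg <- rate_parameter_set(gaussian_rate_params(-0.001, 30, 15),
                            gaussian_rate_params(0.03, 72, 20))
  tab <- rates_table(neg, ages = c(30, 40))
  expect_equal(tab$incidence_per_1000py, c(0, 0))
  expect_true(all(tab$inc_truncated))
  expect_false(any(tab$rem_truncated))
  expect_error(rates_table(params, ages = c(10, 30)), "\\[19, 74\\]")
})

test_that("peaks clamp to the observable boundary like the study population", {
  p <- function(il, rl) rate_parameter_set(gaussian_rate_params(0.004, il, 15),
                                           gaussian_rate_params(0.05, rl, 20))
  pk <- find_peaks(p(20, 80))
  expect_equal(pk$age, c(20, 74))
  expect_equal(pk$value[1], 0.004)     # in-range peak equals the amplitude
  expect_true(pk$at_boundary[2])
  expect_equal(find_peaks(p(10, 40))$age[1], 19)   # below-range peak
  # negative amplitude: maximum at the boundary farther from the mode
  negp <- rate_parameter_set(gaussian_rate_params(-0.01, 30, 10),
                             gaussian_rate_params(0.05, 40, 20))
  expect_equal(find_peaks(negp)$age[1], 74)
})
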