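test_that("gaussian_rate evaluates the three-parameter bump correctly", {
  g <- gaussian_rate_params(0.004, 20, 18)
  expect_identical(gaussian_rate(20, g), 0.004)          # value at the mode
  g2 <- gaussian_rate_params(0.004, 20, 10)
  expect_equal(gaussian_rate(30, g2), 0.004 * exp(-1))
  # symmetry about the mode
  for (d in c(0.5, 3, 17.2)) {
    expect_equal(gaussian_rate(20 - d, g), gaussian_rate(20 + d, g))
  }
  expect_error(gaussian_rate_params(0.004, 20, 0), "width")
  expect_error(gaussian_rate_params(0.004, 20, -3), "width")
})

test_that("gaussian_rate integrates to amplitude * width * sqrt(pi)", {
  g <- gaussian_rate_params(0.03, 50, 12)
  got <- stats::integrate(function(a) gaussian_rate(a, g), -400, 500,
                          rel.tol = 1e-10)$value
  expect_equal(got, 0.03 * 12 * sqrt(pi), tolerance = 1e-6)
})

test_that("the balance equation matches hand-computed values", {
  expect_equal(pde_rhs(0, incidence = 0.004, remission = 0.5,
                       m0 = 0.01, m1 = 0.01), 0.004)
  expect_equal(pde_rhs(0.1, 0.004, 0.02, 0.01, 0.02),
               0.0036 - 0.002 - 0.0009)
  # stationary when nothing flows and mortality does not differ
  for (p in c(0, 0.3, 1)) {
    expect_identical(pde_rhs(p, 0, 0, 0.02, 0.02), 0)
  }
  expect_error(pde_rhs(-0.01, 0.004, 0.02, 0.01, 0.02), "\\[0, 1\\]")
  expect_error(pde_rhs(1.2, 0.004, 0.02, 0.01, 0.02), "\\[0, 1\\]")
})

test_that("the MRR form of the balance equation matches hand values and pde_rhs", {
  # m, R consistent with (m0, m1) = (0.01, 0.02) at p = 0.1
  expect_equal(pde_rhs_mrr(0.1, 0.004, 0.02, m = 0.011, mrr = 2), 0.0007)
  # no excess mortality: third term vanishes
  p <- c(0, 0.2, 0.7)
  expect_equal(pde_rhs_mrr(p, 0.004, 0.02, m = 0.05, mrr = 1),
               (1 - p) * 0.004 - p * 0.02)
  expect_equal(pde_rhs_mrr(0.5, 0, 0, m = 0.01, mrr = 3), -0.0025)
  expect_error(pde_rhs_mrr(0.5, 0, 0, m = 0.01, mrr = 0), "positive")
  expect_error(pde_rhs_mrr(0.5, 0, 0, m = 0.01, mrr = -2), "positive")
})

test_that("cohort solver reproduces stationary and analytic solutions", {
  ages <- seq(19, 74, by = 1)
  # stationary
  p <- solve_cohort_prevalence(0.06, 19, ages, incidence = 0, remission = 0,
                               m0 = 0.01, m1 = 0.01)
  expect_equal(p, rep(0.06, length(ages)), tolerance = 1e-12)
  # growth toward 1: p(a) = 1 - (1 - p0) exp(-i (a - a0))
  p <- solve_cohort_prevalence(0, 19, c(19, 29), incidence = 0.01,
                               remission = 0, m0 = 0.005, m1 = 0.005)
  expect_equal(p[2], 1 - exp(-0.1), tolerance = 1e-9)
  # pure decay: p(a) = p0 exp(-r (a - a0))
  p <- solve_cohort_prevalence(1, 19, c(19, 29), incidence = 0,
                               remission = 0.05, m0 = 0.005, m1 = 0.005)
  expect_equal(p[2], exp(-0.5), tolerance = 1e-9)
  expect_error(solve_cohort_prevalence(0.1, 19, c(19, 25, 24), 0.01, 0,
                                       m0 = 0, m1 = 0), "increasing")
})

test_that("cohort solver agrees between the (m0, m1) and (m, R) forms", {
  i_f <- function(a) gaussian_rate(a, gaussian_rate_params(0.004, 20, 18))
  r_f <- function(a) gaussian_rate(a, gaussian_rate_params(0.04, 72, 20))
  m0_f <- function(a) 1e-4 * exp(0.09 * (a - 19))
  ages <- seq(19, 74, by = 0.5)
  p1 <- solve_cohort_prevalence(0.05, 19, ages, i_f, r_f,
                                m0 = m0_f, m1 = function(a) 2 * m0_f(a))
  # the (m, R) route needs the general mortality consistent with p(a)
  m_f <- function(a) {
    p <- stats::approx(ages, p1, xout = a, rule = 2)$y
    (1 - p) * m0_f(a) + p * 2 * m0_f(a)
  }
  p2 <- solve_cohort_prevalence(0.05, 19, ages, i_f, r_f, m = m_f, mrr = 2)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("cohort solver output stays within [0, 1] for random nonnegative rates", {
  set.seed(401)
  ages <- seq(19, 74, by = 1)
  for (k in 1:20) {
    i_f <- function(a) gaussian_rate(a, gaussian_rate_params(runif(1, 0, 0.3),
                                                             runif(1, 10, 80),
                                                             runif(1, 3, 40)))
    r_f <- function(a) gaussian_rate(a, gaussian_rate_params(runif(1, 0, 0.5),
                                                             runif(1, 10, 80),
                                                             runif(1, 3, 40)))
    p <- solve_cohort_prevalence(runif(1), 19, ages, i_f, r_f,
                                 m = function(a) runif(1, 0, 0.05),
                                 mrr = runif(1, 0.5, 4))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("misclassification adjustment follows the Rogan-Gladen formula", {
  # perfect instrument is the identity
  expect_equal(adjust_prevalence(0.3, 1, 1)$adjusted, 0.3)
  expect_true(adjust_prevalence(0.3, 1, 1)$valid)
  # screener-like operating characteristics can push the estimate negative
  res <- adjust_prevalence(0.102, 0.78, 0.87)
  expect_equal(res$adjusted, (0.102 - 0.13) / 0.65)
  expect_false(res$valid)
  res <- adjust_prevalence(0.20, 0.89, 0.82)
  expect_equal(res$adjusted, 0.02 / 0.71)
  expect_true(res$valid)
  expect_error(adjust_prevalence(0.2, 0.5, 0.5), "exceed 1")
  # strictly increasing in observed prevalence
  p <- seq(0, 1, by = 0.05)
  adj <- adjust_prevalence(p, 0.89, 0.82)$adjusted
  expect_true(all(diff(adj) > 0))
})
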