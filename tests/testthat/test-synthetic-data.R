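test_that("mortality and MRR fixtures evaluate their functional forms", {
  mt <- make_mortality_table(1e-4, 0.09)
  expect_equal(mt$rate[mt$age == 19], 1e-4)
  expect_equal(mt$rate[mt$age == 74], 1e-4 * exp(0.09 * 55))
  expect_equal(make_mortality_table(1e-4, 0)$rate, rep(1e-4, 56))
  expect_error(make_mortality_table(-1e-4, 0.09), "non-negative")

  expect_equal(make_mrr_curve(2, 0)$ratio, rep(2, 56))
  mc <- make_mrr_curve(3, -0.02)
  expect_equal(mc$ratio[mc$age == 69], 2)
  expect_error(make_mrr_curve(1, -0.02), "positive")
})

test_that("make_truth derives prevalence from the configured rates", {
  p <- truth_prevalence(truth_default, c(19, 20), "anxiety", "female")
  expect_equal(p[1], 0.05)
  expect_gt(p[2], p[1])    # rising prevalence while incidence dominates
  # deterministic given the config
  expect_identical(make_truth()$strata[["anxiety.female"]]$p,
                   truth_default$strata[["anxiety.female"]]$p)
  # no flows, no excess mortality: constant prevalence
  ft <- flat_truth(0.1)
  expect_equal(ft$strata[["anxiety.female"]]$p,
               rep(0.1, length(ft$strata[["anxiety.female"]]$ages)),
               tolerance = 1e-12)
  bad <- default_truth_config()
  bad$conditions$anxiety$female$p_start <- 1.5
  expect_error(make_truth(bad), "\\[0, 1\\]")
})

test_that("sample_study draws a reproducible, truth-consistent study", {
  ft <- flat_truth(0.10)
  rec <- sample_study(ft, 10000, centers = "Hamburg", sexes = "female",
                      missingness = 0, weight_dispersion = 0.2, seed = 5)
  expect_identical(rec, sample_study(ft, 10000, centers = "Hamburg",
                                     sexes = "female", missingness = 0,
                                     weight_dispersion = 0.2, seed = 5))
  expect_true(all(rec$age >= 19 & rec$age <= 74))
  expect_true(all(rec$weight > 0))
  # weighted case proportion near the flat truth (3 design-adjusted SEs)
  phat <- sum(rec$weight * rec$case_anx) / sum(rec$weight)
  se <- sqrt(0.1 * 0.9 * (1 + 0.2) / nrow(rec))
  expect_lt(abs(phat - 0.10), 3 * se)
  # weights have mean about one
  expect_lt(abs(mean(rec$weight) - 1), 1e-2)
})

test_that("missingness is applied at the configured rate", {
  rec <- sample_study(truth_default, 10000, centers = "Berlin",
                      sexes = "male", missingness = 0.06, seed = 9)
  share <- mean(is.na(rec$case_anx))
  se <- sqrt(0.06 * 0.94 / nrow(rec))
  expect_lt(abs(share - 0.06), 3 * se)
  # missing status is NA, never a phantom value
  expect_true(all(rec$case_anx %in% c(0L, 1L, NA)))
  expect_error(sample_study(truth_default, 100, centers = character(0)),
               "non-empty")
})

test_that("empirical prevalence converges to the truth curve with n", {
  devs <- sapply(c(1e3, 1e4, 1e5), function(n) {
    rec <- sample_study(truth_default, n, centers = "Hamburg",
                        sexes = "female", weight_dispersion = 0, seed = 21)
    cells <- aggregate_cells(rec, "anxiety")
    emp <- tapply(cells$wcase, cells$age, sum) / tapply(cells$wtot, cells$age, sum)
    ages <- as.numeric(names(emp))
    max(abs(emp - truth_prevalence(truth_default, ages, "anxiety", "female")))
  })
  expect_true(all(diff(devs) < 0))      # shrinking with n
  expect_lt(devs[3], 3 * devs[1] / sqrt(100) * 4)  # roughly 1/sqrt(n)
})

test_that("tables survive CSV round trips", {
  rec <- sample_study(truth_default, 50, centers = "Augsburg", seed = 2,
                      missingness = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_participants(rec, f)
  back <- read_participants(f)
  expect_equal(back$case_anx, rec$case_anx)
  expect_equal(back$weight, rec$weight, tolerance = 1e-12)

  mt <- make_mortality_table(1e-4, 0.09)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mortality_table(mt, f2)
  expect_equal(read_mortality_table(f2)$rate, mt$rate, tolerance = 1e-12)

  mc <- make_mrr_curve(2, 0.01)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_mrr_curve(mc, f3)
  expect_equal(read_mrr_curve(f3)$ratio, mc$ratio, tolerance = 1e-12)
})
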