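test_that("Kaplan-Meier matches the hand-worked product-limit table", {
  # 5 subjects: events at t=1 and t=2, three censored at 2.5
  km <- km_estimate(toy_cohort())
  expect_equal(km$times, c(1, 2))
  expect_equal(km$at_risk, c(5L, 4L))
  expect_equal(km$survival, c(4 / 5, 4 / 5 * 3 / 4))
  expect_equal(km_eval(km, c(0.5, 1, 1.5, 3)), c(1, 0.8, 0.8, 0.6))
})

test_that("degenerate cohorts yield degenerate curves", {
  no_ev <- cohort(data.frame(id = 1:4, time = 1:4, event = 0))
  expect_equal(km_eval(km_estimate(no_ev), c(1, 10)), c(1, 1))
  all_ev <- cohort(data.frame(id = 1:4, time = c(1, 2, 3, 4), event = 1))
  km <- km_estimate(all_ev)
  expect_equal(km$survival, c(3 / 4, 1 / 2, 1 / 4, 0))
})

test_that("km_estimate agrees exactly with the survival-package estimator", {
  withr::local_seed(2718)
  for (i in 1:50) {
    n <- sample(3:60, 1)
    tm <- round(rexp(n, 0.5) + 0.01, 2)   # ties likely
    ev <- rbinom(n, 1, 0.5)
    km <- km_estimate(data.frame(time = tm, event = ev))
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    et <- sf$time[sf$n.event > 0]
    expect_equal(km$times, et)
    expect_equal(km$survival, sf$surv[sf$n.event > 0])
  }
})

test_that("self-VPC covers the observed curve; bands are ordered and bounded", {
  m <- stroke_model(levels = c(0.3, 0.05), shapes = c(-1.63, -0.23),
                    coefficients = c(HPLD = 0.8))
  cfg <- simulation_config(600, model = m, prevalences = c(HPLD = 0.3),
                           seed = 21)
  co <- generate_cohort(cfg)
  v <- vpc(m, co, n_sim = 150, seed = 8)
  b <- v$bands
  expect_true(all(b$lower <= b$median + 1e-12 & b$median <= b$upper + 1e-12))
  expect_true(all(b$upper <= 1 + 1e-12))
  expect_gte(vpc_coverage(v), 0.9)
  expect_error(vpc(m, co, n_sim = 1), "at least 2")
})

test_that("a misspecified model pushes the observed curve outside the band", {
  m <- const_model(0.15)
  cfg <- simulation_config(800, model = m, prevalences = numeric(0), seed = 33)
  co <- generate_cohort(cfg)  # data generated at hazard theta
  half <- const_model(0.075)  # checked against a model with half the hazard
  v <- vpc(half, co, n_sim = 150, seed = 9)
  b <- v$bands
  # the model over-predicts survival: observed falls below the lower band
  # over a contiguous late stretch
  out_low <- b$observed < b$lower - 1e-12
  expect_gt(mean(out_low), 0.3)
})

test_that("n_sim = 2 bands degenerate to the min/max of the two replicates", {
  co <- generate_cohort(simulation_config(200, model = const_model(0.3),
                                          prevalences = numeric(0), seed = 6))
  v <- vpc(const_model(0.3), co, n_sim = 2, seed = 1)
  expect_true(all(v$bands$lower <= v$bands$upper))
  expect_equal(v$bands$median, (v$bands$lower + v$bands$upper) / 2)
})

test_that("VPC output is reproducible and exportable", {
  co <- generate_cohort(simulation_config(150, model = const_model(0.3),
                                          prevalences = numeric(0), seed = 2))
  v1 <- vpc(const_model(0.3), co, n_sim = 20, seed = 4)
  v2 <- vpc(const_model(0.3), co, n_sim = 20, seed = 4)
  expect_identical(v1$bands, v2$bands)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vpc(v1, f)
  expect_equal(read.csv(f)$observed, v1$bands$observed)
})

test_that("SIR reproduces asymptotic uncertainty on a near-Gaussian problem", {
  withr::local_seed(14)
  n <- 2000
  dat <- data.frame(id = 1:n, time = rexp(n, 0.5), event = rbinom(n, 1, 0.7))
  co <- cohort(dat)
  fit <- fit_mle(co, const_model(0.3))
  s <- sir(fit, co, n_samples = 2000, n_resamples = 1000, seed = 61)
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  expect_true(all(s$weights >= 0))
  expect_gt(s$ess, 0.5 * s$n_samples)  # proposal is near-exact here
  rse_asym <- fit$estimates$rse[1]
  rse_sir <- s$estimates$rse[1]
  expect_lt(abs(rse_sir - rse_asym) / rse_asym, 0.10)
  # percentile CI brackets the MLE
  expect_lt(s$estimates$ci_lower[1], fit$estimates$estimate[1])
  expect_gt(s$estimates$ci_upper[1], fit$estimates$estimate[1])
})

test_that("SIR guards its preconditions", {
  withr::local_seed(15)
  dat <- data.frame(id = 1:300, time = rexp(300, 0.5), event = rbinom(300, 1, 0.6))
  co <- cohort(dat)
  fit <- fit_mle(co, const_model(0.3))
  expect_error(sir(fit, co, n_samples = 100, n_resamples = 200), "exceed")
  broken <- fit; broken$covariance <- NULL
  expect_error(sir(broken, co), "covariance")
})

test_that("rse_report formats hazard ratios with their intervals", {
  withr::local_seed(16)
  true <- hazard_model(hazard_segment(0, Inf, "constant", 0.2,
                                      level_name = "th1"),
                       coefficients = c(APLT = -0.514))
  co <- generate_cohort(simulation_config(3000, model = true,
                                          prevalences = c(APLT = 0.9),
                                          seed = 19))
  fit <- fit_mle(co, true)
  tab <- rse_report(fit)
  hr_row <- tab[tab$name == "APLT", ]
  expect_equal(hr_row$hr, exp(hr_row$estimate))
  expect_lt(hr_row$hr, 1)
  expect_lt(hr_row$hr_lower, hr_row$hr)
  expect_gt(hr_row$hr_upper, hr_row$hr)
  s <- sir(fit, co, n_samples = 500, n_resamples = 250, seed = 3)
  tab2 <- rse_report(s)
  expect_true(all(c("hr", "hr_lower", "hr_upper") %in% names(tab2)))
  # degenerate: no covariance -> estimates only, flagged
  broken <- fit; broken$covariance <- NULL
  broken$estimates$se <- NA_real_; broken$estimates$rse <- NA_real_
  tab3 <- rse_report(broken)
  expect_false(tab3$uncertainty_available[1])
})
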