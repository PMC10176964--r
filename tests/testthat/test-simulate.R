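test_that("covariate sampling hits configured prevalences", {
  m <- hazard_model(hazard_segment(0, Inf, "constant", 0.1),
                    coefficients = c(HPLD = 0.5, ALL = 0.1, NONE = -0.1))
  cfg <- simulation_config(50000, model = m,
                           prevalences = c(HPLD = 0.2634, ALL = 1, NONE = 0),
                           seed = 99)
  X <- sample_covariates(cfg)
  expect_equal(unname(colMeans(X)[c("ALL", "NONE")]), c(1, 0))
  # binomial 3-sigma bound around 0.2634 at n = 50,000 is about +/-0.006
  expect_lt(abs(mean(X[, "HPLD"]) - 0.2634), 0.006)
  expect_error(simulation_config(10, model = m, prevalences = c(HPLD = 0.5)),
               "prevalence")
})

test_that("event times drawn by inversion follow the model distribution", {
  withr::local_seed(123)
  # exponential special case: mean of draws ~ 1/theta
  m <- const_model(0.7)
  tt <- sample_event_time(m, n = 100000)
  expect_lt(abs(mean(tt) - 1 / 0.7) / (1 / 0.7), 0.01)
  # deterministic inversion at u = e^{-1}: H(t) = 1 exactly
  t1 <- sample_event_time(const_model(0.5), u = exp(-1))
  expect_equal(cumulative_hazard(const_model(0.5), t = t1), 1, tolerance = 1e-10)
  # empirical survival matches the closed form pointwise
  pm <- stroke_model(levels = c(0.8, 0.3), shapes = c(-1.63, -0.23),
                     coefficients = numeric(0))
  draws <- sample_event_time(pm, n = 100000)
  for (tp in c(0.25, 0.5, 1, 3)) {
    expect_lt(abs(mean(draws > tp) - survival_prob(pm, t = tp)), 0.005)
  }
})

test_that("generated cohorts are reproducible and carry the censoring design", {
  cfg <- simulation_config(800, model = stroke_model(levels = c(0.08, 0.02),
                                                     shapes = c(-1.63, -0.23)),
                           seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "censor_time"), attr(c2, "censor_time"))
  expect_true(all(c1$time <= 7.37))
  expect_true(all(c1$time > 0))
  # events happen strictly before the subject's censoring time
  expect_true(all(c1$time[c1$event == 1] <= attr(c1, "censor_time")[c1$event == 1]))
})

test_that("event-time draws are unchanged when covariate columns are added", {
  m0 <- const_model(0.2)
  base <- simulation_config(500, model = m0, prevalences = numeric(0), seed = 31)
  extra <- simulation_config(500, model = m0,
                             prevalences = c(X1 = 0.4, X2 = 0.6), seed = 31)
  c0 <- generate_cohort(base); c1 <- generate_cohort(extra)
  # independent RNG streams: the null columns do not perturb times or events
  expect_identical(c0$time, c1$time)
  expect_identical(c0$event, c1$event)
})

test_that("uniform-entry event fraction matches semi-analytic integration", {
  pm <- stroke_model(levels = c(0.08, 0.02), shapes = c(-1.63, -0.23),
                     coefficients = numeric(0))
  h <- 7.37
  cfg <- simulation_config(50000, model = pm, prevalences = numeric(0),
                           censoring_horizon = h, seed = 4242)
  co <- generate_cohort(cfg)
  # P(event) = E_C[1 - S(C)] with C ~ Uniform(0, h)
  oracle <- integrate(function(cc) 1 - survival_prob(pm, t = cc), 0, h,
                      rel.tol = 1e-10)$value / h
  expect_lt(abs(mean(co$event) - oracle), 0.005)
})

test_that("frailty widens the event-time distribution", {
  mf <- const_model(0.3); mf$omega_sq <- 1
  cfg <- simulation_config(20000, model = mf, prevalences = numeric(0),
                           censoring_scheme = "fixed-horizon",
                           censoring_horizon = 50, seed = 88)
  cof <- generate_cohort(cfg)
  m0 <- const_model(0.3)
  cfg0 <- simulation_config(20000, model = m0, prevalences = numeric(0),
                            censoring_scheme = "fixed-horizon",
                            censoring_horizon = 50, seed = 88)
  co0 <- generate_cohort(cfg0)
  # a log-normal frailty inflates the variance of the mixture of exponentials
  expect_gt(var(cof$time[cof$event == 1]), var(co0$time[co0$event == 1]))
})

test_that("degenerate simulations are flagged, not fatal", {
  tiny <- const_model(1e-9)
  cfg <- simulation_config(50, model = tiny, prevalences = numeric(0),
                           censoring_horizon = 0.01, seed = 3)
  expect_warning(co <- generate_cohort(cfg), "no events")
  expect_equal(sum(co$event), 0)
})

test_that("simulation config YAML round-trips through the reader", {
  m <- stroke_model(levels = c(0.08, 0.02), shapes = c(-1.63, -0.23))
  dir <- withr::local_tempdir()
  write_hazard_model(m, file.path(dir, "model.yaml"))
  fc <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(n_subjects = 100,
                        model_file = "model.yaml",
                        prevalences = as.list(stroke_prevalences()),
                        censoring_horizon = 7.37,
                        censoring_scheme = "uniform-entry",
                        seed = 17), fc)
  cfg <- read_simulation_config(fc)
  expect_equal(cfg$n_subjects, 100L)
  expect_equal(cfg$seed, 17L)
  expect_identical(as.data.frame(generate_cohort(cfg)),
                   as.data.frame(generate_cohort(
                     simulation_config(100, model = m, seed = 17))))
})

test_that("the simulation manifest records seed and config", {
  cfg <- simulation_config(50, model = const_model(0.2),
                           prevalences = numeric(0), seed = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_manifest(cfg, "cohort.csv", f)
  j <- jsonlite::read_json(f)
  expect_equal(j$config$seed, 12)
  expect_equal(j$config$n_subjects, 50)
})
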