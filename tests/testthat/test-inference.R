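test_that("subject log-likelihood matches the exact-event-time closed forms", {
  m1 <- const_model(1)
  expect_equal(subject_loglik(rec(2, 0), m1), -2)           # censored: -H
  expect_equal(subject_loglik(rec(1, 1), m1), -1)           # event: log h - H
  expect_equal(subject_loglik(rec(0.5, 1), const_model(2)), log(2) - 1)
  # covariates enter both hazard and cumulative hazard
  m2 <- hazard_model(hazard_segment(0, Inf, "constant", 1),
                     coefficients = c(HTN = 0.7))
  expect_equal(subject_loglik(rec(1, 1, HTN = 1), m2), 0.7 - exp(0.7))
})

test_that("Laplace marginal reduces to the fixed-effect likelihood at omega^2 = 0", {
  m <- gompertz_model(0.3, -0.5)
  for (r in list(rec(2, 0), rec(0.7, 1)))
    expect_identical(laplace_marginal_loglik(r, m), subject_loglik(r, m))
})

test_that("Laplace marginal agrees with 64-point Gauss-Hermite quadrature", {
  gh <- pracma::gaussHermite(64)
  gh_marginal <- function(r, model) {
    # adaptive Gauss-Hermite: nodes centred at the joint mode and scaled by
    # its curvature, log-sum-exp for stability -- near-exact for these cases
    sd <- sqrt(model$omega_sq)
    f <- function(eta) subject_loglik(r, model, eta = eta) +
      dnorm(eta, 0, sd, log = TRUE)
    mode <- optimize(f, c(-15 * sd - 5, 15 * sd + 5), maximum = TRUE,
                     tol = 1e-12)$maximum
    h <- 1e-5
    curv <- (f(mode + h) - 2 * f(mode) + f(mode - h)) / h^2
    s_hat <- sqrt(-1 / curv)
    v <- vapply(gh$x, function(z) f(mode + sqrt(2) * s_hat * z) + z^2,
                numeric(1))
    m <- max(v)
    log(sqrt(2) * s_hat) + m + log(sum(gh$w * exp(v - m)))
  }
  # the Laplace error is the intrinsic second-order one: it vanishes as
  # omega^2 -> 0 and stays within ~1e-2 over omega^2 <= 1 for cohort-scale
  # hazards (see the methods vignette for the measured error surface)
  m <- const_model(0.8); m$omega_sq <- 0.01
  r <- rec(1.5, 0)
  expect_equal(laplace_marginal_loglik(r, m), gh_marginal(r, m), tolerance = 1e-4)
  m$omega_sq <- 0.25
  expect_equal(laplace_marginal_loglik(r, m), gh_marginal(r, m), tolerance = 5e-3)

  withr::local_seed(41)
  for (i in 1:12) {
    mo <- gompertz_model(runif(1, 0.05, 1), runif(1, -1.5, 1.5))
    mo$omega_sq <- runif(1, 0.01, 1)
    r <- rec(runif(1, 0.2, 5), rbinom(1, 1, 0.5))
    expect_lt(abs(laplace_marginal_loglik(r, mo) - gh_marginal(r, mo)), 2e-2)
  }
})

test_that("doubling the scale while shifting eta by -log 2 leaves the joint density's data part unchanged", {
  m <- const_model(0.4); m$omega_sq <- 0.5
  r <- rec(2, 0)
  m2 <- const_model(0.8); m2$omega_sq <- 0.5
  expect_equal(subject_loglik(r, m, eta = 0.3),
               subject_loglik(r, m2, eta = 0.3 - log(2)))
})

test_that("OFV is -2 x the summed marginal log-likelihood and additive over subjects", {
  m <- const_model(1)
  one <- cohort(data.frame(id = 1, time = 2, event = 0))
  two <- cohort(data.frame(id = 1:2, time = c(2, 2), event = c(0, 0)))
  expect_equal(ofv(two, m), 2 * ofv(one, m))
  expect_equal(ofv(cohort(data.frame(id = 1, time = 1, event = 1)), m), 2)
  # invariant under subject reordering and covariate column reordering
  co <- toy_cohort()
  sm <- hazard_model(hazard_segment(0, Inf, "constant", 0.3),
                     coefficients = c(HPLD = 0.5))
  perm <- cohort(as.data.frame(co)[5:1, ])
  expect_equal(ofv(co, sm), ofv(perm, sm))
})

test_that("frailty-free OFV agrees with a brute-force numerically integrated likelihood", {
  withr::local_seed(55)
  pm <- random_piecewise_model()
  n <- 30
  dat <- data.frame(id = 1:n, time = runif(n, 0.1, 6), event = rbinom(n, 1, 0.5))
  co <- cohort(dat)
  brute <- sum(vapply(seq_len(n), function(i) {
    H <- quad_cumhaz(pm, dat$time[i])
    if (dat$event[i] == 1) log(baseline_hazard(pm$baseline, dat$time[i])) - H else -H
  }, numeric(1)))
  expect_equal(ofv(co, pm), -2 * brute, tolerance = 1e-6)
})

test_that("constant-hazard MLE recovers the closed-form exposure estimator", {
  withr::local_seed(9)
  n <- 500
  dat <- data.frame(id = 1:n, time = rexp(n, 0.4), event = rbinom(n, 1, 0.6))
  co <- cohort(dat)
  fit <- fit_mle(co, const_model(0.1))
  theta_hat <- fit$estimates$estimate[fit$estimates$name == "th1"]
  expect_equal(theta_hat, sum(dat$event) / sum(dat$time), tolerance = 1e-6)
  expect_true(fit$converged)
  # descent: the fitted OFV cannot exceed the OFV at the starting values
  expect_lte(fit$ofv, ofv(co, const_model(0.1)) + 1e-8)
})

test_that("adding a covariate with a true effect lowers the OFV", {
  true <- hazard_model(hazard_segment(0, Inf, "constant", 0.15),
                       coefficients = c(A = 0.8))
  cfg <- simulation_config(1500, model = true, prevalences = c(A = 0.4),
                           seed = 314)
  co <- generate_cohort(cfg)
  f0 <- fit_mle(co, const_model(0.1))
  f1 <- fit_mle(co, hazard_model(hazard_segment(0, Inf, "constant", 0.1,
                                                level_name = "th1"),
                                 coefficients = c(A = 0)))
  expect_lt(f1$ofv, f0$ofv)
})

test_that("frailty variance can be estimated on the log scale", {
  m <- const_model(0.5); m$omega_sq <- 0.4
  cfg <- simulation_config(400, model = m, prevalences = numeric(0),
                           censoring_scheme = "fixed-horizon",
                           censoring_horizon = 4, seed = 77)
  co <- generate_cohort(cfg)
  start <- const_model(0.3); start$omega_sq <- 0.2
  fit <- fit_mle(co, start, estimate_frailty = TRUE)
  expect_true("omega_sq" %in% fit$estimates$name)
  expect_true(fit$estimates$estimate[fit$estimates$name == "omega_sq"] > 0)
})

test_that("likelihood-ratio p-values follow chi-square(1)", {
  expect_lt(abs(lrt(103.84, 100, 1) - 0.05), 1e-3)
  expect_equal(lrt(100, 100, 1), 1)
  expect_lt(abs(lrt(106.64, 100, 1) - 0.01), 1e-4)
  expect_warning(expect_equal(lrt(99, 100, 5), 1), "lower OFV")  # negative delta clipped
  expect_error(lrt(1, 0, df = 0), "df")
})

test_that("fit JSON serialisation includes the reference comparison", {
  withr::local_seed(10)
  dat <- data.frame(id = 1:200, time = rexp(200, 0.5), event = rbinom(200, 1, 0.5))
  co <- cohort(dat)
  f0 <- fit_mle(co, const_model(0.2))
  f1 <- fit_mle(co, gompertz_model(0.2, 0))
  p <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f1, p, reference = f0)
  j <- jsonlite::read_json(p)
  expect_equal(j$reference$delta_ofv, f0$ofv - f1$ofv, tolerance = 1e-10)
  expect_true(j$converged)
})
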