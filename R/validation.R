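#' Kaplan-Meier product-limit estimator
#'
#' The standard product-limit estimator of the survivor function from
#' right-censored data. Ties at an event time are handled with a single
#' simultaneous `(1 - d/n)` factor.
#'
#' @param x a [cohort()], or a data frame with `time` and `event` columns.
#' @return a `km_curve`: `times` (distinct event times), `survival` (step
#'   values just after each event time), `at_risk` and `n_events` per step,
#'   and `n` subjects. A cohort without events yields a flat curve at 1.
#' @export
km_estimate <- function(x) {
  time <- as.numeric(x$time); event <- as.numeric(x$event)
  stopifnot(length(time) >= 1, all(time > 0))
  km_estimate_raw(time, event)
}

km_estimate_raw <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  et <- unique(time[event == 1])
  n <- length(time)
  if (!length(et)) {
    return(structure(list(times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0), n = n),
                     class = "km_curve"))
  }
  # at risk just before each event time; events at each time
  at_risk <- n - findInterval(et, time, left.open = TRUE)
  d <- as.integer(tabulate(factor(time[event == 1], levels = et)))
  surv <- cumprod(1 - d / at_risk)
  structure(list(times = et, survival = surv, at_risk = as.integer(at_risk),
                 n_events = d, n = n),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: 1 before the first event time, then the
#' product-limit value of the last event time at or before `t`.
#'
#' @param km a `km_curve`.
#' @param t evaluation times.
#' @return survival probabilities.
#' @export
km_eval <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  if (!length(km$times)) return(rep(1, length(t)))
  idx <- findInterval(t, km$times)
  c(1, km$survival)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event time(s)\n",
              x$n, length(x$times)))
  if (length(x$times))
    print(utils::head(data.frame(time = x$times, at_risk = x$at_risk,
                                 events = x$n_events, survival = x$survival), 10))
  invisible(x)
}

#' Kaplan-Meier visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the model while preserving each
#' subject's own covariates and censoring time (the observation design),
#' computes the Kaplan-Meier curve of every replicate, and summarises them
#' as pointwise percentile bands on a dense time grid up to the horizon. The
#' observed cohort's Kaplan-Meier curve is evaluated on the same grid for
#' overlay.
#'
#' Censoring times are taken from the cohort's `"censor_time"` attribute
#' when present (synthetic cohorts carry it); otherwise a censored subject's
#' censoring time is its observed time and an event subject's is the
#' horizon.
#'
#' @param model a fully parameterised [hazard_model()].
#' @param x a [cohort()].
#' @param n_sim number of replicate datasets (>= 2; 1000 gives stable 95%
#'   bands).
#' @param horizon grid end in years.
#' @param probs lower / median / upper percentiles of the simulated curves.
#' @param grid_points number of equally spaced grid times (observed event
#'   times are added to the grid).
#' @param seed integer seed for the replicate simulations.
#' @return a `vpc_bands` object: data frame `bands` (time, lower, median,
#'   upper, observed) plus `n_sim` and `probs`.
#' @export
vpc <- function(model, x, n_sim = 1000L, horizon = 7.37,
                probs = c(0.025, 0.5, 0.975), grid_points = 200L, seed = 1L) {
  stopifnot(inherits(model, "hazard_model"), inherits(x, "cohort"))
  if (n_sim < 2) stop("'n_sim' must be at least 2")
  n <- nrow(x)
  C <- attr(x, "censor_time")
  if (is.null(C)) C <- ifelse(x$event == 1, horizon, x$time)
  X <- cohort_design(x, model)
  lp <- if (ncol(X)) drop(X %*% model$coefficients) else rep(0, n)
  obs_km <- km_estimate(x)
  grid <- sort(unique(c(seq(0, horizon, length.out = grid_points), obs_km$times)))
  grid <- grid[grid <= horizon]
  sims <- matrix(NA_real_, length(grid), n_sim)
  set.seed(seed)
  for (r in seq_len(n_sim)) {
    eta <- if (model$omega_sq > 0) stats::rnorm(n, 0, sqrt(model$omega_sq)) else 0
    u <- stats::runif(n)
    E <- invert_baseline_cumhaz(model$baseline, -log(u) / exp(lp + eta))
    tm <- pmin(E, C)
    km <- km_estimate_raw(tm, as.numeric(E <= C))
    sims[, r] <- km_eval(km, grid)
  }
  qs <- t(apply(sims, 1, stats::quantile, probs = probs, names = FALSE))
  bands <- data.frame(time = grid, lower = qs[, 1], median = qs[, 2],
                      upper = qs[, 3], observed = km_eval(obs_km, grid))
  structure(list(bands = bands, n_sim = as.integer(n_sim), probs = probs,
                 horizon = horizon),
            class = "vpc_bands")
}

#' @export
print.vpc_bands <- function(x, ...) {
  cov <- vpc_coverage(x)
  cat(sprintf("KM-VPC: %d replicates, %d grid points, observed curve inside the %g%% band at %.1f%% of points\n",
              x$n_sim, nrow(x$bands), 100 * (x$probs[3] - x$probs[1]), 100 * cov))
  invisible(x)
}

#' Fraction of grid points where the observed KM lies inside the band
#'
#' @param v a `vpc_bands` object.
#' @return proportion in `[0, 1]`.
#' @export
vpc_coverage <- function(v) {
  stopifnot(inherits(v, "vpc_bands"))
  b <- v$bands
  mean(b$observed >= b$lower - 1e-12 & b$observed <= b$upper + 1e-12)
}

#' Write VPC bands as CSV
#'
#' @param v a `vpc_bands` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vpc <- function(v, path) {
  stopifnot(inherits(v, "vpc_bands"))
  utils::write.csv(v$bands, path, row.names = FALSE)
  invisible(path)
}

#' Plot VPC bands
#'
#' Base-graphics plot of the observed Kaplan-Meier curve over the simulated
#' percentile envelope.
#'
#' @param x a `vpc_bands` object.
#' @param ... passed to [plot()].
#' @export
plot.vpc_bands <- function(x, ...) {
  b <- x$bands
  plot(b$time, b$observed, type = "n", ylim = c(min(b$lower), 1),
       xlab = "Years since index stroke", ylab = "Recurrence-free fraction", ...)
  graphics::polygon(c(b$time, rev(b$time)), c(b$lower, rev(b$upper)),
                    col = "grey85", border = NA)
  graphics::lines(b$time, b$median, lty = 2)
  graphics::lines(b$time, b$observed, lwd = 2)
  invisible(x)
}

## ---- sampling importance resampling ---------------------------------------

mvn_logpdf <- function(Z, mu, chol_sigma) {
  # Z: samples in rows; chol_sigma: upper Cholesky factor of sigma
  p <- length(mu)
  dev <- sweep(Z, 2, mu)
  sol <- backsolve(chol_sigma, t(dev), transpose = TRUE)
  -0.5 * colSums(sol^2) - sum(log(diag(chol_sigma))) - 0.5 * p * log(2 * pi)
}

#' Sampling importance resampling (SIR) uncertainty
#'
#' Approximates the parameter distribution around the MLE: draw `n_samples`
#' from a multivariate-normal proposal centred at the MLE on the transformed
#' scale with the asymptotic covariance, weight each draw by the likelihood
#' ratio (model likelihood over proposal density, normalised), and resample
#' `n_resamples` draws without replacement with probability proportional to
#' weight. RSE% and percentile confidence intervals are computed from the
#' resamples on the natural scale.
#'
#' If the effective sample size falls below 10% of `n_samples` the proposal
#' covariance is inflated by `inflate` and the sampling is retried once;
#' a second failure is an error.
#'
#' @param fit a converged `fit_result` with a covariance matrix.
#' @param x the [cohort()] the model was fitted to (used to evaluate the
#'   likelihood at each draw).
#' @param n_samples proposal draws.
#' @param n_resamples resampled subset size (<= `n_samples`).
#' @param seed integer seed.
#' @param inflate covariance inflation factor for the single retry.
#' @return a `sir_result`: `samples` (transformed draws), `weights`
#'   (normalised), `resamples` (natural-scale data frame), `estimates`
#'   (per-parameter point estimate, RSE%, percentile CI), and `ess`.
#' @export
sir <- function(fit, x, n_samples = 2000L, n_resamples = 1000L, seed = 1L,
                inflate = 1.5) {
  stopifnot(inherits(fit, "fit_result"), inherits(x, "cohort"))
  if (!fit$converged) stop("SIR requires a converged fit")
  if (is.null(fit$covariance))
    stop("SIR requires a fit with an available covariance matrix")
  if (n_resamples > n_samples) stop("'n_resamples' must not exceed 'n_samples'")
  map <- fit$map
  mu <- fit$par_transformed
  fn <- model_ofv_fn(x, fit$model, map)
  ofv_hat <- fit$ofv
  draw <- function(sigma, stream_seed) {
    ch <- chol(sigma)
    set.seed(stream_seed)
    Z <- matrix(stats::rnorm(n_samples * length(mu)), n_samples)
    S <- sweep(Z %*% ch, 2, mu, `+`)
    lq <- mvn_logpdf(S, mu, ch)
    lt <- -0.5 * (apply(S, 1, fn) - ofv_hat)   # log-likelihood up to a constant
    lw <- lt - lq
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    list(S = S, w = w, ess = 1 / sum(w^2))
  }
  seeds <- derive_seeds(seed, 3L)
  d <- draw(fit$covariance, seeds[1])
  if (d$ess < 0.1 * n_samples) {
    warning("effective sample size below 10% of n_samples; ",
            "inflating proposal covariance and retrying once")
    d <- draw(fit$covariance * inflate, seeds[2])
    if (d$ess < 0.1 * n_samples)
      stop("SIR proposal remains degenerate after inflation (ESS = ",
           round(d$ess, 1), ")")
  }
  set.seed(seeds[3])
  idx <- sample.int(n_samples, n_resamples, replace = FALSE, prob = d$w)
  res_t <- d$S[idx, , drop = FALSE]
  colnames(res_t) <- map$name
  res_nat <- res_t
  for (k in seq_len(nrow(map)))
    if (map$transform[k] == "log") res_nat[, k] <- exp(res_t[, k])
  est <- fit$estimates[, c("name", "kind", "estimate")]
  est$rse <- 100 * apply(res_nat, 2, stats::sd) / abs(est$estimate)
  ci <- t(apply(res_nat, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  est$ci_lower <- ci[, 1]; est$ci_upper <- ci[, 2]
  structure(list(samples = d$S, weights = d$w,
                 resamples = as.data.frame(res_nat),
                 estimates = est, ess = d$ess,
                 n_samples = as.integer(n_samples),
                 n_resamples = as.integer(n_resamples)),
            class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf("SIR: %d samples, %d resamples, ESS = %.0f\n",
              x$n_samples, x$n_resamples, x$ess))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Parameter uncertainty report
#'
#' Tabulates natural-scale estimates with RSE% and confidence intervals.
#' For covariate coefficients the hazard ratio `exp(coef)` and its interval
#' are added: percentile-based (exp of the coefficient percentiles) for SIR
#' results, Wald `exp(coef +/- 1.96 SE)` for asymptotic fits. A fit without
#' available uncertainty yields the estimate column only, with a flag.
#'
#' @param result a `fit_result` or `sir_result`.
#' @return a data frame (parameter, estimate, rse, ci_lower, ci_upper, and
#'   hr / hr_lower / hr_upper on coefficient rows).
#' @export
rse_report <- function(result) {
  if (inherits(result, "sir_result")) {
    est <- result$estimates
  } else if (inherits(result, "fit_result")) {
    est <- result$estimates[, c("name", "kind", "estimate", "rse")]
    if (all(is.na(est$rse))) {
      est$uncertainty_available <- FALSE
      return(est)
    }
    se <- result$estimates$se
    est$ci_lower <- est$estimate - 1.96 * se
    est$ci_upper <- est$estimate + 1.96 * se
  } else stop("'result' must be a fit_result or sir_result")
  is_coef <- est$kind == "coef"
  est$hr <- ifelse(is_coef, exp(est$estimate), NA_real_)
  est$hr_lower <- ifelse(is_coef, exp(est$ci_lower), NA_real_)
  est$hr_upper <- ifelse(is_coef, exp(est$ci_upper), NA_real_)
  est
}
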