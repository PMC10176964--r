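#' Exact-event-time log-likelihood for one subject
#'
#' Events are treated as occurring exactly at the observed time: an event
#' contributes \eqn{\log h(T) - H(T)}, a right-censored subject contributes
#' \eqn{-H(T)}, where hazard and cumulative hazard include the covariate and
#' frailty multipliers.
#'
#' @param record a one-row data frame (or list) with `time`, `event`, and
#'   the model's covariate columns.
#' @param model a [hazard_model()].
#' @param eta frailty value on the log-hazard scale.
#' @return the log-density contribution (finite, or `-Inf` with a warning if
#'   the hazard vanishes at an event time).
#' @export
subject_loglik <- function(record, model, eta = 0) {
  stopifnot(inherits(model, "hazard_model"))
  tt <- as.numeric(record$time)
  ev <- as.numeric(record$event)
  stopifnot(length(tt) == 1L, tt > 0, ev %in% c(0, 1))
  x <- if (length(model$coefficients))
    unlist(record[names(model$coefficients)]) else NULL
  H <- cumulative_hazard(model, x = x, eta = eta, t = tt)
  if (ev == 0) return(-H)
  h <- subject_hazard(model, x = x, eta = eta, t = tt)
  if (h <= 0) {
    warning("hazard is zero at an observed event time; log-likelihood is -Inf")
    return(-Inf)
  }
  log(h) - H
}

# vectorised fixed-effect log-likelihood over the whole cohort
cohort_loglik_fixed <- function(x, model, eta = 0) {
  X <- cohort_design(x, model)
  lp <- if (ncol(X)) drop(X %*% model$coefficients) else rep(0, nrow(x))
  lp <- lp + eta
  H0 <- baseline_cumhaz(model$baseline, x$time)
  ev <- x$event == 1
  ll <- -exp(lp) * H0
  if (any(ev)) {
    h0 <- baseline_hazard(model$baseline, x$time[ev])
    if (any(h0 <= 0)) {
      warning("hazard is zero at an observed event time; log-likelihood is -Inf")
      return(-Inf)
    }
    ll[ev] <- ll[ev] + log(h0) + lp[ev]
  }
  sum(ll)
}

#' Laplace-approximated marginal log-likelihood for one subject
#'
#' With a frailty \eqn{\eta \sim N(0, \omega^2)} multiplying the hazard as
#' \eqn{e^\eta}, the subject's marginal likelihood integrates the conditional
#' likelihood over \eqn{\eta}. The Laplace approximation maximises the joint
#' log-density \eqn{f(\eta) = \ell(\eta) + \log\phi(\eta; 0, \omega^2)} and
#' evaluates
#' \deqn{\log L \approx f(\hat\eta) + \tfrac12\log(2\pi) - \tfrac12\log(-f''(\hat\eta)),}
#' with the curvature obtained by central finite differences. With
#' \eqn{\omega^2 = 0} this reduces exactly to [subject_loglik()] at
#' \eqn{\eta = 0}.
#'
#' @inheritParams subject_loglik
#' @return the approximate log marginal likelihood.
#' @export
laplace_marginal_loglik <- function(record, model) {
  stopifnot(inherits(model, "hazard_model"))
  w2 <- model$omega_sq
  if (w2 == 0) return(subject_loglik(record, model, eta = 0))
  sd <- sqrt(w2)
  f <- function(eta) subject_loglik(record, model, eta = eta) +
    stats::dnorm(eta, 0, sd, log = TRUE)
  opt <- stats::optimize(f, interval = c(-12 * sd - 2, 12 * sd + 2), maximum = TRUE,
                         tol = 1e-10)
  eta_hat <- opt$maximum
  h <- 1e-4
  curv <- (f(eta_hat + h) - 2 * opt$objective + f(eta_hat - h)) / h^2
  if (!is.finite(curv) || curv >= 0)
    stop("joint log-density is not concave at the frailty mode; ",
         "Laplace approximation failed for subject id ", record$id %||% "?")
  opt$objective + 0.5 * log(2 * pi) - 0.5 * log(-curv)
}

#' Objective function value (OFV)
#'
#' \eqn{-2 \times} the cohort log (marginal) likelihood: the scale on which
#' nested models are compared, with differences asymptotically chi-square.
#' Fixed-effect models (`omega_sq = 0`) use a closed-form vectorised
#' likelihood; with frailty each subject's marginal is integrated by the
#' Laplace approximation.
#'
#' @param x a [cohort()].
#' @param model a [hazard_model()].
#' @return the OFV (dimensionless).
#' @export
ofv <- function(x, model) {
  stopifnot(inherits(x, "cohort"), inherits(model, "hazard_model"))
  if (model$omega_sq == 0) return(-2 * cohort_loglik_fixed(x, model))
  ll <- vapply(seq_len(nrow(x)), function(i)
    laplace_marginal_loglik(as.list(as.data.frame(x)[i, , drop = FALSE]), model),
    numeric(1))
  -2 * sum(ll)
}

#' Likelihood-ratio test from OFVs
#'
#' Compares two nested fits on the OFV scale: `delta = ofv_reduced - ofv_full`
#' is referred to a chi-square distribution with `df` degrees of freedom
#' (one per added covariate coefficient). A negative difference (numerical
#' noise) is clipped to 0.
#'
#' @param ofv_reduced,ofv_full OFVs of the reduced and full model.
#' @param df degrees of freedom (>= 1).
#' @return the upper-tail p-value.
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1) {
  if (df < 1) stop("'df' must be at least 1")
  delta <- ofv_reduced - ofv_full
  if (delta < -1e-6)
    warning("reduced model has lower OFV than the full model (non-nested fits?)")
  stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
}

## ---- parameter packing: model <-> transformed vector ----------------------

# Free parameters: one per unique level name (log scale), one per unique
# non-constant shape name (identity), one per coefficient (identity), plus
# log omega^2 when frailty is estimated. Segments sharing a name share the
# free parameter.
param_map <- function(model, estimate_frailty = FALSE) {
  segs <- model$baseline$segments
  lev_names <- character(0); shp_names <- character(0)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    ln <- s$level_name %||% sprintf("level_%d", i)
    lev_names <- c(lev_names, ln)
    if (s$form != "constant") {
      sn <- s$shape_name %||% sprintf("shape_%d", i)
      shp_names <- c(shp_names, sn)
    }
  }
  entries <- data.frame(
    name = c(unique(lev_names), unique(shp_names), names(model$coefficients)),
    kind = c(rep("level", length(unique(lev_names))),
             rep("shape", length(unique(shp_names))),
             rep("coef", length(model$coefficients))),
    transform = c(rep("log", length(unique(lev_names))),
                  rep("identity", length(unique(shp_names))),
                  rep("identity", length(model$coefficients))),
    stringsAsFactors = FALSE)
  if (estimate_frailty)
    entries <- rbind(entries, data.frame(name = "omega_sq", kind = "frailty",
                                         transform = "log"))
  entries
}

pack_params <- function(model, map) {
  segs <- model$baseline$segments
  val <- numeric(nrow(map))
  for (k in seq_len(nrow(map))) {
    nm <- map$name[k]
    v <- switch(map$kind[k],
                level = {
                  hit <- NA_real_
                  for (i in seq_along(segs)) {
                    ln <- segs[[i]]$level_name %||% sprintf("level_%d", i)
                    if (ln == nm) { hit <- segs[[i]]$level; break }
                  }
                  hit
                },
                shape = {
                  hit <- NA_real_
                  for (i in seq_along(segs)) {
                    sn <- segs[[i]]$shape_name %||% sprintf("shape_%d", i)
                    if (segs[[i]]$form != "constant" && sn == nm) {
                      hit <- segs[[i]]$shape; break
                    }
                  }
                  hit
                },
                coef = model$coefficients[[nm]],
                frailty = model$omega_sq)
    val[k] <- if (map$transform[k] == "log") log(v) else v
  }
  stats::setNames(val, map$name)
}

unpack_params <- function(par_t, model, map) {
  nat <- ifelse(map$transform == "log", exp(par_t), par_t)
  names(nat) <- map$name
  segs <- model$baseline$segments
  for (i in seq_along(segs)) {
    ln <- segs[[i]]$level_name %||% sprintf("level_%d", i)
    if (ln %in% map$name[map$kind == "level"]) segs[[i]]$level <- nat[[ln]]
    if (segs[[i]]$form != "constant") {
      sn <- segs[[i]]$shape_name %||% sprintf("shape_%d", i)
      if (sn %in% map$name[map$kind == "shape"]) segs[[i]]$shape <- nat[[sn]]
    }
  }
  model$baseline$segments <- segs
  coef_names <- map$name[map$kind == "coef"]
  if (length(coef_names)) model$coefficients[coef_names] <- nat[coef_names]
  if ("omega_sq" %in% map$name) model$omega_sq <- nat[["omega_sq"]]
  model
}

# central finite-difference Hessian
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

model_ofv_fn <- function(x, model, map) {
  function(par_t) {
    if (any(!is.finite(par_t)) || any(abs(par_t) > 50)) return(1e10)
    m <- unpack_params(par_t, model, map)
    for (s in m$baseline$segments)
      if (s$form == "weibull" && s$shape <= -1 + 1e-8) return(1e10)
    val <- tryCatch(suppressWarnings(ofv(x, m)), error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
}

#' Maximum-likelihood fit of a hazard model
#'
#' Minimises the OFV over the model's free parameters by quasi-Newton (BFGS)
#' iteration on a transformed scale: log for positive-constrained baseline
#' scales and the frailty variance, identity for shapes and covariate
#' coefficients. Segments sharing a `level_name`/`shape_name` share one free
#' parameter. Standard errors come from the inverse finite-difference
#' Hessian on the transformed scale (central differences, step `1e-4`), with
#' natural-scale SEs and RSE% by the delta method.
#'
#' @param x a [cohort()] with at least one event.
#' @param model a [hazard_model()] whose parameter values are the starting
#'   point (use `init` to override).
#' @param init optional named numeric vector of natural-scale starting values
#'   (by parameter name from the model's level/shape/coefficient names).
#' @param estimate_frailty if `TRUE`, `omega_sq` is estimated (log scale);
#'   default `FALSE` (fixed-effect analysis).
#' @param robust if `TRUE`, runs 3 additional jittered starts (deterministic
#'   sub-seeds derived from `seed`) and keeps the best OFV.
#' @param seed integer seed used only for the jittered starts.
#' @param control list passed to [stats::optim()]'s `control` (defaults:
#'   `maxit = 500`, `reltol = 1e-10`).
#' @return a `fit_result`: the fitted `model`, an `estimates` table (name,
#'   transform, estimate, se, rse), `ofv`, `converged`, `covariance`
#'   (transformed scale; `NULL` if the Hessian is not positive definite),
#'   and bookkeeping fields.
#' @export
fit_mle <- function(x, model, init = NULL, estimate_frailty = FALSE,
                    robust = FALSE, seed = 1L, control = list()) {
  stopifnot(inherits(x, "cohort"), inherits(model, "hazard_model"))
  if (sum(x$event) < 1) stop("cohort has no events; nothing to fit")
  map <- param_map(model, estimate_frailty = estimate_frailty)
  if (!is.null(init)) {
    for (nm in names(init)) {
      k <- match(nm, map$name)
      if (is.na(k)) stop("unknown parameter in 'init': ", nm)
    }
    # write init into the model by round-tripping through the packing
    par0 <- pack_params(model, map)
    tv <- ifelse(map$transform[match(names(init), map$name)] == "log",
                 log(unlist(init)), unlist(init))
    par0[names(init)] <- tv
    model <- unpack_params(par0, model, map)
  }
  fn <- model_ofv_fn(x, model, map)
  par0 <- pack_params(model, map)
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  starts <- list(par0)
  if (robust) {
    rs <- derive_seeds(seed, 3L)
    for (k in 1:3) {
      set.seed(rs[k])
      starts[[k + 1]] <- par0 + stats::rnorm(length(par0), 0, 0.3)
    }
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, fn, method = "BFGS", control = ctrl)
    if (is.null(best) || o$value < best$value) best <- o
  }
  conv <- best$convergence == 0 && best$value < 1e9
  par_hat <- best$par
  H <- fd_hessian(fn, par_hat)
  cov_t <- NULL
  se_t <- rep(NA_real_, length(par_hat))
  # OFV = -2 loglik, so the nll Hessian is H/2 and cov = 2 H^{-1}
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA)
  if (all(is.finite(ev)) && all(ev > 0)) {
    cov_t <- 2 * solve(H)
    dimnames(cov_t) <- list(map$name, map$name)
    se_t <- sqrt(diag(cov_t))
  }
  nat <- ifelse(map$transform == "log", exp(par_hat), par_hat)
  se_nat <- ifelse(map$transform == "log", nat * se_t, se_t)
  rse <- ifelse(is.na(se_nat), NA_real_, 100 * se_nat / abs(nat))
  est <- data.frame(name = map$name, kind = map$kind, transform = map$transform,
                    estimate = as.numeric(nat), se = as.numeric(se_nat),
                    rse = as.numeric(rse), stringsAsFactors = FALSE)
  structure(list(model = unpack_params(par_hat, model, map),
                 estimates = est,
                 par_transformed = stats::setNames(par_hat, map$name),
                 ofv = best$value,
                 converged = conv,
                 covariance = cov_t,
                 n_subjects = nrow(x), n_events = sum(x$event),
                 map = map),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Hazard-model fit: OFV = %.4f (%s), %d subjects / %d events\n",
              x$ofv, if (x$converged) "converged" else "NOT converged",
              x$n_subjects, x$n_events))
  est <- x$estimates
  for (k in seq_len(nrow(est)))
    cat(sprintf("  %-12s %10.5g  (RSE %s)\n", est$name[k], est$estimate[k],
                if (is.na(est$rse[k])) "n/a" else sprintf("%.1f%%", est$rse[k])))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes parameter names, natural-scale estimates, SEs, RSE%, the OFV and
#' convergence flag — and, when `reference` is supplied, the OFV difference
#' and 1-df likelihood-ratio p-value against that reference fit (the
#' OFV / dOFV / p-value layout used in model-comparison tables).
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @param reference optional `fit_result` of a nested reduced model.
#' @param df degrees of freedom for the reference comparison.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, reference = NULL, df = 1) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(parameters = fit$estimates,
              ofv = fit$ofv, converged = fit$converged,
              n_subjects = fit$n_subjects, n_events = fit$n_events)
  if (!is.null(reference)) {
    d <- reference$ofv - fit$ofv
    out$reference <- list(ofv = reference$ofv, delta_ofv = d,
                          df = df, p_value = lrt(reference$ofv, fit$ofv, df))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# deterministic sub-seeds below 2^31 for independent RNG streams
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}
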