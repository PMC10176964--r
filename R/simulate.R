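#' Synthetic registry-cohort simulation configuration
#'
#' Describes a registry-like cohort to generate: independent Bernoulli
#' binary covariates at given prevalences, event times drawn from a fully
#' parameterised hazard model by inverse-transform sampling through the
#' cumulative hazard, and administrative right-censoring. The defaults
#' emulate the structure of the source stroke-registry population:
#' 7,697 subjects, four binary comorbidity/treatment covariates at their
#' registry prevalences, and follow-up capped at 7.37 years.
#'
#' Two censoring schemes are available. `"uniform-entry"` (default) draws a
#' per-subject censoring time uniformly on (0, horizon], mimicking staggered
#' enrollment over several calendar years with a fixed data cutoff;
#' `"fixed-horizon"` censors everyone at the horizon (useful for clean unit
#' checks).
#'
#' @param n_subjects number of subjects.
#' @param model the true [hazard_model()] generating the event times.
#' @param prevalences named probabilities for the model's covariates.
#' @param censoring_horizon maximum follow-up in years.
#' @param censoring_scheme `"uniform-entry"` or `"fixed-horizon"`.
#' @param seed master integer seed; four independent sub-streams (covariates,
#'   frailty, event times, censoring) are derived from it, so adding or
#'   removing covariates does not perturb the event-time draws.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects,
                              model = stroke_model(),
                              prevalences = stroke_prevalences(),
                              censoring_horizon = 7.37,
                              censoring_scheme = c("uniform-entry", "fixed-horizon"),
                              seed = 1L) {
  censoring_scheme <- match.arg(censoring_scheme)
  stopifnot(n_subjects >= 1, censoring_horizon > 0,
            inherits(model, "hazard_model"))
  if (length(model$coefficients)) {
    missing <- setdiff(names(model$coefficients), names(prevalences))
    if (length(missing))
      stop("no prevalence configured for model covariate(s): ",
           paste(missing, collapse = ", "))
  }
  # prevalences may list extra covariates with no effect in the true model;
  # they are sampled as columns (null candidates for covariate-search studies)
  if (length(prevalences) && (any(prevalences < 0) || any(prevalences > 1)))
    stop("prevalences must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 prevalences = prevalences,
                 censoring_horizon = censoring_horizon,
                 censoring_scheme = censoring_scheme,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param path YAML file with keys mirroring the `simulation_config`
#'   arguments plus a `model` block in [read_hazard_model()] layout (or a
#'   `model_file` path).
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- if (!is.null(y$model_file)) {
    read_hazard_model(file.path(dirname(path), y$model_file))
  } else if (!is.null(y$model)) {
    tmp <- tempfile(fileext = ".yaml"); on.exit(unlink(tmp))
    yaml::write_yaml(y$model, tmp)
    read_hazard_model(tmp)
  } else stroke_model()
  simulation_config(n_subjects = y$n_subjects,
                    model = model,
                    prevalences = unlist(y$prevalences %||% stroke_prevalences()),
                    censoring_horizon = y$censoring_horizon %||% 7.37,
                    censoring_scheme = y$censoring_scheme %||% "uniform-entry",
                    seed = y$seed %||% 1L)
}

#' Sample binary covariates
#'
#' Independent Bernoulli draws per covariate per subject, at the configured
#' prevalences, on the configuration's dedicated covariate RNG stream.
#'
#' @param config a [simulation_config()].
#' @return an `n_subjects` x `n_covariates` 0/1 matrix (named columns).
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  streams <- derive_seeds(config$seed, 4L)
  sample_covariates_stream(config, streams[1])
}

sample_covariates_stream <- function(config, stream_seed) {
  p <- config$prevalences
  X <- matrix(0, config$n_subjects, length(p),
              dimnames = list(NULL, names(p)))
  if (length(p)) {
    set.seed(stream_seed)
    for (j in seq_along(p))
      X[, j] <- stats::rbinom(config$n_subjects, 1L, p[j])
  }
  X
}

#' Sample event times by inverting the cumulative hazard
#'
#' Standard inverse-transform simulation for survival models: draw
#' \eqn{u \sim U(0,1)} and return the time at which the subject's cumulative
#' hazard reaches \eqn{-\log u}. Returns `Inf` for subjects whose total
#' cumulative hazard never reaches the target (a decaying hazard leaves a
#' "never" mass). Vectorised over subjects.
#'
#' @param model a fully parameterised [hazard_model()].
#' @param X covariate matrix (rows = subjects, columns named by coefficient);
#'   `NULL` for a covariate-free model.
#' @param eta per-subject frailty values (default all 0).
#' @param u optional uniform draws (for deterministic checks); drawn from
#'   the current RNG state when `NULL`.
#' @param n number of subjects when `X` is `NULL`.
#' @return event times in years (possibly `Inf`).
#' @export
sample_event_time <- function(model, X = NULL, eta = 0, u = NULL, n = NULL) {
  stopifnot(inherits(model, "hazard_model"))
  if (is.null(n)) n <- if (!is.null(X)) nrow(X) else length(u) %||% 1L
  if (is.null(u)) u <- stats::runif(n)
  lp <- if (length(model$coefficients)) {
    stopifnot(!is.null(X))
    drop(as.matrix(X)[, names(model$coefficients), drop = FALSE] %*%
           model$coefficients)
  } else rep(0, n)
  mult <- exp(lp + eta)
  invert_baseline_cumhaz(model$baseline, -log(u) / mult)
}

#' Generate a synthetic cohort
#'
#' Per subject: covariates are sampled at the configured prevalences, a
#' frailty is drawn if the model has `omega_sq > 0`, an event time is drawn
#' by inverse-transform sampling, and a censoring time is drawn per the
#' censoring scheme. The record's `time` is `min(event, censoring)` and
#' `event = 1` iff the event came first. Fully reproducible from the master
#' seed; the four RNG streams are independent.
#'
#' The returned cohort carries the per-subject censoring times as attribute
#' `"censor_time"` (used by [vpc()] to preserve the observation design) and
#' attribute `"sim_seed"`.
#'
#' @param config a [simulation_config()].
#' @return a [cohort()]. If no events occurred the cohort is still returned,
#'   with a warning (downstream fitting will refuse it).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  streams <- derive_seeds(config$seed, 4L)
  X <- sample_covariates_stream(config, streams[1])
  eta <- if (config$model$omega_sq > 0) {
    set.seed(streams[2])
    stats::rnorm(n, 0, sqrt(config$model$omega_sq))
  } else rep(0, n)
  set.seed(streams[3])
  u <- stats::runif(n)
  E <- sample_event_time(config$model, X = if (ncol(X)) X else NULL,
                         eta = eta, u = u)
  C <- switch(config$censoring_scheme,
              "fixed-horizon" = rep(config$censoring_horizon, n),
              "uniform-entry" = {
                set.seed(streams[4])
                stats::runif(n, 0, config$censoring_horizon)
              })
  time <- pmin(E, C)
  event <- as.integer(E <= C)
  dat <- data.frame(id = seq_len(n), time = time, event = event)
  for (j in colnames(X)) dat[[j]] <- X[, j]
  out <- cohort(dat, covariate_names = colnames(X))
  attr(out, "censor_time") <- C
  attr(out, "sim_seed") <- config$seed
  if (sum(event) == 0) warning("simulated cohort contains no events")
  out
}

#' Write a simulation manifest
#'
#' Records seed, configuration digest, and package version alongside a
#' generated cohort, sufficient to regenerate it bit-identically.
#'
#' @param config the [simulation_config()] used.
#' @param cohort_path path of the written cohort CSV.
#' @param path manifest JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_manifest <- function(config, cohort_path, path) {
  cfg <- list(n_subjects = config$n_subjects,
              prevalences = as.list(config$prevalences),
              censoring_horizon = config$censoring_horizon,
              censoring_scheme = config$censoring_scheme,
              seed = config$seed)
  jsonlite::write_json(list(
    generator = "recurtte::generate_cohort",
    version = as.character(utils::packageVersion("recurtte")),
    config = cfg,
    cohort_file = basename(cohort_path)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
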