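#' Stepwise covariate modelling configuration
#'
#' Settings for the forward-inclusion / backward-elimination search over
#' binary covariates, driven by OFV differences. Each covariate adds one
#' coefficient, so every test has 1 degree of freedom. Default significance
#' levels are 0.05 forward (chi-square(1) critical value 3.84) and 0.01
#' backward (6.63): a candidate enters when its OFV drop strictly exceeds
#' the forward threshold, and an included covariate is retained when
#' removing it would raise the OFV by at least the backward threshold.
#'
#' @param candidates character vector of candidate covariate names.
#' @param forward_alpha forward-inclusion significance level.
#' @param backward_alpha backward-elimination significance level
#'   (must not exceed `forward_alpha`).
#' @param max_steps cap on the total number of forward + backward steps.
#' @return an `scm_config` list, including the derived `forward_dofv` /
#'   `backward_dofv` chi-square(1) thresholds.
#' @export
scm_config <- function(candidates, forward_alpha = 0.05, backward_alpha = 0.01,
                       max_steps = 50L) {
  stopifnot(length(candidates) >= 0, is.character(candidates) || length(candidates) == 0,
            forward_alpha > 0, forward_alpha < 1,
            backward_alpha > 0, backward_alpha <= forward_alpha)
  structure(list(candidates = candidates,
                 forward_alpha = forward_alpha,
                 backward_alpha = backward_alpha,
                 forward_dofv = stats::qchisq(1 - forward_alpha, df = 1),
                 backward_dofv = stats::qchisq(1 - backward_alpha, df = 1),
                 max_steps = as.integer(max_steps)),
            class = "scm_config")
}

scm_step_row <- function(phase, covariate, ofv_base, ofv_test, decision) {
  delta <- ofv_base - ofv_test
  data.frame(phase = phase, covariate = covariate,
             ofv_base = ofv_base, ofv_test = ofv_test,
             delta_ofv = delta, df = 1L,
             p = stats::pchisq(max(delta, 0), 1, lower.tail = FALSE),
             decision = decision, stringsAsFactors = FALSE)
}

add_covariate <- function(model, name, value = 0) {
  model$coefficients <- c(model$coefficients, stats::setNames(value, name))
  model
}

drop_covariate <- function(model, name) {
  model$coefficients <- model$coefficients[setdiff(names(model$coefficients), name)]
  model
}

# fit current model plus one candidate, warm-started at the current estimates
fit_with_candidate <- function(x, current_fit, name) {
  m <- add_covariate(current_fit$model, name, 0)
  fit_mle(x, m)
}

#' Univariate covariate screen
#'
#' Tests each candidate covariate one at a time on the base hazard model and
#' reports the OFV drop and 1-df p-value, sorted by OFV drop (largest
#' first). The screen is advisory — it orders and reports, but does not
#' exclude candidates from the stepwise search.
#'
#' @param x a [cohort()].
#' @param base a fitted base `fit_result` (or a [hazard_model()] to be
#'   fitted first) containing none of the candidates.
#' @param candidates character vector of covariate names present in `x`.
#' @return a data frame (covariate, delta_ofv, df, p), sorted by
#'   `delta_ofv` descending.
#' @export
univariate_screen <- function(x, base, candidates) {
  if (inherits(base, "hazard_model")) base <- fit_mle(x, base)
  stopifnot(inherits(base, "fit_result"))
  if (any(candidates %in% names(base$model$coefficients)))
    stop("base model already contains candidate covariate(s)")
  missing <- setdiff(candidates, attr(x, "covariate_names"))
  if (length(missing))
    stop("candidate covariate(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  rows <- lapply(candidates, function(cv) {
    f <- tryCatch(fit_with_candidate(x, base, cv), error = function(e) NULL)
    if (is.null(f)) {
      warning("univariate fit failed for covariate ", cv)
      return(data.frame(covariate = cv, delta_ofv = NA_real_, df = 1L,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    d <- base$ofv - f$ofv
    data.frame(covariate = cv, delta_ofv = d, df = 1L,
               p = stats::pchisq(max(d, 0), 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$delta_ofv, out$covariate), , drop = FALSE]
}

#' One forward-inclusion step
#'
#' Fits the current model extended by each remaining candidate, and includes
#' the candidate with the largest OFV drop if that drop strictly exceeds the
#' forward threshold. Ties (within 1e-6) are broken by the lexicographically
#' smaller covariate name. Candidates whose fit fails are skipped with a
#' warning.
#'
#' @param x a [cohort()].
#' @param current_fit the current `fit_result`.
#' @param remaining character vector of candidates not yet included.
#' @param config an [scm_config()].
#' @return list with `fit` (the updated `fit_result`, or `NULL` on stop),
#'   `included` (covariate name or `NA`), and `trace` (one row per tested
#'   candidate plus the decision).
#' @export
forward_step <- function(x, current_fit, remaining, config) {
  stopifnot(inherits(current_fit, "fit_result"), length(remaining) >= 1)
  fits <- list(); rows <- list()
  for (cv in remaining) {
    f <- tryCatch(fit_with_candidate(x, current_fit, cv), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("forward fit for covariate ", cv, " did not converge; skipped")
      next
    }
    fits[[cv]] <- f
    rows[[cv]] <- scm_step_row("forward", cv, current_fit$ofv, f$ofv, "tested")
  }
  trace <- do.call(rbind, rows)
  if (is.null(trace) || nrow(trace) == 0)
    return(list(fit = NULL, included = NA_character_, trace = trace))
  d <- trace$delta_ofv
  best <- which(d > max(d) - 1e-6)
  pick <- best[order(trace$covariate[best])][1]
  if (trace$delta_ofv[pick] > config$forward_dofv) {
    trace$decision[pick] <- "included"
    list(fit = fits[[trace$covariate[pick]]], included = trace$covariate[pick],
         trace = trace)
  } else {
    trace$decision <- ifelse(seq_len(nrow(trace)) == pick, "stop (best below threshold)",
                             trace$decision)
    list(fit = NULL, included = NA_character_, trace = trace)
  }
}

#' One backward-elimination step
#'
#' Refits the current model with each included covariate removed. The
#' covariate whose removal raises the OFV the least is dropped if that rise
#' is below the backward threshold; if even the smallest rise meets the
#' threshold, every covariate is retained and the phase stops.
#'
#' @inheritParams forward_step
#' @return list with `fit` (reduced `fit_result`, or `NULL` on stop),
#'   `dropped` (name or `NA`), and `trace`.
#' @export
backward_step <- function(x, current_fit, config) {
  stopifnot(inherits(current_fit, "fit_result"))
  incl <- names(current_fit$model$coefficients)
  if (!length(incl)) stop("backward step requires at least one included covariate")
  fits <- list(); rows <- list()
  for (cv in incl) {
    m <- drop_covariate(current_fit$model, cv)
    f <- tryCatch(fit_mle(x, m), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("backward fit removing ", cv, " did not converge; skipped")
      next
    }
    fits[[cv]] <- f
    # delta = rise in OFV caused by removal (reduced - full)
    rows[[cv]] <- scm_step_row("backward", cv, f$ofv, current_fit$ofv, "tested")
  }
  trace <- do.call(rbind, rows)
  if (is.null(trace) || nrow(trace) == 0)
    return(list(fit = NULL, dropped = NA_character_, trace = trace))
  d <- trace$delta_ofv
  worst <- which(d < min(d) + 1e-6)
  pick <- worst[order(trace$covariate[worst])][1]
  if (trace$delta_ofv[pick] < config$backward_dofv) {
    trace$decision[pick] <- "dropped"
    list(fit = fits[[trace$covariate[pick]]], dropped = trace$covariate[pick],
         trace = trace)
  } else {
    trace$decision <- ifelse(seq_len(nrow(trace)) == pick, "stop (all retained)",
                             trace$decision)
    list(fit = NULL, dropped = NA_character_, trace = trace)
  }
}

#' Run the full stepwise covariate search
#'
#' Univariate screen (advisory ordering), forward inclusion to exhaustion,
#' then backward elimination to exhaustion. The forward phase never removes
#' covariates and the backward phase never re-adds them. Every fit is
#' recorded in the trace for audit; the whole procedure is deterministic for
#' a fixed cohort and configuration.
#'
#' @param x a [cohort()].
#' @param base a base [hazard_model()] (no candidates included) or its
#'   `fit_result`.
#' @param config an [scm_config()].
#' @return an `scm_result`: `final_fit`, `trace` (phase, covariate,
#'   ofv_base, ofv_test, delta_ofv, df, p, decision), `screen` (the
#'   univariate table), `selected` (final covariate names), and `completed`
#'   (`FALSE` if `max_steps` was hit).
#' @export
run_scm <- function(x, base, config) {
  stopifnot(inherits(config, "scm_config"))
  if (inherits(base, "hazard_model")) base <- fit_mle(x, base)
  stopifnot(inherits(base, "fit_result"))
  trace <- scm_step_row("base", "(none)", base$ofv, base$ofv, "base model")
  if (!length(config$candidates)) {
    return(structure(list(final_fit = base, trace = trace,
                          screen = NULL, selected = character(0),
                          completed = TRUE), class = "scm_result"))
  }
  screen <- univariate_screen(x, base, config$candidates)
  current <- base
  remaining <- sort(config$candidates)
  steps <- 0L; completed <- TRUE
  while (length(remaining)) {
    steps <- steps + 1L
    if (steps > config$max_steps) { completed <- FALSE; break }
    st <- forward_step(x, current, remaining, config)
    if (!is.null(st$trace)) trace <- rbind(trace, st$trace)
    if (is.null(st$fit)) break
    current <- st$fit
    remaining <- setdiff(remaining, st$included)
  }
  while (completed && length(names(current$model$coefficients))) {
    steps <- steps + 1L
    if (steps > config$max_steps) { completed <- FALSE; break }
    st <- backward_step(x, current, config)
    if (!is.null(st$trace)) trace <- rbind(trace, st$trace)
    if (is.null(st$fit)) break
    current <- st$fit
  }
  structure(list(final_fit = current, trace = trace, screen = screen,
                 selected = sort(names(current$model$coefficients)),
                 completed = completed),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate search:",
      if (x$completed) "completed" else "stopped at max_steps", "\n")
  cat("Selected covariates:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("Final OFV: %.4f\n", x$final_fit$ofv))
  invisible(x)
}

#' Write an SCM trace as CSV
#'
#' @param result an `scm_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scm_trace <- function(result, path) {
  stopifnot(inherits(result, "scm_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
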