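#' Hazard ratio from a log-hazard coefficient
#'
#' Exponentiation of a proportional-hazards coefficient gives the
#' multiplicative effect of the covariate on the hazard.
#'
#' @param coefficient finite numeric coefficient(s).
#' @return `exp(coefficient)`.
#' @export
hazard_ratio <- function(coefficient) {
  if (any(!is.finite(coefficient))) stop("'coefficient' must be finite")
  exp(coefficient)
}

#' Half-life of an exponentially changing hazard
#'
#' For a Gompertz hazard \eqn{h_0 e^{\beta t}}, the time over which the
#' hazard halves (or doubles) is \eqn{\ln 2 / |\beta|}. The result carries a
#' `direction` attribute: `"decay"` when the hazard shrinks with time
#' (negative shape), `"growth"` otherwise.
#'
#' @param shape Gompertz shape in per-year units; must be non-zero.
#' @return half-life in years, with attribute `direction`.
#' @export
half_life <- function(shape) {
  if (any(shape == 0)) stop("half-life is undefined for shape = 0")
  structure(log(2) / abs(shape),
            direction = ifelse(shape < 0, "decay", "growth"))
}

#' Survival curves for covariate-defined risk groups
#'
#' Evaluates the model survivor function on a time grid for each covariate
#' profile — e.g. treated vs untreated, or counts of concomitant risk
#' factors. Groups whose combined hazard multiplier is below 1 lie above
#' the reference (all-zero) curve at every positive time.
#'
#' @param model a [hazard_model()].
#' @param groups named list of covariate vectors (named 0/1 per model
#'   covariate).
#' @param horizon grid end, years.
#' @param grid_points grid resolution.
#' @return a data frame with `time` and one survival column per group.
#' @export
risk_group_curves <- function(model, groups, horizon = 7.37, grid_points = 200L) {
  stopifnot(inherits(model, "hazard_model"), length(groups) >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list")
  tt <- seq(0, horizon, length.out = grid_points)
  out <- data.frame(time = tt)
  for (g in names(groups)) {
    x <- groups[[g]]
    unknown <- setdiff(names(x), names(model$coefficients))
    if (length(unknown))
      stop("unknown covariate(s) in group '", g, "': ",
           paste(unknown, collapse = ", "))
    out[[g]] <- survival_prob(model, x = x, t = tt)
  }
  out
}

#' Compare baseline hazard families by OFV
#'
#' Fits the same cohort under constant, Gompertz, and Weibull baseline
#' hazards (single segment, no covariates unless supplied) and tabulates
#' OFV, the OFV difference versus the constant model, and the 1-df
#' likelihood-ratio p-value — the standard base-model selection table.
#'
#' @param x a [cohort()].
#' @param families subset of `c("constant", "gompertz", "weibull")`.
#' @param coefficients optional named starting coefficients included in all
#'   fits.
#' @return a `data.frame` (n_parameters, model, ofv, delta_ofv, p) with the
#'   fits attached as attribute `"fits"`.
#' @export
compare_baselines <- function(x, families = c("constant", "gompertz", "weibull"),
                              coefficients = numeric(0)) {
  stopifnot(inherits(x, "cohort"))
  families <- match.arg(families, several.ok = TRUE)
  rate0 <- sum(x$event) / sum(x$time)   # crude exposure rate as starting value
  fits <- list()
  for (fam in families) {
    seg <- hazard_segment(0, Inf, fam, level = rate0, shape = 0,
                          level_name = "th1",
                          shape_name = if (fam == "constant") NULL else "th2")
    m <- hazard_model(baseline_spec(list(seg)), coefficients = coefficients)
    fits[[fam]] <- fit_mle(x, m)
  }
  ref <- if ("constant" %in% families) fits[["constant"]]$ofv else fits[[1]]$ofv
  out <- data.frame(
    n_parameters = vapply(fits, function(f) nrow(f$estimates), integer(1)),
    model = names(fits),
    ofv = vapply(fits, `[[`, numeric(1), "ofv"),
    stringsAsFactors = FALSE)
  out$delta_ofv <- out$ofv - ref
  out$p <- ifelse(out$model == "constant", NA_real_,
                  mapply(function(o, np) lrt(ref, o, df = max(np - 1, 1)),
                         out$ofv, out$n_parameters))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' End-to-end demonstration pipeline
#'
#' Chains the full analysis on a synthetic registry cohort: simulate from a
#' known model, fit the base hazard, run the stepwise covariate search, run
#' a Kaplan-Meier visual predictive check of the final model, and quantify
#' parameter uncertainty by SIR. All artifacts (cohort CSV, fit JSONs, SCM
#' trace CSV, VPC CSV, SIR report JSON, manifest) are written to `out_dir`.
#'
#' Sized for a desk run: the defaults finish in a few minutes on one core.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every stochastic stage.
#' @param n_subjects synthetic cohort size.
#' @param n_sim VPC replicate count.
#' @param true_model generating [hazard_model()]; the default is a
#'   decaying two-phase Gompertz baseline with the packaged covariate
#'   effects, which yields a registry-like low event fraction.
#' @param prevalences covariate prevalences for the generator.
#' @return invisibly, a list with the fitted objects and artifact paths.
#' @export
run_demo <- function(out_dir, seed = 1L, n_subjects = 2000L, n_sim = 200L,
                     true_model = stroke_model(levels = c(0.08, 0.02),
                                               shapes = c(-1.63, -0.23)),
                     prevalences = stroke_prevalences()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  cfg <- simulation_config(n_subjects, model = true_model,
                           prevalences = prevalences, seed = seed)
  coh <- generate_cohort(cfg)
  write_cohort(coh, p("cohort.csv"))
  write_sim_manifest(cfg, p("cohort.csv"), p("manifest.json"))
  base <- hazard_model(base_structure_from(true_model))
  base_fit <- fit_mle(coh, base)
  write_fit_json(base_fit, p("fit_base.json"))
  search <- run_scm(coh, base_fit,
                    scm_config(names(true_model$coefficients)))
  write_scm_trace(search, p("scm_trace.csv"))
  write_fit_json(search$final_fit, p("fit_final.json"), reference = base_fit,
                 df = max(length(search$selected), 1))
  bands <- vpc(search$final_fit$model, coh, n_sim = n_sim,
               horizon = cfg$censoring_horizon, seed = seed)
  write_vpc(bands, p("vpc.csv"))
  unc <- sir(search$final_fit, coh, seed = seed)
  jsonlite::write_json(rse_report(unc), p("sir_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = coh, base_fit = base_fit, scm = search,
                 vpc = bands, sir = unc, dir = out_dir))
}

# same baseline structure as a model, with neutral starting values and no
# covariates (the base model of a covariate search)
base_structure_from <- function(model) {
  segs <- lapply(model$baseline$segments, function(s) {
    hazard_segment(s$t_start, s$t_end, s$form, level = 0.05,
                   shape = if (s$form == "constant") 0 else -0.1,
                   level_name = s$level_name, shape_name = s$shape_name)
  })
  baseline_spec(segs)
}
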