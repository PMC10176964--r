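# shared fixtures: small models and cohorts built in code

const_model <- function(theta, ...) {
  hazard_model(hazard_segment(0, Inf, "constant", theta, level_name = "th1"), ...)
}

gompertz_model <- function(theta, beta, ...) {
  hazard_model(hazard_segment(0, Inf, "gompertz", theta, beta,
                              level_name = "th1", shape_name = "th2"), ...)
}

# a random piecewise model mixing all three forms (weibull only allowed to
# start the hazard; its negative-shape singularity sits at t = 0)
random_piecewise_model <- function() {
  k <- sample(1:3, 1)
  knots <- sort(runif(k - 1, 0.3, 4))
  bounds <- c(0, knots, Inf)
  segs <- vector("list", k)
  for (j in seq_len(k)) {
    form <- if (j == 1) sample(c("constant", "gompertz", "weibull"), 1)
            else sample(c("constant", "gompertz"), 1)
    segs[[j]] <- hazard_segment(
      bounds[j], bounds[j + 1], form,
      level = runif(1, 0.02, 1.5),
      shape = switch(form, constant = 0, gompertz = runif(1, -2, 2),
                     weibull = runif(1, -0.8, 2)))
  }
  hazard_model(baseline_spec(segs))
}

# independent quadrature oracle for the baseline cumulative hazard: adaptive
# Gauss-Kronrod per segment, with a power substitution s = w^10 to lift the
# integrable weibull singularity at t = 0 off the axis
quad_cumhaz <- function(spec, tt) {
  if (inherits(spec, "hazard_model")) spec <- spec$baseline
  total <- 0
  for (seg in spec$segments) {
    hi <- min(tt, seg$t_end)
    if (hi <= seg$t_start) next
    if (seg$form == "weibull" && seg$t_start == 0 && seg$shape < 0) {
      k <- 10
      total <- total + integrate(function(w)
        baseline_hazard(spec, w^k) * k * w^(k - 1),
        0, hi^(1 / k), rel.tol = 1e-12, subdivisions = 500L)$value
    } else {
      total <- total + integrate(function(s) baseline_hazard(spec, s),
                                 seg$t_start, hi, rel.tol = 1e-12,
                                 subdivisions = 500L)$value
    }
  }
  total
}

# tiny hand-rolled cohort data frame
toy_cohort <- function() {
  cohort(data.frame(id = 1:5,
                    time = c(1, 2, 2.5, 2.5, 2.5),
                    event = c(1, 1, 0, 0, 0),
                    HPLD = c(1, 0, 1, 0, 0)))
}

# single-subject record in the list form subject_loglik accepts
rec <- function(time, event, ...) c(list(id = 1L, time = time, event = event), list(...))
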