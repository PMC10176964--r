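#' Subject-level event cohort
#'
#' A cohort is a data frame with one row per subject — time-to-first-recurrence
#' data: a subject identifier, follow-up `time` in years (> 0), an `event`
#' indicator (1 = recurrent ischemic stroke observed at `time`, 0 = right
#' censored at `time`), and zero or more binary covariate columns. All
#' subjects carry the same covariate set; ids are unique.
#'
#' @param data a data frame with columns `id`, `time`, `event` and the
#'   covariate columns.
#' @param covariate_names character vector naming the covariate columns
#'   (default: every column other than id/time/event).
#' @return an object of class `cohort` (a validated data frame with
#'   attributes `covariate_names` and `max_followup`).
#' @export
cohort <- function(data, covariate_names = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("id", "time", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(data), required)
  data <- as.data.frame(data)[, c(required, covariate_names), drop = FALSE]
  validate_cohort(data, covariate_names)
  structure(data,
            covariate_names = covariate_names,
            max_followup = max(data$time),
            class = c("cohort", "data.frame"))
}

validate_cohort <- function(data, covariate_names) {
  if (nrow(data) == 0L) stop("cohort has no subjects")
  problems <- character(0)
  bad_row <- function(sel, what) {
    if (any(sel)) {
      ids <- utils::head(data$id[sel], 5L)
      problems <<- c(problems, sprintf(
        "%s (%d row(s), e.g. id %s)", what, sum(sel),
        paste(ids, collapse = ", ")))
    }
  }
  if (anyDuplicated(data$id))
    problems <- c(problems, sprintf(
      "duplicate subject ids (e.g. %s)",
      paste(utils::head(unique(data$id[duplicated(data$id)]), 5L), collapse = ", ")))
  tm <- suppressWarnings(as.numeric(data$time))
  bad_row(is.na(tm) | tm <= 0, "time must be a positive number")
  ev <- suppressWarnings(as.numeric(data$event))
  bad_row(is.na(ev) | !ev %in% c(0, 1), "event must be 0 or 1")
  for (cv in covariate_names) {
    v <- suppressWarnings(as.numeric(data[[cv]]))
    bad_row(is.na(v) | !v %in% c(0, 1),
            sprintf("covariate '%s' must be 0 or 1 (missing values are rejected)", cv))
  }
  if (length(problems))
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Column-name schema for cohort files
#'
#' Maps the canonical roles (id, time, event) to the column names used in a
#' delimited file, and lists the covariate columns. NONMEM-style headers
#' (`ID`, `TIME`, `DV`) are a common dialect for time-to-event datasets.
#'
#' @param id,time,event column names in the file.
#' @param covariates character vector of covariate column names, or `NULL`
#'   to take every remaining column.
#' @return a `cohort_schema` list.
#' @export
cohort_schema <- function(id = "id", time = "time", event = "event",
                          covariates = NULL) {
  structure(list(id = id, time = time, event = event, covariates = covariates),
            class = "cohort_schema")
}

#' @rdname cohort_schema
#' @param path YAML file with keys `id`, `time`, `event`, `covariates`.
#' @export
read_cohort_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_schema(id = y$id %||% "id", time = y$time %||% "time",
                event = y$event %||% "event",
                covariates = if (is.null(y$covariates)) NULL else unlist(y$covariates))
}

#' Read a cohort from a delimited text file
#'
#' Reads a comma-separated file with a header row, maps columns through the
#' schema, and validates every row (positive time, binary event and
#' covariates, unique ids). Rows violating the invariants are reported by
#' subject id and the read is rejected.
#'
#' @param path CSV file path.
#' @param schema a [cohort_schema()]; the default accepts lower-case
#'   `id/time/event` headers as well as NONMEM-style `ID/TIME/DV`.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(schema)) {
    nm <- names(raw)
    pick <- function(cands, role) {
      hit <- cands[cands %in% nm]
      if (!length(hit)) stop("no column for '", role, "' (looked for: ",
                             paste(cands, collapse = ", "), ")")
      hit[1]
    }
    schema <- cohort_schema(id = pick(c("id", "ID"), "id"),
                            time = pick(c("time", "TIME"), "time"),
                            event = pick(c("event", "EVENT", "DV"), "event"))
  }
  for (role in c("id", "time", "event")) {
    if (!schema[[role]] %in% names(raw))
      stop("schema column '", schema[[role]], "' (", role, ") not present in file")
  }
  covs <- schema$covariates %||% setdiff(names(raw),
                                         c(schema$id, schema$time, schema$event))
  missing_cov <- setdiff(covs, names(raw))
  if (length(missing_cov))
    stop("schema covariate column(s) not present in file: ",
         paste(missing_cov, collapse = ", "))
  out <- data.frame(id = raw[[schema$id]],
                    time = as.numeric(raw[[schema$time]]),
                    event = as.numeric(raw[[schema$event]]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (cv in covs) out[[cv]] <- as.numeric(raw[[cv]])
  cohort(out, covariate_names = covs)
}

#' Write a cohort to a delimited text file
#'
#' Writes CSV with a header and full numeric precision, so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x) == 0L) stop("refusing to write an empty cohort")
  out <- as.data.frame(x)
  out$time <- formatC(out$time, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a cohort
#'
#' Event counts, the event fraction, the median time to the event among
#' subjects with an event, and covariate prevalences overall and stratified
#' by event status — the shape of a registry "Table 1".
#'
#' @param x a [cohort()].
#' @return a `cohort_summary` list: `n_subjects`, `n_events`,
#'   `event_fraction`, `median_event_time` (NA when there are no events),
#'   `max_followup`, and `prevalence` (data frame with overall / event /
#'   non-event columns per covariate).
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x) == 0L) stop("cannot summarize an empty cohort")
  ev <- x$event == 1
  covs <- attr(x, "covariate_names")
  prev <- data.frame(covariate = covs,
                     overall = rep(NA_real_, length(covs)),
                     event = rep(NA_real_, length(covs)),
                     no_event = rep(NA_real_, length(covs)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(covs)) {
    v <- x[[covs[i]]]
    prev$overall[i] <- mean(v)
    prev$event[i] <- if (any(ev)) mean(v[ev]) else NA_real_
    prev$no_event[i] <- if (any(!ev)) mean(v[!ev]) else NA_real_
  }
  structure(list(n_subjects = nrow(x),
                 n_events = sum(ev),
                 event_fraction = sum(ev) / nrow(x),
                 median_event_time = if (any(ev)) stats::median(x$time[ev]) else NA_real_,
                 max_followup = max(x$time),
                 prevalence = prev),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d events (%.2f%%)\n",
              x$n_subjects, x$n_events, 100 * x$event_fraction))
  if (!is.na(x$median_event_time))
    cat(sprintf("Median time to event: %.3g years (events only)\n",
                x$median_event_time))
  cat(sprintf("Maximum follow-up: %.3g years\n", x$max_followup))
  if (nrow(x$prevalence)) {
    cat("Covariate prevalence (overall / event / no event):\n")
    for (i in seq_len(nrow(x$prevalence)))
      cat(sprintf("  %s: %.3f / %.3f / %.3f\n", x$prevalence$covariate[i],
                  x$prevalence$overall[i], x$prevalence$event[i],
                  x$prevalence$no_event[i]))
  }
  invisible(x)
}

# covariate design matrix aligned with a model's coefficients
cohort_design <- function(x, model) {
  nms <- names(model$coefficients)
  if (!length(nms)) return(matrix(0, nrow(x), 0))
  missing <- setdiff(nms, attr(x, "covariate_names"))
  if (length(missing))
    stop("cohort lacks covariate(s) required by the model: ",
         paste(missing, collapse = ", "))
  as.matrix(as.data.frame(x)[, nms, drop = FALSE])
}
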