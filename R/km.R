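#' Select a synthetic onset cohort
#'
#' Keeps patients eligible for onset-anchored survival analysis: an assessed
#' onset (time origin) and a minimum number of clinical EDSS observations.
#'
#' @param cohort An [edss_cohort()].
#' @param min_clinical_obs Minimum number of clinical records (default 2).
#' @param require_onset Require a known onset (default `TRUE`).
#' @return The filtered [edss_cohort()]; kept/dropped counts are reported.
#' @export
select_onset_cohort <- function(cohort, min_clinical_obs = 2,
                                require_onset = TRUE) {
  stopifnot(inherits(cohort, "edss_cohort"), min_clinical_obs >= 1)
  visits <- as.data.frame(cohort$visits)
  n_cli <- table(factor(visits$patient_id[visits$source == "clinical"],
                        cohort$patients$patient_id))
  keep <- as.numeric(n_cli) >= min_clinical_obs
  if (require_onset) keep <- keep & cohort$patients$onset_known
  ids <- cohort$patients$patient_id[keep]
  message("select_onset_cohort: kept ", length(ids), " of ",
          n_patients(cohort), " patients (min ", min_clinical_obs,
          " clinical obs", if (require_onset) ", onset required", ")")
  out <- edss_cohort(visits[visits$patient_id %in% ids, , drop = FALSE],
                     cohort$patients[keep, , drop = FALSE])
  out
}

#' Kaplan-Meier curve at one irreversible endpoint
#'
#' Product-limit estimate of the probability `p = 1 - f` of surviving an
#' irreversible EDSS endpoint (not yet having irreversibly progressed to
#' it), with time measured in years since onset. Right-censored patients
#' censor at their last clinical observation under every survival-time
#' assumption — the midpoint adjustment moves event times only, never the
#' right-censoring convention. At tied times events precede censorings
#' (standard product-limit convention).
#'
#' @param events Tibble of endpoint events for a single level and
#'   assumption, as produced by [endpoint_events()].
#' @param se Include Greenwood standard errors (default `FALSE`).
#' @return Object of class `km_curve`: the level, assumption, counts, and a
#'   step table with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (and `std_err` when `se = TRUE`).
#' @export
km_fit <- function(events, se = FALSE) {
  events <- as.data.frame(events)
  if (!nrow(events)) stop("no events to fit", call. = FALSE)
  if (length(unique(events$level)) != 1 ||
      length(unique(events$assumption)) != 1) {
    stop("km_fit expects events for a single level and assumption",
         call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(events$time, events$status == "event") ~ 1,
    conf.type = "none"
  )
  tab <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  if (se) tab$std_err <- fit$surv * fit$std.err  # Greenwood, survival scale
  structure(
    list(level = events$level[1], assumption = events$assumption[1],
         table = tab,
         n = nrow(events),
         n_events = sum(events$status == "event"),
         n_censored = sum(events$status == "right_censored")),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_survival(x)
  cat("<km_curve> endpoint EDSS ", x$level, " (", x$assumption,
      " survival time): ", x$n_events, " events, ", x$n_censored,
      " censored; median ",
      if (is.na(med)) "not reached" else paste0(format(med, digits = 4), " yso"),
      "\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier curves at a set of endpoints
#'
#' Builds endpoint events for every requested level under one survival-time
#' assumption (via [endpoint_events()]) and fits one product-limit curve per
#' level. The default level set is the integer endpoints EDSS 1–9.
#'
#' @param cohort An [edss_cohort()], typically filtered with
#'   [select_onset_cohort()].
#' @param levels Endpoint levels (default `1:9`).
#' @param assumption Survival-time assumption.
#' @param se Include Greenwood standard errors.
#' @return A list of `km_curve` objects (class `km_suite`), named by level.
#' @export
km_suite <- function(cohort, levels = 1:9, assumption = "maximum",
                     se = FALSE) {
  assumption <- match_assumption(assumption)
  events <- endpoint_events(cohort, levels, assumption)
  curves <- lapply(as.numeric(levels), function(e) {
    km_fit(events[events$level == e, , drop = FALSE], se = se)
  })
  names(curves) <- format(as.numeric(levels))
  structure(curves, class = "km_suite")
}

#' @export
print.km_suite <- function(x, ...) {
  cat("<km_suite> ", length(x), " endpoint curves (",
      x[[1]]$assumption, " survival time)\n", sep = "")
  for (cv in x) {
    med <- median_survival(cv)
    cat("  EDSS ", format(cv$level, width = 4), ": ", cv$n_events,
        " events / ", cv$n, " patients; median ",
        if (is.na(med)) "not reached" else
          paste0(format(med, digits = 4), " yso"), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a Kaplan-Meier suite into long format
#'
#' @param suite A `km_suite` (or single `km_curve`).
#' @return Tibble with columns `level`, `assumption`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_tidy <- function(suite) {
  if (inherits(suite, "km_curve")) suite <- list(suite)
  do.call(rbind, lapply(suite, function(cv) {
    cbind(tibble::tibble(level = cv$level, assumption = cv$assumption),
          cv$table)
  }))
}

#' Median survival time of a curve
#'
#' The smallest time at which the survival function falls to 0.5 or below;
#' `NA` when the curve never crosses 0.5 within follow-up.
#'
#' @param curve A `km_curve`.
#' @return A single time in years since onset, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$table$survival <= 0.5)
  if (!length(hit)) NA_real_ else curve$table$time[hit[1]]
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation: `S(t) = 1` before the first
#' tabulated time.
#'
#' @param curve A `km_curve`.
#' @param t Numeric vector of times (years since onset).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- curve$table
  if (!nrow(tab)) return(rep(1, length(t)))
  stats::stepfun(tab$time, c(1, tab$survival), right = FALSE)(t)
}
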