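#' EDSS assessment rates per patient-year
#'
#' The size of censoring bias is driven by how often patients are assessed.
#' This computes records per patient-year over a basis window — from first
#' to last clinical observation (interval-censoring window) or from assessed
#' onset to last clinical observation — counting either clinical
#' observations only (`"obs"`) or clinical plus expected midpoint measures
#' (`"obs_plus_exp"`). Onset anchors are never counted as observations.
#' The primary `rate` is pooled (total records / total person-years); the
#' mean of per-patient rates is reported alongside as `rate_mean`.
#'
#' Patients with a single clinical observation have a zero-length
#' first-to-last window and are excluded from `first_to_last` rates (with a
#' message); they are included in `onset_to_last`. Patients without a known
#' onset are excluded from the `onset_to_last` basis.
#'
#' The mean onset-to-first-observation gap (a left-censoring size measure)
#' is reported for onset-known patients; under `obs_plus_exp` counting, a
#' patient with expected measures uses their first expected measure as the
#' first observation.
#'
#' @param cohort An [edss_cohort()] (augmented, for `obs_plus_exp`).
#' @param basis `"first_to_last"` or `"onset_to_last"`.
#' @param counting `"obs"` or `"obs_plus_exp"`.
#' @return One row per study group (plus a pooled `"all"` row when several
#'   groups are present): `group`, `basis`, `counting`, `n_patients`,
#'   `total_records`, `person_years`, `rate`, `rate_mean`,
#'   `mean_onset_to_first`.
#' @export
assessment_rate <- function(cohort,
                            basis = c("first_to_last", "onset_to_last"),
                            counting = c("obs", "obs_plus_exp")) {
  stopifnot(inherits(cohort, "edss_cohort"))
  basis <- match.arg(basis)
  counting <- match.arg(counting)
  if (!n_patients(cohort)) stop("empty cohort", call. = FALSE)

  per <- patient_assessment_stats(cohort)
  groups <- patient_group_lists(cohort)
  labels <- sort(unique(unlist(groups)))
  rows <- lapply(labels, function(g) {
    sub <- per[vapply(groups, function(x) g %in% x, logical(1)), , drop = FALSE]
    summarise_rates(sub, g, basis, counting)
  })
  if (length(labels) != 1) {
    rows <- c(rows, list(summarise_rates(per, "all", basis, counting)))
  }
  do.call(rbind, rows)
}

# Per-patient counts and window endpoints used by the rate summaries.
patient_assessment_stats <- function(cohort) {
  trajs <- split_trajectories(cohort)
  rows <- lapply(trajs, function(tr) {
    cli <- clinical_rows(tr)
    exp_t <- tr$time[tr$source == "expected_midpoint"]
    data.frame(
      patient_id = tr$patient_id[1],
      n_obs = nrow(cli),
      n_exp = length(exp_t),
      first_obs = if (nrow(cli)) min(cli$time) else NA_real_,
      last_obs = if (nrow(cli)) max(cli$time) else NA_real_,
      first_exp = if (length(exp_t)) min(exp_t) else NA_real_,
      onset_known = any(tr$source == "onset_anchor"),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, rows)
  meta_known <- cohort$patients$onset_known[
    match(per$patient_id, cohort$patients$patient_id)]
  per$onset_known <- per$onset_known | meta_known
  per
}

summarise_rates <- function(per, group, basis, counting) {
  per <- per[per$n_obs > 0, , drop = FALSE]
  if (!nrow(per)) stop("empty group: ", group, call. = FALSE)
  if (basis == "first_to_last") {
    window <- per$last_obs - per$first_obs
    drop <- window <= 0
    if (any(drop)) {
      message("assessment_rate: excluding ", sum(drop),
              " single-observation patient(s) from first_to_last basis")
    }
    per <- per[!drop, , drop = FALSE]
    window <- window[!drop]
  } else {
    keep <- per$onset_known
    if (any(!keep)) {
      message("assessment_rate: excluding ", sum(!keep),
              " patient(s) without assessed onset from onset_to_last basis")
    }
    per <- per[keep, , drop = FALSE]
    window <- per$last_obs
  }
  if (!nrow(per)) stop("no eligible patients in group: ", group, call. = FALSE)
  records <- per$n_obs + if (counting == "obs_plus_exp") per$n_exp else 0
  first_seen <- if (counting == "obs_plus_exp") {
    ifelse(is.na(per$first_exp), per$first_obs,
           pmin(per$first_exp, per$first_obs))
  } else {
    per$first_obs
  }
  tibble::tibble(
    group = group, basis = basis, counting = counting,
    n_patients = nrow(per),
    total_records = sum(records),
    person_years = sum(window),
    rate = sum(records) / sum(window),
    rate_mean = mean(records / window),
    mean_onset_to_first = mean(first_seen[per$onset_known])
  )
}

# ";"-separated group labels per patient, "all" when absent.
patient_group_lists <- function(cohort) {
  g <- cohort$patients$groups
  lapply(seq_along(g), function(i) {
    if (is.na(g[i]) || !nzchar(g[i])) "all" else strsplit(g[i], ";")[[1]]
  })
}

#' Left / interval / right censoring windows of a trajectory
#'
#' Partitions a patient's timeline into the three censoring windows:
#' left-censoring (assessed onset to first clinical observation),
#' interval-censoring (first to last clinical observation) and
#' right-censoring (last clinical observation to the analysis horizon). The
#' windows are contiguous and tile (onset, horizon) exactly. Without a
#' known onset the left window is undefined (flagged, `start = NA`);
#' without a supplied horizon the right window's end is undefined — not
#' zero.
#'
#' @param traj A single patient's records.
#' @param horizon Optional analysis horizon (years since onset).
#' @return Tibble with columns `patient_id`, `window`, `start`, `end`,
#'   `length`, `defined`.
#' @export
censoring_partition <- function(traj, horizon = NULL) {
  cli <- clinical_rows(traj)
  if (!nrow(cli)) stop("trajectory has no clinical visits", call. = FALSE)
  onset_known <- any(traj$source == "onset_anchor")
  first <- min(cli$time)
  last <- max(cli$time)
  right_end <- if (is.null(horizon)) NA_real_ else horizon
  out <- tibble::tibble(
    patient_id = traj$patient_id[1],
    window = c("left", "interval", "right"),
    start = c(if (onset_known) 0 else NA_real_, first, last),
    end = c(first, last, right_end),
    defined = c(onset_known, TRUE, !is.null(horizon))
  )
  out$length <- ifelse(out$defined, out$end - out$start, NA_real_)
  out
}

#' Assessment rates by calendar era
#'
#' Splits a cohort's records into calendar eras (using each patient's
#' assessed onset year to place records in calendar time) and reports
#' within-era assessment rates. A patient contributes to every era in which
#' they have at least one clinical observation; person-years are the
#' first-to-last clinical-observation window *within* the era, and patients
#' with a single in-era observation are excluded from that era's rate.
#'
#' @param cohort An [edss_cohort()] whose patients carry `onset_year`.
#' @param eras Data frame with columns `era`, `start`, `end` (inclusive
#'   calendar years), or a numeric vector of breakpoints from which
#'   consecutive `[start, end)` eras are formed.
#' @param counting `"obs"` or `"obs_plus_exp"`.
#' @return Tibble with one row per non-empty era (empty eras are omitted
#'   with a warning): `era`, `n_patients`, `total_records`, `person_years`,
#'   `rate`.
#' @export
era_report <- function(cohort, eras, counting = c("obs", "obs_plus_exp")) {
  stopifnot(inherits(cohort, "edss_cohort"))
  counting <- match.arg(counting)
  if (is.numeric(eras)) {
    eras <- data.frame(
      era = paste0(utils::head(eras, -1), "-", utils::tail(eras, -1) - 1),
      start = utils::head(eras, -1),
      end = utils::tail(eras, -1) - 1
    )
  }
  onset_year <- cohort$patients$onset_year
  if (anyNA(onset_year)) {
    stop("era_report needs onset_year for every patient", call. = FALSE)
  }
  visits <- as.data.frame(cohort$visits)
  visits$year <- onset_year[match(visits$patient_id,
                                  cohort$patients$patient_id)] + visits$time

  rows <- lapply(seq_len(nrow(eras)), function(i) {
    inb <- visits$year >= eras$start[i] & visits$year < eras$end[i] + 1
    cli <- visits[inb & visits$source == "clinical", , drop = FALSE]
    if (!nrow(cli)) {
      warning("era ", eras$era[i], " has no clinical observations; omitted",
              call. = FALSE)
      return(NULL)
    }
    f <- factor(cli$patient_id)
    window <- as.numeric(tapply(cli$time, f, max) - tapply(cli$time, f, min))
    n_obs <- as.numeric(table(f))
    n_exp <- if (counting == "obs_plus_exp") {
      ex <- visits[inb & visits$source == "expected_midpoint", , drop = FALSE]
      as.numeric(table(factor(ex$patient_id, levels(f))))
    } else {
      numeric(length(window))
    }
    keep <- window > 0
    if (!any(keep)) {
      warning("era ", eras$era[i],
              " has only single-observation patients; omitted", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      era = eras$era[i],
      n_patients = sum(keep),
      total_records = sum((n_obs + n_exp)[keep]),
      person_years = sum(window[keep]),
      rate = sum((n_obs + n_exp)[keep]) / sum(window[keep])
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no era contains clinical observations", call. = FALSE)
  out
}
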