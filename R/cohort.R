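#' Construct an EDSS visit cohort
#'
#' The central data container: a long-format table of timed EDSS measurements
#' (one row per record) plus per-patient metadata. Time is measured in years
#' since assessed symptom onset (yso). Three record sources are
#' distinguished: `"clinical"` (a clinic-visit EDSS assessment),
#' `"onset_anchor"` (the synthetic EDSS = 0 observation at assessed onset,
#' time 0) and `"expected_midpoint"` (an imputed expected midpoint
#' survival-time measure, produced by [augment_cohort()], never read from
#' input files).
#'
#' @param visits Data frame with columns `patient_id`, `time` (years since
#'   onset, >= 0), `edss` (on the admissible grid, see [edss_grid()]) and
#'   optionally `source` (default `"clinical"`) and bracket columns
#'   `bracket_low`/`bracket_high` for expected-midpoint rows.
#' @param patients Optional data frame with columns `patient_id` and any of
#'   `onset_known` (logical), `onset_year` (calendar year of assessed onset)
#'   and `groups` (character, `";"`-separated study-group labels). Patients
#'   appearing in `visits` but not here are filled in with `onset_known`
#'   deduced from the presence of an onset anchor.
#' @return An object of class `edss_cohort`: a list with tibbles `visits`
#'   (sorted by patient and time) and `patients`.
#' @export
#' @examples
#' coh <- edss_cohort(data.frame(
#'   patient_id = "p1", time = c(0, 2, 4), edss = c(0, 1, 1.5),
#'   source = c("onset_anchor", "clinical", "clinical")
#' ))
#' coh
edss_cohort <- function(visits, patients = NULL) {
  visits <- as.data.frame(visits)
  required <- c("patient_id", "time", "edss")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols)) {
    stop("visits is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"source" %in% names(visits)) {
    visits$source <- rep("clinical", nrow(visits))
  }
  if (!"bracket_low" %in% names(visits)) {
    visits$bracket_low <- rep(NA_real_, nrow(visits))
  }
  if (!"bracket_high" %in% names(visits)) {
    visits$bracket_high <- rep(NA_real_, nrow(visits))
  }
  visits$patient_id <- as.character(visits$patient_id)
  visits$time <- as.numeric(visits$time)
  visits$edss <- as.numeric(visits$edss)

  validate_visits(visits)

  # Sort: patient, time; at tied times anchor < clinical < expected.
  src_rank <- match(visits$source, visit_sources())
  ord <- order(visits$patient_id, visits$time, src_rank)
  visits <- visits[ord, c("patient_id", "time", "edss", "source",
                          "bracket_low", "bracket_high")]
  rownames(visits) <- NULL

  ids <- unique(visits$patient_id)
  has_anchor <- vapply(
    split(visits$source == "onset_anchor", factor(visits$patient_id, ids)),
    any, logical(1)
  )
  meta <- tibble::tibble(
    patient_id = ids,
    onset_known = unname(has_anchor),
    onset_year = NA_real_,
    groups = NA_character_
  )
  if (!is.null(patients)) {
    patients <- as.data.frame(patients)
    patients$patient_id <- as.character(patients$patient_id)
    idx <- match(meta$patient_id, patients$patient_id)
    if ("onset_known" %in% names(patients)) {
      known <- patients$onset_known[idx]
      meta$onset_known <- ifelse(is.na(known), meta$onset_known, known)
    }
    if ("onset_year" %in% names(patients)) {
      meta$onset_year <- as.numeric(patients$onset_year[idx])
    }
    if ("groups" %in% names(patients)) {
      meta$groups <- as.character(patients$groups[idx])
    }
  }

  structure(
    list(visits = tibble::as_tibble(visits), patients = meta),
    class = "edss_cohort"
  )
}

validate_visits <- function(visits) {
  bad <- which(is.na(visits$time) | visits$time < 0)
  if (length(bad)) {
    stop("negative or missing time at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is_edss_value(visits$edss))
  if (length(bad)) {
    stop("EDSS value not on the admissible grid (0, 1, 1.5, ..., 10) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value ", visits$edss[bad[1]], ")", call. = FALSE)
  }
  bad <- which(!visits$source %in% visit_sources())
  if (length(bad)) {
    stop("unknown record source at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  anch <- visits$source == "onset_anchor"
  if (any(anch & (visits$time != 0 | visits$edss != 0))) {
    stop("onset_anchor records must have time = 0 and EDSS = 0", call. = FALSE)
  }
  n_anch <- table(visits$patient_id[anch])
  if (any(n_anch > 1)) {
    stop("more than one onset_anchor record for patient(s): ",
         paste(names(n_anch)[n_anch > 1], collapse = ", "), call. = FALSE)
  }
  # Same-day repeats for one patient are an input error, not merged.
  obs <- visits[visits$source != "expected_midpoint", ]
  key <- paste(obs$patient_id, obs$time)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (patient, time) observation: ", dup, call. = FALSE)
  }
  invisible(visits)
}

#' @export
print.edss_cohort <- function(x, ...) {
  src <- table(factor(x$visits$source, visit_sources()))
  cat("<edss_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$visits), " records (",
      src[["clinical"]], " clinical, ",
      src[["onset_anchor"]], " onset anchors, ",
      src[["expected_midpoint"]], " expected midpoint)\n", sep = "")
  cat("  onset known for ", sum(x$patients$onset_known), " patients\n", sep = "")
  invisible(x)
}

#' Number of patients / records in a cohort
#' @param cohort An `edss_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "edss_cohort"))
  nrow(cohort$patients)
}

#' @rdname n_patients
#' @export
n_records <- function(cohort) {
  stopifnot(inherits(cohort, "edss_cohort"))
  nrow(cohort$visits)
}

#' Extract one patient's trajectory
#'
#' @param cohort An `edss_cohort`.
#' @param patient_id Patient identifier.
#' @return Tibble of that patient's records, time-ordered.
#' @export
trajectory <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "edss_cohort"))
  out <- cohort$visits[cohort$visits$patient_id == patient_id, ]
  if (!nrow(out)) stop("no such patient: ", patient_id, call. = FALSE)
  out
}

# Split the visit table into a named list of per-patient data frames,
# preserving patient order. The workhorse for per-trajectory operations.
split_trajectories <- function(cohort) {
  stopifnot(inherits(cohort, "edss_cohort"))
  ids <- cohort$patients$patient_id
  split(as.data.frame(cohort$visits), factor(cohort$visits$patient_id, ids))
}

# Keep only non-imputed rows (anchor + clinical) of a trajectory.
observed_rows <- function(traj) {
  traj[traj$source != "expected_midpoint", , drop = FALSE]
}

# Keep only clinical rows of a trajectory.
clinical_rows <- function(traj) {
  traj[traj$source == "clinical", , drop = FALSE]
}
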