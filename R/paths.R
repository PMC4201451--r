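#' Irreversible EDSS endpoint levels of a trajectory
#'
#' An EDSS endpoint level `e` (grid value >= 1) is *irreversible* for a
#' patient when some clinical visit records EDSS >= `e` and no later visit
#' records EDSS < `e` — the patient progresses to the endpoint and never
#' reverts below it within follow-up. The attainment time of an irreversible
#' level is the time of the earliest visit from which the trajectory never
#' again falls below the level.
#'
#' Because the suffix minimum of the visit series is non-decreasing, level
#' `e` is irreversible iff the suffix minimum ever reaches `e`, and every
#' grid level from 1.0 up to the highest irreversible level (the last
#' visit's EDSS) is itself irreversible.
#'
#' @param traj A single patient's records (rows of an [edss_cohort()] visit
#'   table); only clinical rows are used.
#' @return Tibble with columns `level` and `t_attained`, one row per
#'   irreversible level in increasing order; zero rows when no level >= 1 is
#'   irreversibly reached.
#' @export
#' @examples
#' traj <- data.frame(patient_id = "p", time = c(2, 4, 6),
#'                    edss = c(1, 1, 2), source = "clinical")
#' irreversible_levels(traj)
irreversible_levels <- function(traj) {
  cli <- clinical_rows(traj)
  if (!nrow(cli)) stop("trajectory has no clinical visits", call. = FALSE)
  s <- rev(cummin(rev(cli$edss)))        # suffix minimum, non-decreasing
  levels <- edss_endpoint_levels()
  levels <- levels[levels <= s[length(s)]]
  if (!length(levels)) {
    return(tibble::tibble(level = numeric(), t_attained = numeric()))
  }
  # first index i with s[i] >= e  ==  (# of s[i] < e) + 1
  first_ge <- findInterval(levels, s, left.open = TRUE) + 1L
  tibble::tibble(level = levels, t_attained = cli$time[first_ge])
}

#' Label the observations of a trajectory
#'
#' Classifies each record (see [observation_labels()]): the onset anchor is
#' `Oo`; a clinical visit later contradicted by a strictly lower reading is
#' transitorily high (`Ot`); the remaining clinical visits form
#' non-decreasing plateau runs at irreversible values, labelled `Of` (first
#' observation at the plateau), `Or` (last repeat before the next increase)
#' and `Om` (interior repeats); imputed records are `Exp`.
#'
#' @param traj A single patient's records.
#' @return The trajectory with an added `label` column.
#' @export
#' @examples
#' traj <- data.frame(patient_id = "p", time = 1:3, edss = c(2, 1, 1),
#'                    source = "clinical")
#' label_observations(traj)$label  # "Ot" "Of" "Or"
label_observations <- function(traj) {
  lab <- character(nrow(traj))
  lab[traj$source == "onset_anchor"] <- "Oo"
  lab[traj$source == "expected_midpoint"] <- "Exp"

  cli_idx <- which(traj$source == "clinical")
  if (length(cli_idx)) {
    edss <- traj$edss[cli_idx]
    s <- rev(cummin(rev(edss)))
    is_ot <- edss > s
    cl <- character(length(edss))
    cl[is_ot] <- "Ot"
    keep <- which(!is_ot)
    if (length(keep)) {
      v <- edss[keep]                    # non-decreasing by construction
      run_id <- cumsum(c(TRUE, v[-1] != v[-length(v)]))
      for (r in split(seq_along(keep), run_id)) {
        k <- length(r)
        cl[keep[r[1]]] <- "Of"
        if (k >= 2) cl[keep[r[k]]] <- "Or"
        if (k >= 3) cl[keep[r[2:(k - 1)]]] <- "Om"
      }
    }
    lab[cli_idx] <- cl
  }
  traj$label <- lab
  traj
}

# Labels for every record of a cohort, in visit-table row order.
cohort_labels <- function(cohort) {
  visits <- as.data.frame(cohort$visits)
  if (!nrow(visits)) return(character())
  ids <- cohort$patients$patient_id
  f <- factor(visits$patient_id, ids)
  out <- character(nrow(visits))
  for (idx in split(seq_len(nrow(visits)), f)) {
    out[idx] <- label_observations(visits[idx, , drop = FALSE])$label
  }
  out
}

#' Event or censoring time at one endpoint level
#'
#' Computes the survival time at an irreversible EDSS endpoint under one
#' survival-time assumption. If the level is irreversible within follow-up
#' the result is an event: under `"maximum"` the event is placed on the day
#' of the attaining visit (disability is modelled to remain as previously
#' measured until that visit); under `"minimum"` it is placed immediately
#' after the last prior record (onset anchor or clinic visit) at which the
#' patient was still strictly below the level, represented numerically as
#' that record's time; under `"midpoint"` at the expected midpoint measure
#' (see [expected_midpoints()]; a level whose censoring bracket is undefined
#' enters at its maximum time). If the level is not irreversibly reached,
#' the patient is right-censored at the last clinical observation — the
#' right-censoring convention is never moved by the midpoint adjustment.
#'
#' @param traj A single patient's records.
#' @param level Endpoint level, grid value >= 1.
#' @param assumption One of `"maximum"`, `"minimum"`, `"midpoint"`.
#' @return One-row tibble: `patient_id`, `level`, `assumption`, `time`,
#'   `status` (`"event"` or `"right_censored"`).
#' @export
event_time <- function(traj, level, assumption = "maximum") {
  assumption <- match_assumption(assumption)
  if (length(level) != 1 || !is_edss_value(level) || level < 1) {
    stop("endpoint level must be a single grid value >= 1.0 (got ",
         level, ")", call. = FALSE)
  }
  endpoint_events_one(traj, level, assumption)
}

# Internal: events for several levels of one trajectory, one assumption.
endpoint_events_one <- function(traj, levels, assumption) {
  cli <- clinical_rows(traj)
  if (!nrow(cli)) stop("trajectory has no clinical visits", call. = FALSE)
  irr <- irreversible_levels(traj)
  last_time <- max(cli$time)
  obs <- observed_rows(traj)

  mid <- NULL
  if (assumption == "midpoint") mid <- expected_midpoints(traj, warn = FALSE)

  time <- numeric(length(levels))
  status <- character(length(levels))
  for (i in seq_along(levels)) {
    e <- levels[i]
    j <- match(e, irr$level)
    if (is.na(j)) {
      time[i] <- last_time
      status[i] <- "right_censored"
      next
    }
    t_att <- irr$t_attained[j]
    status[i] <- "event"
    time[i] <- switch(assumption,
      maximum = t_att,
      minimum = {
        below <- obs$time[obs$time < t_att & obs$edss < e]
        if (length(below)) max(below) else t_att
      },
      midpoint = {
        k <- match(e, mid$level)
        if (is.na(k)) t_att else mid$time[k]
      }
    )
  }
  tibble::tibble(patient_id = traj$patient_id[1], level = levels,
                 assumption = assumption, time = time, status = status)
}

#' Endpoint events for a whole cohort
#'
#' Applies [event_time()] to every patient for a set of endpoint levels.
#'
#' @param cohort An [edss_cohort()] (or a single patient's records).
#' @param levels Endpoint levels; default the integer levels 1–9.
#' @param assumption Survival-time assumption.
#' @return Tibble of events, one row per (patient, level).
#' @export
endpoint_events <- function(cohort, levels = 1:9, assumption = "maximum") {
  assumption <- match_assumption(assumption)
  levels <- as.numeric(levels)
  if (!all(is_edss_value(levels)) || any(levels < 1)) {
    stop("endpoint levels must be grid values >= 1.0", call. = FALSE)
  }
  trajs <- if (inherits(cohort, "edss_cohort")) {
    split_trajectories(cohort)
  } else {
    list(as.data.frame(cohort))
  }
  out <- lapply(trajs, endpoint_events_one, levels = levels,
                assumption = assumption)
  do.call(rbind, out)
}

#' Irreversible disability progression path
#'
#' The step path (time, level) through a patient's irreversible endpoints
#' under one survival-time assumption, starting at (0, 0) when onset is
#' known. Levels are strictly increasing and times non-decreasing by
#' construction.
#'
#' @inheritParams event_time
#' @param assumption Survival-time assumption.
#' @return Tibble with columns `time` and `level`.
#' @export
build_path <- function(traj, assumption = "maximum") {
  assumption <- match_assumption(assumption)
  irr <- irreversible_levels(traj)
  has_anchor <- any(traj$source == "onset_anchor")
  origin <- if (has_anchor) tibble::tibble(time = 0, level = 0) else NULL
  if (!nrow(irr)) {
    return(if (is.null(origin)) tibble::tibble(time = numeric(),
                                               level = numeric()) else origin)
  }
  ev <- endpoint_events_one(traj, irr$level, assumption)
  steps <- tibble::tibble(time = ev$time, level = ev$level)
  rbind(origin, steps)
}
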