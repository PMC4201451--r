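#' Expected midpoint survival-time measures
#'
#' For every irreversible endpoint level of a trajectory, places the
#' progression event at the expected midpoint of its censoring interval.
#' Irreversible levels are walked in increasing order and grouped into
#' maximal runs of `k` consecutive grid levels first attained at the same
#' visit time `t_b`. The bracket start `t_a` is the latest prior record
#' (onset anchor or clinic visit) at which the patient was still strictly
#' below the lowest level of the run — transitorily high readings can never
#' shrink a bracket, because any such reading below the run is followed by a
#' still lower one. The run's interval `(t_a, t_b]` is partitioned into `k`
#' equal subintervals and level `j` (j = 1..k) placed at the midpoint of
#' subinterval `j`:
#' \deqn{t_j = t_a + (2j - 1)(t_b - t_a) / (2k)}
#' For `k = 1` this is the adjacent-endpoint midpoint `(t_a + t_b)/2`; for
#' `k > 1` it realises equal-interval placement of endpoints skipped between
#' non-adjacent observed levels. Every imputed time is strictly inside its
#' bracket.
#'
#' When onset is unknown and no record below the first run's lowest level
#' exists, that bracket is undefined: no expected measures are generated for
#' the run (a warning is raised) and the affected levels enter downstream
#' models at their maximum survival time.
#'
#' @param traj A single patient's records.
#' @param warn Warn when a leading bracket is undefined (default `TRUE`).
#' @return Tibble with columns `patient_id`, `level`, `time`,
#'   `bracket_low`, `bracket_high`; zero rows when no level is irreversible.
#' @export
#' @examples
#' traj <- data.frame(
#'   patient_id = "p", time = c(0, 2), edss = c(0, 1),
#'   source = c("onset_anchor", "clinical")
#' )
#' expected_midpoints(traj)  # level 1.0 at time 1.0
expected_midpoints <- function(traj, warn = TRUE) {
  empty <- tibble::tibble(patient_id = character(), level = numeric(),
                          time = numeric(), bracket_low = numeric(),
                          bracket_high = numeric())
  irr <- irreversible_levels(traj)
  if (!nrow(irr)) return(empty)
  obs <- observed_rows(traj)

  out <- vector("list", length(unique(irr$t_attained)))
  i <- 0L
  for (run in split(seq_len(nrow(irr)), match(irr$t_attained,
                                              unique(irr$t_attained)))) {
    levels <- irr$level[run]
    t_b <- irr$t_attained[run[1]]
    e_low <- levels[1]
    below <- obs$time[obs$time < t_b & obs$edss < e_low]
    if (!length(below)) {
      if (warn) {
        warning("no record below level ", e_low, " before its attainment for ",
                "patient ", traj$patient_id[1],
                ": leading bracket undefined, expected measures skipped",
                call. = FALSE)
      }
      next
    }
    t_a <- max(below)
    k <- length(levels)
    j <- seq_len(k)
    i <- i + 1L
    out[[i]] <- tibble::tibble(
      patient_id = traj$patient_id[1],
      level = levels,
      time = t_a + (2 * j - 1) * (t_b - t_a) / (2 * k),
      bracket_low = t_a,
      bracket_high = t_b
    )
  }
  if (i == 0L) return(empty)
  do.call(rbind, out[seq_len(i)])
}

#' Augment a cohort with expected midpoint measures
#'
#' Adds one `expected_midpoint` record per irreversible endpoint level of
#' every patient (see [expected_midpoints()]). Clinical records and onset
#' anchors are never modified or removed; any previously imputed records are
#' regenerated, making the operation idempotent.
#'
#' @param cohort An [edss_cohort()].
#' @return The augmented [edss_cohort()].
#' @export
augment_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "edss_cohort"))
  trajs <- split_trajectories(cohort)
  exp_list <- lapply(trajs, function(tr) {
    expected_midpoints(observed_rows(tr), warn = TRUE)
  })
  exps <- do.call(rbind, exp_list)
  base <- as.data.frame(cohort$visits)
  base <- base[base$source != "expected_midpoint", , drop = FALSE]
  if (!is.null(exps) && nrow(exps)) {
    rows <- data.frame(patient_id = exps$patient_id, time = exps$time,
                       edss = exps$level, source = "expected_midpoint",
                       bracket_low = exps$bracket_low,
                       bracket_high = exps$bracket_high,
                       stringsAsFactors = FALSE)
    base <- rbind(base, rows)
  }
  out <- edss_cohort(base, cohort$patients)
  message("augment_cohort: ", sum(out$visits$source == "expected_midpoint"),
          " expected midpoint records for ", n_patients(out), " patients")
  out
}
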