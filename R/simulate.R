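#' Simulation parameters for a synthetic natural-history cohort
#'
#' Defines the generative model used throughout testing and calibration: a
#' latent irreversible disability process `D(t) = min(beta_true * t, 10)`
#' (EDSS per year since onset), observed at irregular clinic visits and
#' floored to the last attained value on the admissible EDSS grid. Visits
#' start after a years-long onset-to-first-visit gap and then follow a
#' gamma renewal process over a fixed follow-up window; transitory relapse
#' elevations are added to readings that fall inside a relapse window and
#' revert afterwards, producing the transitorily high (`Ot`) observations
#' seen in clinic records. The trajectory is right-censored at the last
#' visit and carries an onset anchor (EDSS 0 at time 0).
#'
#' Defaults describe a relapsing-onset MS natural-history cohort: a latent
#' progression rate of 0.17 EDSS/year, a mean onset-to-first-visit delay of
#' 2 years, visits every 2 years on average (gamma shape 2) over 20 years of
#' follow-up, and relapses at 0.4/year raising the reading by 1–2 EDSS
#' points for about 8 weeks.
#'
#' @param n_patients Number of patients (>= 1).
#' @param beta_true Latent progression rate, EDSS per year (>= 0). With
#'   `beta_sd > 0` each patient draws a gamma-distributed rate with this
#'   mean.
#' @param beta_sd Between-patient SD of the latent rate (default 0: common
#'   rate).
#' @param visit_gap_mean,visit_gap_shape Mean (years) and gamma shape of
#'   inter-visit gaps.
#' @param onset_delay_mean,onset_delay_shape Mean (years) and gamma shape of
#'   the onset-to-first-visit delay; 0 mean puts the first visit at onset.
#' @param followup_mean Follow-up window length (years) from the first
#'   visit; visits are generated until `onset_delay + followup_mean`.
#' @param relapse_rate Relapse events per year (Poisson).
#' @param relapse_height Possible transient EDSS elevations (half-point
#'   multiples), sampled uniformly per relapse.
#' @param relapse_duration_mean Mean relapse duration, years (exponential).
#' @param onset_year_range Integer range of calendar onset years, sampled
#'   uniformly, giving the cohort calendar structure for era reporting.
#' @param group Study-group label attached to every patient.
#' @param id_prefix Prefix for generated patient identifiers.
#' @param seed Integer seed for [simulate_cohort()]; `NULL` uses the current
#'   RNG stream.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 250,
                       beta_true = 0.17,
                       beta_sd = 0,
                       visit_gap_mean = 2,
                       visit_gap_shape = 2,
                       onset_delay_mean = 2,
                       onset_delay_shape = 2,
                       followup_mean = 20,
                       relapse_rate = 0.4,
                       relapse_height = c(1, 1.5, 2),
                       relapse_duration_mean = 0.15,
                       onset_year_range = c(1979, 2005),
                       group = "simulated",
                       id_prefix = "p",
                       seed = NULL) {
  p <- list(n_patients = as.integer(n_patients), beta_true = beta_true,
            beta_sd = beta_sd, visit_gap_mean = visit_gap_mean,
            visit_gap_shape = visit_gap_shape,
            onset_delay_mean = onset_delay_mean,
            onset_delay_shape = onset_delay_shape,
            followup_mean = followup_mean, relapse_rate = relapse_rate,
            relapse_height = relapse_height,
            relapse_duration_mean = relapse_duration_mean,
            onset_year_range = onset_year_range, group = group,
            id_prefix = id_prefix, seed = seed)
  if (p$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  nonneg <- c("beta_true", "beta_sd", "onset_delay_mean", "relapse_rate",
              "relapse_duration_mean")
  for (f in nonneg) {
    if (p[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  for (f in c("visit_gap_mean", "visit_gap_shape", "onset_delay_shape",
              "followup_mean")) {
    if (p[[f]] <= 0) stop(f, " must be > 0", call. = FALSE)
  }
  if (any(p$relapse_height <= 0) || any(p$relapse_height %% 0.5 != 0)) {
    stop("relapse_height values must be positive half-point multiples",
         call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

#' Simulate one patient trajectory
#'
#' Draws a single trajectory from the generative model described in
#' [sim_params()], using the current RNG stream (seed handling belongs to
#' [simulate_cohort()]).
#'
#' @param params A [sim_params()] object.
#' @param patient_id Identifier for the generated patient.
#' @return Data frame of records (onset anchor first, then clinical visits
#'   in time order) in the [edss_cohort()] visit dialect.
#' @export
simulate_trajectory <- function(params, patient_id = "p1") {
  stopifnot(inherits(params, "sim_params"))
  beta <- if (params$beta_sd > 0) {
    shape <- (params$beta_true / params$beta_sd)^2
    stats::rgamma(1, shape = shape, scale = params$beta_true / shape)
  } else {
    params$beta_true
  }
  delay <- if (params$onset_delay_mean > 0) {
    stats::rgamma(1, shape = params$onset_delay_shape,
                  scale = params$onset_delay_mean / params$onset_delay_shape)
  } else 0
  horizon <- delay + params$followup_mean

  # Gamma renewal visit times starting at the first visit (= onset delay).
  n_guess <- max(8, ceiling(2 * params$followup_mean / params$visit_gap_mean) + 8)
  gaps <- stats::rgamma(n_guess, shape = params$visit_gap_shape,
                        scale = params$visit_gap_mean / params$visit_gap_shape)
  times <- delay + c(0, cumsum(gaps))
  while (times[length(times)] <= horizon) {
    more <- stats::rgamma(n_guess, shape = params$visit_gap_shape,
                          scale = params$visit_gap_mean / params$visit_gap_shape)
    times <- c(times, times[length(times)] + cumsum(more))
  }
  times <- times[times <= horizon]

  base <- edss_grid_floor(pmin(beta * times, 10))
  edss <- base
  if (params$relapse_rate > 0) {
    n_rel <- stats::rpois(1, params$relapse_rate * horizon)
    if (n_rel > 0) {
      starts <- stats::runif(n_rel, 0, horizon)
      ends <- starts + stats::rexp(n_rel, rate = 1 / params$relapse_duration_mean)
      heights <- params$relapse_height[
        sample.int(length(params$relapse_height), n_rel, replace = TRUE)]
      for (i in seq_along(times)) {
        active <- starts <= times[i] & times[i] < ends
        if (any(active)) {
          edss[i] <- edss_grid_snap(base[i] + max(heights[active]))
        }
      }
    }
  }

  data.frame(
    patient_id = patient_id,
    time = c(0, times),
    edss = c(0, edss),
    source = c("onset_anchor", rep("clinical", length(times))),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic natural-history cohort
#'
#' Draws `n_patients` independent trajectories from one seeded RNG stream
#' and assembles them into an [edss_cohort()] with onset metadata (every
#' simulated patient has a known onset and a uniformly sampled calendar
#' onset year).
#'
#' @param params A [sim_params()] object; `params$seed`, when non-`NULL`,
#'   seeds the stream so identical parameters reproduce the cohort exactly.
#' @return An [edss_cohort()].
#' @export
#' @examples
#' coh <- simulate_cohort(sim_params(n_patients = 5, seed = 1))
#' coh
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_patients
  ids <- sprintf("%s%0*d", params$id_prefix, max(4, nchar(n)), seq_len(n))
  onset_years <- sample(seq(params$onset_year_range[1],
                            params$onset_year_range[2]), n, replace = TRUE)
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_trajectory(params, patient_id = ids[i])
  }))
  patients <- data.frame(patient_id = ids, onset_known = TRUE,
                         onset_year = onset_years, groups = params$group,
                         stringsAsFactors = FALSE)
  edss_cohort(visits, patients)
}

#' Simulate a multi-era (mixture) cohort
#'
#' Concatenates cohorts drawn from several parameter sets into one cohort —
#' e.g. a low-assessment-rate early era and a high-rate late era — from a
#' single seeded stream. Patient identifiers are prefixed per block and each
#' block carries its own group label.
#'
#' @param params_list List of [sim_params()] objects; each should carry a
#'   distinct `group` and `id_prefix`.
#' @param seed Integer seed for the shared stream (overrides per-block
#'   seeds).
#' @return An [edss_cohort()] containing all blocks.
#' @export
simulate_era_cohort <- function(params_list, seed = NULL) {
  stopifnot(length(params_list) >= 1)
  if (!is.null(seed)) set.seed(seed)
  cohorts <- lapply(params_list, function(p) {
    p$seed <- NULL
    simulate_cohort(p)
  })
  visits <- do.call(rbind, lapply(cohorts, function(x) as.data.frame(x$visits)))
  patients <- do.call(rbind, lapply(cohorts, function(x) as.data.frame(x$patients)))
  if (anyDuplicated(patients$patient_id)) {
    stop("patient id collision across blocks; set distinct id_prefix values",
         call. = FALSE)
  }
  edss_cohort(visits, patients)
}
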