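# Independent oracles and fixture builders used across the suite.

# Build a single-patient trajectory data frame.
make_traj <- function(time, edss, anchor = FALSE, id = "p1") {
  df <- data.frame(patient_id = rep(id, length(time)), time = time,
                   edss = edss, source = rep("clinical", length(time)),
                   stringsAsFactors = FALSE)
  if (anchor) {
    df <- rbind(data.frame(patient_id = id, time = 0, edss = 0,
                           source = "onset_anchor", stringsAsFactors = FALSE),
                df)
  }
  df
}

# Quadratic brute-force scan of the irreversibility definition: level e is
# irreversible iff some visit has EDSS >= e and no later visit has EDSS < e;
# attainment time is the earliest such visit. Deliberately naive.
brute_force_irreversible <- function(traj) {
  cli <- traj[traj$source == "clinical", , drop = FALSE]
  cli <- cli[order(cli$time), , drop = FALSE]
  n <- nrow(cli)
  levels <- numeric(0)
  times <- numeric(0)
  for (e in edss_endpoint_levels()) {
    t_att <- NA_real_
    for (i in seq_len(n)) {
      if (cli$edss[i] >= e) {
        later <- if (i < n) cli$edss[(i + 1):n] else numeric()
        if (all(later >= e)) {
          t_att <- cli$time[i]
          break
        }
      }
    }
    if (!is.na(t_att)) {
      levels <- c(levels, e)
      times <- c(times, t_att)
    }
  }
  data.frame(level = levels, t_attained = times)
}

# Hand product-limit estimator: events precede censorings at tied times.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Random trajectory for fuzzing: 1-40 visits at strictly increasing times,
# EDSS drawn uniformly from the admissible grid.
random_traj <- function(id = "f1", max_len = 40) {
  n <- sample.int(max_len, 1)
  gaps <- stats::rexp(n, rate = 1) + 1e-3
  make_traj(cumsum(gaps), sample(edss_grid(), n, replace = TRUE), id = id)
}

# Small noiseless cohort parameters shared by recovery-style tests.
noiseless_params <- function(n_patients, seed = NULL, ...) {
  sim_params(n_patients = n_patients, relapse_rate = 0, seed = seed, ...)
}
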