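events_tbl <- function(time, status, level = 3, assumption = "maximum") {
  tibble::tibble(patient_id = paste0("p", seq_along(time)), level = level,
                 assumption = assumption, time = time, status = status)
}

test_that("the product-limit estimator matches closed forms", {
  # no censoring: KM equals the empirical survival function
  cv <- km_fit(events_tbl(1:4, rep("event", 4)))
  expect_equal(cv$table$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(cv$table$time, 1:4)

  # hand-computed product limit with an interior censoring
  cv <- km_fit(events_tbl(c(1, 2, 3), c("event", "right_censored", "event")))
  expect_equal(cv$table$survival[cv$table$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(cv$table$survival[cv$table$time == 3], 0, tolerance = 1e-12)

  # all censored: flat at 1
  cv <- km_fit(events_tbl(c(2, 5), rep("right_censored", 2)))
  expect_true(all(cv$table$survival == 1))
  expect_true(is.na(median_survival(cv)))

  expect_error(km_fit(events_tbl(numeric(), character())), "no events")
})

test_that("KM agrees with an independent hand-rolled oracle on random data", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    time <- round(rexp(n, 0.2), 1) + 0.1
    status <- ifelse(runif(n) < 0.7, "event", "right_censored")
    cv <- km_fit(events_tbl(time, status))
    orc <- km_oracle(time, status == "event")
    got <- km_survival_at(cv, orc$time)
    expect_equal(got, orc$survival, tolerance = 1e-12)
  }
})

test_that("tied event and censor times follow the events-first convention", {
  cv <- km_fit(events_tbl(c(2, 2, 4), c("event", "right_censored", "event")))
  # at t = 2 the risk set holds all 3; the censored patient leaves after
  expect_equal(cv$table$n_risk[cv$table$time == 2], 3)
  expect_equal(cv$table$survival[cv$table$time == 2], 2 / 3, tolerance = 1e-12)
  expect_equal(cv$table$survival[cv$table$time == 4], 0, tolerance = 1e-12)
})

test_that("median survival is the first time the curve reaches one half", {
  cv <- km_fit(events_tbl(1:4, rep("event", 4)))
  expect_equal(median_survival(cv), 2)
  cv <- km_fit(events_tbl(rep(5, 4), rep("event", 4)))
  expect_equal(median_survival(cv), 5)
})

test_that("onset-cohort selection filters on onset and observation count", {
  visits <- rbind(make_traj(2, 1, anchor = TRUE, id = "a"),
                  make_traj(c(1, 3), c(1, 2), anchor = TRUE, id = "b"),
                  make_traj(c(1, 3), c(1, 2), id = "c"))
  coh <- edss_cohort(visits)
  kept <- suppressMessages(select_onset_cohort(coh, min_clinical_obs = 2))
  expect_equal(kept$patients$patient_id, "b")   # a: 1 obs; c: no onset
  all3 <- suppressMessages(
    select_onset_cohort(coh, min_clinical_obs = 1, require_onset = FALSE))
  expect_equal(n_patients(all3), 3)
})

test_that("a suite covers the default endpoint set with conserved counts", {
  coh <- suppressMessages(simulate_cohort(sim_params(n_patients = 40, seed = 70)))
  suite <- km_suite(coh, assumption = "maximum")
  expect_length(suite, 9)
  for (cv in suite) {
    expect_equal(cv$n_events + cv$n_censored, 40)
    expect_true(all(diff(cv$table$survival) <= 1e-12))
    expect_true(all(cv$table$survival >= 0 & cv$table$survival <= 1))
  }
  # nobody reaches EDSS 9 in 20 years at 0.17/yr without a terminal relapse:
  # the level-9 curve stays flat wherever no events occurred
  lvl9 <- suite[["9"]]
  if (lvl9$n_events == 0) expect_true(all(lvl9$table$survival == 1))

  tidy <- km_tidy(suite)
  expect_true(all(c("level", "assumption", "time", "survival") %in% names(tidy)))
  expect_equal(sort(unique(tidy$level)), 1:9)
})

test_that("midpoint curves dominate maximum curves from the left", {
  set.seed(90)
  for (i in 1:5) {
    coh <- suppressMessages(simulate_cohort(
      sim_params(n_patients = 80, relapse_rate = if (i %% 2) 0 else 0.5)))
    s_max <- km_suite(coh, assumption = "maximum")
    s_mid <- km_suite(coh, assumption = "midpoint")
    for (k in seq_along(s_max)) {
      # dominance holds wherever the curve equals empirical survival of
      # the ordered event times: before the first censoring time, and
      # everywhere on censor-free levels (see test-acceptance.R)
      grid_t <- sort(unique(c(s_max[[k]]$table$time, s_mid[[k]]$table$time)))
      if (s_max[[k]]$n_censored > 0) {
        c_min <- min(s_max[[k]]$table$time[s_max[[k]]$table$n_censor > 0])
        grid_t <- grid_t[grid_t < c_min]
      }
      expect_true(all(km_survival_at(s_mid[[k]], grid_t) <=
                        km_survival_at(s_max[[k]], grid_t) + 1e-12))
      # censoring counts are identical under both assumptions
      expect_equal(s_mid[[k]]$n_censored, s_max[[k]]$n_censored)
    }
  }
})

test_that("midpoint medians track the latent crossing times more closely", {
  set.seed(201)
  level <- 3
  err_mid <- err_max <- c()
  for (i in 1:200) {
    coh <- suppressMessages(simulate_cohort(
      sim_params(n_patients = 40, relapse_rate = 0)))
    truth <- level / 0.17
    ev_max <- endpoint_events(coh, level, "maximum")
    ev_mid <- endpoint_events(coh, level, "midpoint")
    m_max <- median_survival(km_fit(ev_max))
    m_mid <- median_survival(km_fit(ev_mid))
    if (is.na(m_max) || is.na(m_mid)) next
    err_max <- c(err_max, abs(m_max - truth))
    err_mid <- c(err_mid, abs(m_mid - truth))
  }
  expect_gt(length(err_mid), 150)
  expect_lt(mean(err_mid), mean(err_max))
})
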