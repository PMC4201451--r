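test_that("exact linear data are recovered to numerical precision", {
  # 4 patients, 5 visits each, exactly on EDSS = 0.2 * yso
  times <- c(5, 10, 15, 20, 25)
  visits <- do.call(rbind, lapply(1:4, function(i) {
    make_traj(times, 0.2 * times, anchor = TRUE, id = paste0("p", i))
  }))
  coh <- edss_cohort(visits)
  est <- fit_rate(coh, "maximum", boot = 0)
  expect_lt(abs(est$beta_yso - 0.2), 1e-10)
  est_fe <- fit_rate(coh, "maximum", variant = "fe", boot = 0)
  expect_lt(abs(est_fe$beta_yso - 0.2), 1e-10)

  # all-zero records give a zero slope
  flat <- edss_cohort(make_traj(c(1, 2, 3), c(0, 0, 0), anchor = TRUE))
  expect_equal(fit_rate(flat, boot = 0)$beta_yso, 0)
})

test_that("closed-form slopes agree with lm as an independent check", {
  set.seed(4)
  coh <- suppressMessages(simulate_cohort(sim_params(n_patients = 25, seed = 4)))
  rec <- rate_records(coh, "maximum")
  est <- fit_rate(coh, "maximum", boot = 0)
  ref <- unname(coef(lm(edss ~ 0 + time, data = rec)))
  expect_equal(est$beta_yso, ref, tolerance = 1e-10)

  est_fe <- fit_rate(coh, "maximum", variant = "fe", boot = 0)
  ref_fe <- unname(coef(lm(edss ~ 0 + factor(patient_id) + time,
                           data = rec))[["time"]])
  expect_equal(est_fe$beta_yso, ref_fe, tolerance = 1e-8)
})

test_that("the range filter and transitory flag act on the populated records", {
  tr <- make_traj(c(1, 2, 10, 20), c(3, 1, 2, 7), anchor = TRUE)
  coh <- edss_cohort(tr)
  rec <- rate_records(coh, "maximum", range_max = 6)
  expect_false(any(rec$edss > 6))           # the EDSS-7 record is filtered
  expect_true(3 %in% rec$edss)              # Ot records kept by default
  rec2 <- rate_records(coh, "maximum", range_max = 6,
                       include_transitory = FALSE)
  expect_false(3 %in% rec2$edss)
  expect_error(fit_rate(coh, range_max = 6, boot = 0, group = "g",
                        include_transitory = TRUE), NA)
  # nothing left in range -> error
  hi <- edss_cohort(make_traj(c(1, 2), c(7, 7)))
  expect_error(fit_rate(hi, boot = 0), "no records")
})

test_that("the measures population carries the path vertices", {
  tr <- make_traj(c(2, 4, 6), c(1, 1, 2), anchor = TRUE)
  coh <- edss_cohort(tr)
  rec_max <- rate_records(coh, "maximum", population = "measures")
  expect_equal(rec_max$edss, c(1, 1.5, 2))
  expect_equal(rec_max$time, c(2, 6, 6))
  rec_mid <- rate_records(coh, "midpoint", population = "measures")
  expect_equal(rec_mid$time, c(1, 4.5, 5.5))
  rec_min <- rate_records(coh, "minimum", population = "measures")
  expect_equal(rec_min$time, c(0, 4, 4))
  expect_true(all(rec_max$source == "survival_measure"))

  # the range filter applies to the level, and a flat cohort has no measures
  expect_equal(nrow(rate_records(coh, "maximum", range_max = 1.5,
                                 population = "measures")), 2)
  flat <- edss_cohort(make_traj(c(1, 2), c(0, 0), anchor = TRUE))
  expect_equal(nrow(rate_records(flat, "maximum", population = "measures")), 0)
})

test_that("only the measures population is assessment-rate sensitive", {
  # sparse visits delay the maximum survival-time measures (slope biased
  # down with the gap) but leave observation-stream sampling unbiased
  betas <- sapply(c(4, 1), function(gap) {
    p <- sim_params(n_patients = 150, visit_gap_mean = gap, relapse_rate = 0,
                    seed = 400 + gap)
    coh <- suppressMessages(simulate_cohort(p))
    c(stream = fit_rate(coh, "maximum", boot = 0)$beta_yso,
      measures = fit_rate(coh, "maximum", boot = 0,
                          population = "measures")$beta_yso)
  })
  gap_effect <- abs(betas[, 1] - betas[, 2])
  expect_gt(gap_effect[["measures"]], 4 * gap_effect[["stream"]])
})

test_that("per-patient-intercept variant requires repeated measures", {
  coh <- edss_cohort(rbind(make_traj(c(1, 2), c(1, 1), id = "a"),
                           make_traj(3, 2, id = "b")))
  expect_error(fit_rate(coh, variant = "fe", boot = 0), "b")
})

test_that("bootstrap is deterministic in the seed, point estimate free of B", {
  coh <- suppressMessages(simulate_cohort(sim_params(n_patients = 30, seed = 9)))
  e1 <- fit_rate(coh, "maximum", boot = 199, seed = 123)
  e2 <- fit_rate(coh, "maximum", boot = 199, seed = 123)
  expect_identical(e1$ci95, e2$ci95)
  e3 <- fit_rate(coh, "maximum", boot = 19, seed = 123)
  expect_identical(e1$beta_yso, e3$beta_yso)
  expect_true(e1$ci95[1] <= e1$beta_yso && e1$beta_yso <= e1$ci95[2])

  c1 <- compare_assumptions(coh, B = 99, seed = 5)
  c2 <- compare_assumptions(coh, B = 99, seed = 5)
  expect_identical(c1$diff_ci95, c2$diff_ci95)
  expect_equal(c1$pct_faster,
               100 * (c1$beta_mid - c1$beta_max) / c1$beta_max)
})

test_that("midpoint adjustment recovers the latent rate better than maximum", {
  p <- sim_params(n_patients = 200, beta_true = 0.17, visit_gap_mean = 2,
                  followup_mean = 20, relapse_rate = 0, seed = 61)
  coh <- suppressMessages(simulate_cohort(p))
  b_max <- fit_rate(coh, "maximum", boot = 0)$beta_yso
  b_mid <- fit_rate(coh, "midpoint", boot = 0)$beta_yso
  expect_lt(b_max, b_mid)
  expect_lt(abs(b_mid - 0.17), abs(b_max - 0.17))
  cmp <- compare_assumptions(coh, B = 399, seed = 62)
  expect_gt(cmp$pct_faster, 0)
})

test_that("noiseless cohorts order the three assumptions", {
  # minimum >= midpoint >= maximum survival-time estimates
  set.seed(300)
  for (i in seq_len(100)) {
    coh <- suppressMessages(simulate_cohort(
      sim_params(n_patients = 50, relapse_rate = 0, beta_true = 0.2)))
    b <- vapply(c("minimum", "midpoint", "maximum"), function(a) {
      fit_rate(coh, a, boot = 0)$beta_yso
    }, numeric(1))
    expect_gte(b[["minimum"]], b[["midpoint"]] - 1e-12)
    expect_gte(b[["midpoint"]], b[["maximum"]] - 1e-12)
  }
})

test_that("dense observation leaves nothing to adjust", {
  # as the visit schedule densifies, censoring brackets shrink and the
  # midpoint estimate collapses onto the maximum one: pct_faster decreases
  # monotonically and is below 1% at a 0.1-year gap
  beta <- 0.25
  pct <- vapply(c(2, 1, 0.5, 0.2, 0.1), function(dt) {
    times <- seq(dt, 24, by = dt)
    visits <- do.call(rbind, lapply(1:5, function(i) {
      make_traj(times, edssmidpath:::edss_grid_floor(beta * times),
                anchor = TRUE, id = paste0("p", i))
    }))
    compare_assumptions(edss_cohort(visits), B = 99, seed = 1)$pct_faster
  }, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_lt(abs(pct[length(pct)]), 1)
})

test_that("variability report computes dispersion per assumption", {
  est <- data.frame(assumption = rep(c("maximum", "midpoint"), each = 2),
                    group = rep(c("g1", "g2"), 2),
                    beta_yso = c(0.10, 0.20, 0.15, 0.15))
  rep <- variability_report(est)
  expect_equal(rep$cv[rep$assumption == "midpoint"], 0)
  row <- rep[rep$assumption == "maximum", ]
  expect_equal(row$mean_beta, 0.15)
  expect_equal(row$cv, sd(c(0.1, 0.2)) / 0.15)
  expect_equal(row$range, 0.1)
  expect_error(variability_report(est[1, , drop = FALSE]), ">= 2 groups")
})
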