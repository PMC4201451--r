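test_that("assessment-rate arithmetic matches the worked example", {
  # 5 clinical observations from t = 2 to t = 12: 0.5 obs/patient-year
  tr <- make_traj(c(2, 4, 7, 9, 12), c(1, 1, 2, 2, 3), anchor = TRUE)
  coh <- edss_cohort(tr)
  r <- assessment_rate(coh, "first_to_last", "obs")
  expect_equal(r$rate, 0.5)
  expect_equal(r$total_records, 5)
  expect_equal(r$person_years, 10)

  # with 3 expected midpoint records the obs+Exp rate becomes 0.8
  aug <- coh
  aug$visits <- rbind(aug$visits,
                      tibble::tibble(patient_id = "p1", time = c(3, 5, 8),
                                     edss = c(1.5, 2, 2.5),
                                     source = "expected_midpoint",
                                     bracket_low = NA, bracket_high = NA))
  r2 <- assessment_rate(aug, "first_to_last", "obs_plus_exp")
  expect_equal(r2$rate, 0.8)
  # the anchor is never counted as an observation
  expect_equal(r2$total_records, 8)
})

test_that("obs+Exp rates always dominate obs rates, equal only without Exp", {
  coh <- suppressMessages(simulate_cohort(sim_params(n_patients = 30, seed = 15)))
  aug <- suppressMessages(augment_cohort(coh))
  for (basis in c("first_to_last", "onset_to_last")) {
    r_obs <- suppressMessages(assessment_rate(aug, basis, "obs"))
    r_both <- suppressMessages(assessment_rate(aug, basis, "obs_plus_exp"))
    expect_gte(r_both$rate, r_obs$rate)
  }
  plain <- suppressMessages(assessment_rate(coh, "onset_to_last", "obs"))
  noexp <- suppressMessages(assessment_rate(coh, "onset_to_last", "obs_plus_exp"))
  expect_equal(plain$rate, noexp$rate)
})

test_that("single-observation patients drop from first_to_last only", {
  visits <- rbind(make_traj(5, 1, anchor = TRUE, id = "solo"),
                  make_traj(c(2, 6), c(1, 2), anchor = TRUE, id = "duo"))
  coh <- edss_cohort(visits)
  expect_message(r_ftl <- assessment_rate(coh, "first_to_last", "obs"),
                 "single-observation")
  expect_equal(r_ftl$n_patients, 1)
  expect_equal(r_ftl$rate, 2 / 4)
  r_otl <- assessment_rate(coh, "onset_to_last", "obs")
  expect_equal(r_otl$n_patients, 2)
  expect_equal(r_otl$rate, 3 / 11)   # (1 + 2) records over (5 + 6) years
})

test_that("left-censoring size uses the first expected measure when present", {
  tr <- make_traj(c(4, 6), c(1, 1), anchor = TRUE)
  coh <- suppressMessages(augment_cohort(edss_cohort(tr)))
  r_obs <- assessment_rate(coh, "onset_to_last", "obs")
  expect_equal(r_obs$mean_onset_to_first, 4)
  r_exp <- assessment_rate(coh, "onset_to_last", "obs_plus_exp")
  expect_equal(r_exp$mean_onset_to_first, 2)  # Exp for level 1 sits at t = 2
})

test_that("censoring windows tile onset-to-horizon exactly", {
  tr <- make_traj(c(3, 9), c(1, 2), anchor = TRUE)
  part <- censoring_partition(tr, horizon = 12)
  expect_equal(part$window, c("left", "interval", "right"))
  expect_equal(part$start, c(0, 3, 9))
  expect_equal(part$end, c(3, 9, 12))
  expect_equal(sum(part$length), 12)
  expect_true(all(part$defined))

  # a single visit gives a degenerate interval window
  part1 <- censoring_partition(make_traj(5, 1, anchor = TRUE), horizon = 8)
  expect_equal(part1$length[part1$window == "interval"], 0)

  # no horizon: the right window is undefined, not zero
  part2 <- censoring_partition(tr)
  expect_true(is.na(part2$length[part2$window == "right"]))
  expect_false(part2$defined[part2$window == "right"])

  # unknown onset: left window flagged undefined
  part3 <- censoring_partition(make_traj(c(3, 9), c(1, 2)), horizon = 12)
  expect_false(part3$defined[part3$window == "left"])
  expect_true(is.na(part3$start[part3$window == "left"]))
})

test_that("the reported onset-to-first gap recovers the generator's delay", {
  p <- sim_params(n_patients = 1000, onset_delay_mean = 2,
                  onset_delay_shape = 2, relapse_rate = 0, seed = 88)
  coh <- suppressMessages(simulate_cohort(p))
  r <- assessment_rate(coh, "onset_to_last", "obs")
  se <- 2 / sqrt(2) / sqrt(1000)   # gamma(shape 2) sd = mean/sqrt(shape)
  expect_lt(abs(r$mean_onset_to_first - 2), 3 * se)
})

test_that("era reports split rates on calendar time with shared patients", {
  visits <- rbind(make_traj(c(1, 3, 11, 13), c(1, 1, 2, 2), anchor = TRUE,
                            id = "a"),
                  make_traj(c(2, 4), c(1, 1.5), anchor = TRUE, id = "b"))
  patients <- data.frame(patient_id = c("a", "b"), onset_known = TRUE,
                         onset_year = c(1985, 1986), groups = "g")
  coh <- edss_cohort(visits, patients)
  eras <- data.frame(era = c("early", "late"), start = c(1985, 1995),
                     end = c(1994, 2004))
  rep <- era_report(coh, eras)
  # patient a appears in both eras, patient b only in the first
  expect_equal(rep$n_patients, c(2, 1))
  expect_equal(rep$rate[rep$era == "early"], 4 / 4)   # (2+2) obs over (2+2) yrs
  expect_equal(rep$rate[rep$era == "late"], 2 / 2)

  # doubling in-era visits (inside the window) doubles that era's rate
  extra <- make_traj(c(1.5, 2.5), c(1, 1), id = "a")
  coh2 <- edss_cohort(rbind(visits, extra), patients)
  rep2 <- era_report(coh2, eras)
  expect_equal(rep2$total_records[rep2$era == "early"], 6)
  expect_equal(rep2$rate[rep2$era == "late"], rep$rate[rep$era == "late"])

  # an era without observations is omitted with a warning
  eras3 <- rbind(eras, data.frame(era = "none", start = 2050, end = 2060))
  expect_warning(rep3 <- era_report(coh, eras3), "omitted")
  expect_equal(nrow(rep3), 2)
})
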