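# edssmidpath

Censoring-bias-adjusted estimation of disability progression speed from
irregular EDSS clinic-visit records in relapsing-onset multiple sclerosis.

## The problem

Disability in multiple sclerosis is tracked with the Expanded Disability
Status Scale (EDSS), an ordinal score recorded only when the patient
happens to attend clinic. A patient who progresses from EDSS 1 to EDSS 2
between two visits four years apart is first *observed* at EDSS 2 at the
later visit, although the underlying transition happened at some unknown
earlier time. Conventional analyses place the event on the day of the
attaining visit — the **maximum survival time** assumption — and therefore
systematically *understate* progression speed. The size of the bias scales
with the gap between visits, so sparsely assessed patients (and sparsely
assessed eras) look artificially slow, contaminating comparisons across
study groups and time periods.

`edssmidpath` implements the midpoint-survival-time adjustment:

1. **Irreversible disability paths.** For each patient, the monotone
   sequence of EDSS levels that were attained and never subsequently
   undercut is extracted; transitorily high readings (e.g. during a
   relapse) are excluded from the path.
2. **Interval censoring brackets.** Each irreversible level `e` is bracketed
   between `t_min(e)` (the last visit at which the patient was still below
   `e`) and `t_max(e)` (the visit at which `e` was first attained for good).
3. **Expected midpoint measures.** When a single visit attains a run of `k`
   grid levels over a bracket `(t_a, t_b]`, the levels are placed at the
   equal-subinterval midpoints `t_a + (2j - 1)(t_b - t_a) / (2k)`,
   `j = 1, …, k` — for `k = 1` simply the interval midpoint.
4. **Estimation.** Progression speed is the slope `β` in the through-origin
   model `EDSS = β · yso + ε` (yso = years since assessed symptom onset),
   fitted over the near-linear range EDSS ≤ 6, with patient-level cluster
   bootstrap confidence intervals. Under the midpoint assumption the model
   is populated with clinical observations *plus* the expected midpoint
   measures; under the maximum assumption with clinical observations only.
   An alternative `"measures"` population fits on the irreversible-path
   vertices (one record per level at its assumption-specific survival
   time), which isolates the censoring adjustment and is the population
   used for dispersion comparisons across assessment eras.
   Kaplan–Meier curves of time to each irreversible EDSS level are fitted
   under either assumption, with right-censoring at the last clinical
   observation in both cases.

The package also ships a synthetic cohort generator (latent linear
disability, gamma-renewal visit process, Poisson relapses), censoring-size
diagnostics (assessment rates per patient-year, left/interval/right
censoring windows, per-era reports), and a reproducible end-to-end
pipeline.

## Worked example

A patient with assessed onset (EDSS 0 at time 0) and three visits: EDSS 1
at 2 and 4 years, then EDSS 2 at 6 years. The jump 1 → 2 skips level 1.5,
so two levels are attained at the same visit.

```r
library(edssmidpath)

coh <- edss_cohort(data.frame(
  patient_id = "p1",
  time   = c(0, 2, 4, 6),
  edss   = c(0, 1, 1, 2),
  source = c("onset_anchor", "clinical", "clinical", "clinical")
))

irreversible_levels(trajectory(coh, "p1"))
#> # A tibble: 3 × 2
#>   level t_attained
#>   <dbl>      <dbl>
#> 1   1            2
#> 2   1.5          6
#> 3   2            6

expected_midpoints(trajectory(coh, "p1"))
#> # A tibble: 3 × 5
#>   patient_id level  time bracket_low bracket_high
#>   <chr>      <dbl> <dbl>       <dbl>        <dbl>
#> 1 p1           1     1             0            2
#> 2 p1           1.5   4.5           4            6
#> 3 p1           2     5.5           4            6
```

Level 1 is bracketed by onset and the first visit, so its expected time is
the midpoint, 1 year. Levels 1.5 and 2 share the bracket (4, 6] and are
placed at its equal-subinterval midpoints 4.5 and 5.5. `augment_cohort()`
merges these expected measures into the record stream:

```r
augment_cohort(coh)$visits
#> # A tibble: 7 × 6
#>   patient_id  time  edss source            bracket_low bracket_high
#>   <chr>      <dbl> <dbl> <chr>                   <dbl>        <dbl>
#> 1 p1           0     0   onset_anchor               NA           NA
#> 2 p1           1     1   expected_midpoint           0            2
#> 3 p1           2     1   clinical                   NA           NA
#> 4 p1           4     1   clinical                   NA           NA
#> 5 p1           4.5   1.5 expected_midpoint           4            6
#> 6 p1           5.5   2   expected_midpoint           4            6
#> 7 p1           6     2   clinical                   NA           NA
```

On a full simulated cohort (latent rate 0.17 EDSS/year, 2-year mean visit
gap) the adjustment recovers a measurably faster — and less biased — rate:

```r
coh <- simulate_cohort(sim_params(n_patients = 250, seed = 1))
aug <- augment_cohort(coh)
#> augment_cohort: 1417 expected midpoint records for 250 patients

compare_assumptions(aug, B = 999, seed = 1)
#> <assumption_comparison> group = simulated
#>   beta_mid = 0.1637, beta_max = 0.1573 EDSS/yr
#>   midpoint estimate 4.06% faster; difference 95% CI [0.00577, 0.00709] (excludes 0)

fit_rate(aug, "midpoint", boot = 999, seed = 1)
#> <rate_estimate> beta_yso = 0.1637 EDSS/yr (midpoint survival time, pooled variant)
#>   se = 0.000659, 95% CI [0.1625, 0.165] (cluster bootstrap, B = 999)
#>   group = simulated, 250 patients, 4352 records with EDSS <= 6

km_suite(select_onset_cohort(aug), levels = c(2, 3), assumption = "midpoint")
#> <km_suite> 2 endpoint curves (midpoint survival time)
#>   EDSS    2: 250 events / 250 patients; median 11.61 yso
#>   EDSS    3: 236 events / 250 patients; median 17.55 yso
```

The censoring-size diagnostics quantify *why* the adjustment matters:

```r
assessment_rate(aug, "first_to_last", "obs")$rate
#> [1] 0.5793006
```

— roughly one EDSS assessment every other year, leaving multi-year
censoring brackets around every progression event.

## The pipeline

`run_pipeline()` executes the whole analysis from one configuration (an R
list or a YAML file) and writes plain-text artifacts — `augmented.csv`,
`rate_<assumption>.json`, `comparison.json`, `km.csv`,
`censoring_report.csv`, `era_report.csv` and a `manifest.json` — such that
identical configuration and seed reproduce every output byte for byte. A
command-line wrapper is installed at
`system.file("scripts", "edss-midpath.R", package = "edssmidpath")`.

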