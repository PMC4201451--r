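#' The admissible EDSS value grid
#'
#' The Expanded Disability Status Scale (EDSS) is an ordinal neurological
#' disability score running from 0 (normal examination) to 10 (death due to
#' MS) in half-point steps from 1 upward. The value 0.5 does not exist on the
#' scale, so the admissible grid is \{0\} followed by \{1.0, 1.5, ..., 10\}.
#' All half-point values are exactly representable in double precision, so
#' grid membership is tested by exact comparison.
#'
#' @return Numeric vector of the 20 admissible EDSS values, increasing.
#' @export
#' @examples
#' edss_grid()
edss_grid <- function() {
  c(0, (2:20) / 2)
}

#' Test whether values lie on the admissible EDSS grid
#'
#' @param x Numeric vector.
#' @return Logical vector, `TRUE` where `x` is an admissible EDSS value.
#' @export
is_edss_value <- function(x) {
  !is.na(x) & x %in% edss_grid()
}

#' EDSS endpoint levels (grid values >= 1)
#'
#' Irreversible disability endpoints are defined at grid levels 1.0 upward;
#' EDSS 0 is the assumed state at symptom onset, never an endpoint.
#'
#' @param max_level Highest level to include (default 10).
#' @return Numeric vector of endpoint levels.
#' @export
edss_endpoint_levels <- function(max_level = 10) {
  g <- edss_grid()
  g[g >= 1 & g <= max_level]
}

# Floor a latent (continuous) disability value to the last attained grid
# level. Values in (0, 1) floor to 0 because 0.5 is not on the scale.
edss_grid_floor <- function(x) {
  g <- edss_grid()
  idx <- findInterval(x, g)
  out <- numeric(length(x))
  out[idx >= 1] <- g[idx[idx >= 1]]
  out
}

# Snap an elevated (relapse) reading to the admissible grid. Inputs are
# half-point multiples by construction; the only inadmissible one is 0.5,
# which maps up to 1.0. Values are clamped to [0, 10].
edss_grid_snap <- function(x) {
  x <- pmin(pmax(x, 0), 10)
  x[x > 0 & x < 1] <- 1
  x
}

#' Survival-time assumptions
#'
#' The three analytic assumptions about when an interval-censored
#' irreversible progression event occurred: `"maximum"` places the event on
#' the day of the attaining clinic visit (disability is modelled to remain as
#' last measured until the next visit — slowest possible progression),
#' `"minimum"` places it immediately after the last prior visit at which the
#' patient was still below the endpoint (fastest possible), and `"midpoint"`
#' places it at the expected midpoint of the censoring interval.
#'
#' @return Character vector `c("maximum", "minimum", "midpoint")`.
#' @export
survival_assumptions <- function() {
  c("maximum", "minimum", "midpoint")
}

match_assumption <- function(assumption) {
  match.arg(assumption, survival_assumptions())
}

#' Observation labels
#'
#' Classification of records along a patient's trajectory:
#' \describe{
#'   \item{Oo}{synthetic onset observation (EDSS 0 at assessed onset)}
#'   \item{Of}{first clinical observation at an irreversible EDSS endpoint}
#'   \item{Om}{intermediate repeat observation at an irreversible endpoint}
#'   \item{Or}{last repeat observation at an irreversible endpoint}
#'   \item{Ot}{transitorily high clinical observation (later contradicted by
#'     a strictly lower reading, e.g. during a relapse)}
#'   \item{Exp}{expected midpoint survival-time measure (imputed)}
#' }
#'
#' @return Character vector of the six labels.
#' @export
observation_labels <- function() {
  c("Oo", "Of", "Om", "Or", "Ot", "Exp")
}

# Sources a visit record can have.
visit_sources <- function() {
  c("clinical", "onset_anchor", "expected_midpoint")
}
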