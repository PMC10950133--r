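# Per-cycle valuation rules: which euros and which utility each slice of
# the cohort accrues in a cycle, and how both are discounted.

#' Discount factor
#'
#' Costs and health outcomes are discounted identically at the annual rate
#' `rate`; the first model cycle (t = 0) is undiscounted.
#'
#' @param rate Annual discount rate (fraction, e.g. 0.03).
#' @param t Completed years since model start (cycle index, >= 0).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  (1 + rate)^(-t)
}

#' Specialist visit cost under the configured delivery mix
#'
#' The base case averages public-tariff and private-price visits with the
#' configured public share (default 0.5, equal weights). The alternative
#' supply scenarios price every visit publicly, privately, or at the public
#' tariff set equal to the private price.
#'
#' @param costs The `costs` component of an `ha_parameters` object.
#' @param kind `"first"` (diagnostic work-up visit) or `"followup"`
#'   (annual check while using the device).
#' @return Cost in euro per visit.
#' @export
visit_costs <- function(costs, kind = c("first", "followup")) {
  kind <- match.arg(kind)
  pub <- if (kind == "first") costs$first_visit_public else costs$followup_public
  priv <- if (kind == "first") costs$first_visit_private else costs$followup_private
  switch(costs$cost_mix_mode,
    base_mix = costs$public_visit_share * pub + (1 - costs$public_visit_share) * priv,
    private_only = priv,
    public_only = pub,
    public_at_private_price = priv,
    stop("unknown cost_mix_mode: ", costs$cost_mix_mode, call. = FALSE)
  )
}

#' Device cost per acquisition
#'
#' The private market price (which bundles the post-purchase service) in
#' the base case and private-only scenario; the public reimbursement tariff
#' in the public-only scenario; the private price charged to the public
#' payer in the tariff-equals-price scenario.
#'
#' @inheritParams visit_costs
#' @return Cost in euro per device acquired (purchase or replacement).
#' @export
device_cost <- function(costs) {
  switch(costs$cost_mix_mode,
    base_mix = costs$device_private_price,
    private_only = costs$device_private_price,
    public_only = costs$device_public_tariff,
    public_at_private_price = costs$device_private_price,
    stop("unknown cost_mix_mode: ", costs$cost_mix_mode, call. = FALSE)
  )
}

#' Annual probability of an injurious fall leading to hospitalisation
#'
#' Baseline incidence is age-banded (60-64, 65-69, 70-74, 75+; no incidence
#' is available below 60, where the probability is 0). For unaided hearing
#' impairment the published odds ratio is applied on the odds scale,
#' `p' = OR * o / (1 + OR * o)` with `o = p / (1 - p)`; for aided
#' impairment the published hazard ratio is applied on the complement
#' scale, `p' = 1 - (1 - p)^HR`. Both conversions respect the scale each
#' ratio was estimated on.
#'
#' @param falls The `falls` component of an `ha_parameters` object.
#' @param age Age in years (>= 55).
#' @param aided Is the person a compliant hearing-aid user?
#' @param hearing_impaired Does the person have any hearing loss?
#' @return Annual fall probability.
#' @export
falls_probability <- function(falls, age, aided, hearing_impaired) {
  if (age < 60) return(0)
  band <- if (age < 65) "60_64" else if (age < 70) "65_69" else if (age < 75) "70_74" else "75_plus"
  p <- falls$baseline_incidence[[band]]
  if (!hearing_impaired) return(p)
  if (aided) {
    1 - (1 - p)^falls$hr_aided
  } else {
    o <- p / (1 - p)
    falls$or_unaided * o / (1 + falls$or_unaided * o)
  }
}

#' Annual excess occupational cost of hearing impairment
#'
#' Applied to moderate and severe hearing loss up to the working-age limit
#' (64 years). Compliant aid use mitigates the cost proportionally to the
#' relative reduction in unemployment between unaided and aided hearing
#' impaired people of the same severity.
#'
#' @param productivity The `productivity` component of an `ha_parameters`
#'   object.
#' @param age Age in years.
#' @param severity One of `"NORMAL"`, `"MILD"`, `"MODERATE"`, `"SEVERE"`.
#' @param aided Compliant hearing-aid use.
#' @return Euro per person-year.
#' @export
productivity_costs <- function(productivity, age, severity, aided) {
  severity <- match.arg(severity, HEARING_STATES)
  if (age > productivity$productivity_age_limit) return(0)
  if (severity %in% c("NORMAL", "MILD")) return(0)
  base <- productivity$annual_excess_occupational_cost
  if (!aided) return(base)
  sev <- tolower(severity)
  uu <- productivity$unemployment_unaided[[sev]]
  ua <- productivity$unemployment_aided[[sev]]
  if (uu <= 0) stop("unaided unemployment rate must be positive to compute the aided reduction",
                    call. = FALSE)
  base * (1 - (uu - ua) / uu)
}

#' Productivity loss for visit days
#'
#' Each specialist visit costs one day of per-capita gross domestic
#' product, restricted to working age (64 and below), mirroring the
#' occupational-cost block.
#'
#' @inheritParams productivity_costs
#' @param visits Expected number of visits.
#' @return Euro.
#' @export
visit_day_productivity_loss <- function(productivity, visits, age) {
  if (any(visits < 0)) stop("visits must be >= 0", call. = FALSE)
  if (age > productivity$productivity_age_limit) return(0)
  visits * productivity$daily_gdp_per_capita
}

#' Value one model cycle
#'
#' Computes the utility and the component-wise euro costs accrued by a
#' given cohort occupancy and event set in one annual cycle. Utility is the
#' occupancy-weighted mean of state utilities: 1.0 for normal hearing,
#' aided weights for compliant users, unaided weights otherwise (including
#' non-compliant owners). Costs cover first and follow-up visit bundles,
#' device acquisitions, expected injurious falls priced at the femur
#' fracture DRG tariff, transport per visit, and the two productivity
#' components.
#'
#' @param occupancy 4x4 matrix of alive occupancy: rows NORMAL/MILD/
#'   MODERATE/SEVERE, columns NAIVE/DECLINED/OWNER_NONCOMPLIANT/
#'   USER_COMPLIANT (normal-hearing mass sits in the NAIVE column).
#' @param events List with expected counts `first_visits`,
#'   `followup_visits`, `purchases`, `replacements` (missing entries
#'   default to 0).
#' @param params An `ha_parameters` object.
#' @param age Age at the start of the cycle.
#' @return List with `utility` (QALY weight accrued per cohort member this
#'   cycle), `expected_falls`, `components` (named euro vector:
#'   first_visits, followup_visits, device, falls, transport,
#'   productivity_excess, productivity_visit_days) and `total_cost`.
#' @export
cycle_valuation <- function(occupancy, events, params, age) {
  stopifnot(is.matrix(occupancy), all(dim(occupancy) == c(4L, 4L)))
  ev <- list(first_visits = 0, followup_visits = 0, purchases = 0, replacements = 0)
  ev[names(events)] <- events
  u <- params$utilities
  co <- params$costs
  state_u <- matrix(rep(c(u$normal_hearing, u$unaided), 4), 4, 4)
  state_u[2:4, 4] <- u$aided  # compliant users accrue aided utility
  utility <- sum(occupancy * state_u)

  n_visits <- ev$first_visits + ev$followup_visits
  falls_p <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    falls_p[i, j] <- falls_probability(params$falls, age,
                                       aided = (j == 4L && i > 1L),
                                       hearing_impaired = i > 1L)
  }
  expected_falls <- sum(occupancy * falls_p)

  prod_excess <- 0
  if (age <= params$productivity$productivity_age_limit) {
    for (i in 3:4) {  # moderate, severe
      sev <- HEARING_STATES[i]
      unaided_mass <- sum(occupancy[i, 1:3])
      aided_mass <- occupancy[i, 4]
      prod_excess <- prod_excess +
        unaided_mass * productivity_costs(params$productivity, age, sev, aided = FALSE) +
        aided_mass * productivity_costs(params$productivity, age, sev, aided = TRUE)
    }
  }

  components <- c(
    first_visits = ev$first_visits * visit_costs(co, "first"),
    followup_visits = ev$followup_visits * visit_costs(co, "followup"),
    device = (ev$purchases + ev$replacements) * device_cost(co),
    falls = expected_falls * co$femur_drg_tariff,
    transport = n_visits * co$transport_per_visit,
    productivity_excess = prod_excess,
    productivity_visit_days = visit_day_productivity_loss(params$productivity, n_visits, age)
  )
  list(utility = utility, expected_falls = expected_falls,
       components = components, total_cost = sum(components))
}
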