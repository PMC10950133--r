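# Shared fixtures. The default synthetic bundle is deterministic, so it is
# built once per test run and reused.

.fixture_env <- new.env()

test_bundle <- function() {
  if (is.null(.fixture_env$bundle)) .fixture_env$bundle <- fixture_bundle(seed = 1)
  .fixture_env$bundle
}

# life table with a flat annual death probability (horizon still closes)
flat_life_table <- function(q, gender = "male") {
  life_table(55:110, c(rep(q, 55), 1), gender)
}

zero_mortality_lt <- function(gender = "male") flat_life_table(0, gender)

# transition model with a single NORMAL -> MILD rate
single_rate_tm <- function(p_nm) {
  m <- matrix(0, 4, 4)
  m[1, 2] <- p_nm
  transition_model(m)
}

# random valid transition model (gradual ordering by construction)
random_tm <- function() {
  m <- matrix(0, 4, 4)
  for (i in 1:3) {
    steps <- sort(stats::runif(4 - i, 0, 0.25 / (4 - i)), decreasing = TRUE)
    m[i, (i + 1):4] <- steps
  }
  transition_model(m)
}

# parameters stripped to pure survival accounting: unit utilities, no costs
degenerate_params <- function(gender = "male") {
  p <- default_parameters(gender)
  p$utilities$unaided[] <- 1
  p$utilities$aided[] <- 1
  for (k in c("first_visit_public", "first_visit_private", "followup_public",
              "followup_private", "device_private_price", "device_public_tariff",
              "transport_per_visit", "femur_drg_tariff",
              "annual_excess_occupational_cost", "daily_gdp_per_capita")) {
    p <- hearcue:::param_set_key(p, k, 0)
  }
  p$falls$baseline_incidence[] <- 0
  p$economic$annual_discount_rate <- 0
  p
}

# a minimal synthetic arm result for outcome-identity tests
fake_arm_result <- function(arm, cost, qaly, ly = 20, wtp = 16265, gender = "male") {
  structure(list(arm = arm, gender = gender, mean_cost = cost, mean_qaly = qaly,
                 mean_ly = ly, nmb = wtp * qaly - cost, wtp = wtp, trace = NULL),
            class = "ha_arm_result")
}
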