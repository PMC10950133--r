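test_that("compliance with and without post-purchase service", {
  pw <- default_parameters("male")$pathway
  expect_equal(unname(compliance_for_arm(pw, "ha_plus_pps")), rep(0.94, 3))
  expect_equal(unname(compliance_for_arm(pw, "ha_alone")), rep(0.94 * (1 - 0.36), 3))

  pw$pps_decrement_mode <- "absolute"
  expect_equal(unname(compliance_for_arm(pw, "ha_alone")), rep(0.94 - 0.36, 3))
  pw$pps_compliance_decrement <- 0.95
  expect_error(compliance_for_arm(pw, "ha_alone"), "outside")

  pw$pps_compliance_decrement <- 0
  pw$pps_decrement_mode <- "relative"
  expect_equal(compliance_for_arm(pw, "ha_alone"), compliance_for_arm(pw, "ha_plus_pps"))
})

test_that("uptake split is the product of the four journey stages", {
  pw <- default_parameters("male")$pathway
  sp <- uptake_split(pw, "mild", "ha_plus_pps")
  expect_equal(sum(sp), 1)
  expect_equal(sp[["user_compliant"]], 0.27 * 0.7037 * 0.8421 * 0.94)
  expect_equal(sp[["owner_noncompliant"]], 0.27 * 0.7037 * 0.8421 * 0.06)
  expect_equal(sp[["no_device"]], 0.27 * (1 - 0.7037 * 0.8421))
  expect_equal(sp[["no_journey"]], 1 - 0.27)

  sp <- uptake_split(pw, "severe", "ha_plus_pps")
  expect_equal(sp[["user_compliant"]], 0.54 * 0.9259 * 0.94 * 0.94)

  sp <- uptake_split(pw, "severe", "ha_alone")
  expect_equal(sp[["user_compliant"]], 0.54 * 0.9259 * 0.94 * 0.6016)

  pw$completion[] <- 0
  for (sev in c("mild", "moderate", "severe")) {
    expect_equal(unname(uptake_split(pw, sev, "ha_plus_pps")), c(0, 0, 0, 1))
  }
})

test_that("degenerate valuation collapses QALYs to life years", {
  b <- test_bundle()
  p <- degenerate_params()
  res <- run_arm(p, b$tm_male, b$lt_male, "ha_plus_pps")
  expect_equal(res$mean_qaly, res$mean_ly, tolerance = 1e-12)
  expect_equal(res$mean_cost, 0)
})

test_that("survival accounting matches the geometric closed form", {
  # flat 50% annual mortality, no progression, unit utility, no discounting
  p <- degenerate_params()
  res <- run_arm(p, single_rate_tm(0), flat_life_table(0.5), "no_treatment")
  expect_equal(res$mean_ly, sum(0.5^(1:55)), tolerance = 1e-12)
})

test_that("occupancy is conserved and life years are treatment-invariant", {
  b <- test_bundle()
  for (gender in c("male", "female")) {
    p <- if (gender == "male") b$params_male else b$params_female
    lt <- if (gender == "male") b$lt_male else b$lt_female
    tm <- if (gender == "male") b$tm_male else b$tm_female
    arms <- run_all_arms(p, tm, lt)
    lys <- vapply(arms, function(a) a$mean_ly, numeric(1))
    expect_lt(max(lys) - min(lys), 1e-10)
    for (a in arms) {
      expect_true(all(abs(a$trace$alive + a$trace$dead - 1) < 1e-10))
    }
  }
})

test_that("QALYs order with treatment intensity", {
  b <- test_bundle()
  arms <- run_all_arms(b$params_male, b$tm_male, b$lt_male)
  expect_gte(arms$ha_plus_pps$mean_qaly, arms$ha_alone$mean_qaly)
  expect_gte(arms$ha_alone$mean_qaly, arms$no_treatment$mean_qaly)
})

test_that("compliant use is absorbing in the trace", {
  b <- test_bundle()
  for (arm in c("ha_alone", "ha_plus_pps")) {
    res <- run_arm(b$params_male, b$tm_male, b$lt_male, arm)
    tr <- res$trace
    user_cols <- grep("_user_compliant$", names(tr), value = TRUE)
    user <- rowSums(tr[user_cols])
    q <- hearcue:::lt_q(b$lt_male, tr$age)
    # once created, compliant mass can only shrink through mortality
    expect_true(all(user[-1] >= user[-length(user)] * (1 - q[-1]) - 1e-12))
  }
})

test_that("the no-treatment arm accrues no treatment costs or aided utility", {
  b <- test_bundle()
  res <- run_arm(b$params_male, b$tm_male, b$lt_male, "no_treatment")
  tr <- res$trace
  expect_true(all(tr$cost_first_visits == 0))
  expect_true(all(tr$cost_followup_visits == 0))
  expect_true(all(tr$cost_device == 0))
  expect_true(all(tr$purchases == 0))
  user_cols <- grep("_user_compliant$|_owner_noncompliant$|_declined$", names(tr),
                    value = TRUE)
  expect_true(all(as.matrix(tr[user_cols]) == 0))
})

test_that("raising any single uptake probability never lowers treated QALYs", {
  b <- test_bundle()
  base <- run_arm(b$params_male, b$tm_male, b$lt_male, "ha_plus_pps",
                  trace = FALSE)$mean_qaly
  set.seed(99)
  keys <- c("p_journey_completion_mild", "p_journey_completion_severe",
            "p_prescription_moderate", "p_purchase_mild", "p_purchase_severe",
            "p_compliance_moderate")
  for (key in keys) {
    p2 <- b$params_male
    cur <- hearcue:::param_get_key(p2, key)
    p2 <- hearcue:::param_set_key(p2, key, cur + stats::runif(1) * (1 - cur))
    if (length(validate_parameters(p2))) next
    up <- run_arm(p2, b$tm_male, b$lt_male, "ha_plus_pps", trace = FALSE)$mean_qaly
    expect_gte(up, base - 1e-12)
  }
})

test_that("device replacements follow the five-year vintage clock", {
  # single purchase vintage: severe onset forced in year one, no mortality
  # until the horizon closes, so replacements recur every 5 cycles
  p <- default_parameters("male")
  lt0 <- zero_mortality_lt()
  m <- matrix(0, 4, 4); m[1, 2] <- 1  # everyone mild after one cycle
  tm <- transition_model(m)
  res <- run_arm(p, tm, lt0, "ha_plus_pps")
  tr <- res$trace
  compliant0 <- uptake_split(p$pathway, "mild", "ha_plus_pps")[["user_compliant"]]
  expect_equal(tr$purchases[1], 0.27 * 0.7037 * 0.8421)
  # replacement cycles: every 5 years after the cycle-1 purchase, the then
  # still-compliant members of that vintage replace the device
  repl_idx <- which(tr$replacements > 0)
  expect_true(all(diff(repl_idx) == 5))
  expect_equal(tr$replacements[repl_idx[1]], compliant0, tolerance = 1e-9)

  trace_csv <- withr::local_tempfile(fileext = ".csv")
  write_trace(res, trace_csv)
  expect_equal(nrow(utils::read.csv(trace_csv)), nrow(tr))
})
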