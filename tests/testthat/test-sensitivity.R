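test_that("default ranges are clipped to scale and joint validity", {
  p <- default_parameters("male")
  spec <- dsa_spec(p)
  expect_true(all(spec$low <= spec$base + 1e-12))
  expect_true(all(spec$base <= spec$high + 1e-12))
  for (i in seq_len(nrow(spec))) {
    for (v in c(spec$low[i], spec$high[i])) {
      expect_length(validate_parameters(
        hearcue:::param_set_key(p, spec$parameter[i], v)), 0)
    }
  }
  # utilities clip against ordering constraints, not only [0,1]
  row <- spec[spec$parameter == "utility_aided_mild", ]
  expect_gte(row$low, p$utilities$unaided[["mild"]])
  expect_lte(row$high, 1)
  expect_lte(spec[spec$parameter == "falls_hr_aided", "high"], 1)
  expect_gte(spec[spec$parameter == "falls_or_unaided", "low"], 1)
})

test_that("a null perturbation reproduces the base INMB", {
  b <- test_bundle()
  base_price <- b$params_male$costs$device_private_price
  spec <- data.frame(parameter = "device_private_price", base = base_price,
                     low = base_price, high = base_price)
  dsa <- one_way_dsa(b$params_male, b$tm_male, b$lt_male, spec = spec)
  expect_equal(dsa$inmb_low, attr(dsa, "inmb_base"))
  expect_equal(dsa$inmb_high, attr(dsa, "inmb_base"))
  expect_equal(dsa$width, 0)
})

test_that("widening a utility range widens its tornado bar monotonically", {
  b <- test_bundle()
  p <- b$params_male
  base_u <- p$utilities$unaided[["severe"]]
  widths <- vapply(c(0.02, 0.05, 0.10), function(h) {
    spec <- data.frame(parameter = "utility_unaided_severe", base = base_u,
                       low = base_u - h, high = base_u + h)
    dsa <- one_way_dsa(p, b$tm_male, b$lt_male, spec = spec)
    dsa$width
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("tornado ordering sorts by width with alphabetical tie-break", {
  d <- data.frame(parameter = c("b_par", "c_par", "a_par"),
                  base = 1, low = 0, high = 2,
                  inmb_low = c(0, 0, 0), inmb_high = c(5, 1, 3),
                  width = c(5, 1, 3))
  class(d) <- c("ha_dsa", "data.frame")
  expect_equal(tornado_order(d)$parameter, c("b_par", "a_par", "c_par"))

  ties <- d; ties$width <- 2; ties$inmb_high <- 2
  expect_equal(tornado_order(ties)$parameter, c("a_par", "b_par", "c_par"))

  # permutation invariance of the input row order
  perm <- d[c(3, 1, 2), ]
  expect_equal(tornado_order(perm), tornado_order(d))
})

test_that("degenerate PSA distributions reproduce the deterministic run", {
  b <- test_bundle()
  psa <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 5, seed = 3,
                 se_prob = 0, se_cost = 0, sdlog = 0)
  det_a <- run_arm(b$params_male, b$tm_male, b$lt_male, "ha_plus_pps", trace = FALSE)
  det_b <- run_arm(b$params_male, b$tm_male, b$lt_male, "no_treatment", trace = FALSE)
  expect_equal(psa$draws$delta_cost, rep(det_a$mean_cost - det_b$mean_cost, 5))
  expect_equal(psa$draws$delta_qaly, rep(det_a$mean_qaly - det_b$mean_qaly, 5))
})

test_that("PSA is reproducible under a fixed seed and varies across seeds", {
  b <- test_bundle()
  p1 <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 25, seed = 11)
  p2 <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 25, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$spec_hash, p2$spec_hash)
  p3 <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 25, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("PSA means approach the deterministic deltas as uncertainty shrinks", {
  b <- test_bundle()
  det <- run_arm(b$params_male, b$tm_male, b$lt_male, "ha_plus_pps", trace = FALSE)$mean_qaly -
    run_arm(b$params_male, b$tm_male, b$lt_male, "no_treatment", trace = FALSE)$mean_qaly
  errs <- vapply(c(0.05, 0.01), function(se) {
    ps <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 40, seed = 5,
                  se_prob = se, se_cost = se, sdlog = se)
    abs(mean(ps$draws$delta_qaly) - det)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("the acceptability curve equals a direct iteration count", {
  b <- test_bundle()
  psa <- run_psa(b$params_male, b$tm_male, b$lt_male, n = 40, seed = 21)
  grid <- c(0, 5000, 16265)
  curve <- ceac(psa, grid)
  for (i in seq_along(grid)) {
    hits <- 0
    for (j in seq_len(nrow(psa$draws))) {
      if (grid[i] * psa$draws$delta_qaly[j] - psa$draws$delta_cost[j] > 0) hits <- hits + 1
    }
    expect_equal(curve$probability[i], hits / nrow(psa$draws))
  }
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # wtp = 0 counts the cost-saving draws
  expect_equal(curve$probability[1], mean(psa$draws$delta_cost < 0))
  # shuffling iterations leaves the curve unchanged
  shuffled <- psa
  shuffled$draws <- psa$draws[sample.int(nrow(psa$draws)), ]
  expect_equal(ceac(shuffled, grid)$probability, curve$probability)
})

test_that("dropout scenarios force the uptake split and order QALY gains", {
  p <- default_parameters("male")
  full <- hearcue:::apply_dropout_scenario(p, "no_dropout_full_compliance")
  for (sev in c("mild", "moderate", "severe")) {
    expect_equal(unname(uptake_split(full$pathway, sev, "ha_plus_pps")), c(1, 0, 0, 0))
    expect_equal(unname(uptake_split(full$pathway, sev, "ha_alone")), c(1, 0, 0, 0))
  }

  b <- test_bundle()
  grid <- run_scenarios(b$params_male, b$tm_male, b$lt_male,
                        cost_mixes = "base_mix")
  pps <- grid[grid$intervention == "ha_plus_pps", ]
  dq <- setNames(pps$delta_qaly, pps$dropout)
  expect_gte(dq[["no_dropout_full_compliance"]], dq[["no_dropout_partial_compliance"]])
  expect_gte(dq[["no_dropout_partial_compliance"]], dq[["current"]])
  # removing dropout raises the INMB (per-user INMB is positive here)
  inmbs <- setNames(pps$inmb, pps$dropout)
  expect_gt(inmbs[["no_dropout_partial_compliance"]], inmbs[["current"]])
})

test_that("the scenario grid covers all cost-mix cells", {
  b <- test_bundle()
  grid <- run_scenarios(b$params_male, b$tm_male, b$lt_male,
                        dropouts = "current")
  expect_equal(nrow(grid), 4 * 2)
  expect_setequal(unique(grid$cost_mix),
                  c("base_mix", "private_only", "public_only", "public_at_private_price"))
  # public tariffs are the cheapest supply route, private the dearest
  pps <- grid[grid$intervention == "ha_plus_pps", ]
  cost_by_mix <- setNames(pps$delta_cost, pps$cost_mix)
  expect_lt(cost_by_mix[["public_only"]], cost_by_mix[["base_mix"]])
  expect_gt(cost_by_mix[["private_only"]], cost_by_mix[["public_only"]])
})
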