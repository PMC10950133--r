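test_that("transition rows combine mortality and progression correctly", {
  lt <- flat_life_table(0.02)
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- c(0.05, 0.01, 0.001)
  tm <- transition_model(m)

  # direct arithmetic: death takes q, survivors split between stay and moves
  row <- transition_row(tm, lt, "NORMAL", 60)
  expect_equal(unname(row),
               c(0.98 * (1 - 0.061), 0.98 * 0.05, 0.98 * 0.01, 0.98 * 0.001, 0.02))
  expect_equal(sum(row), 1)

  # absorbing death
  expect_equal(unname(transition_row(tm, lt, "DEAD", 80)), c(0, 0, 0, 0, 1))

  # most severe state: only stay or die
  lt10 <- flat_life_table(0.1)
  expect_equal(unname(transition_row(tm, lt10, "SEVERE", 70)), c(0, 0, 0, 0.9, 0.1))

  expect_error(transition_row(tm, lt, "NORMAL", 120), "age")
})

test_that("transition rows sum to one for random models, states and ages", {
  set.seed(421)
  for (rep in 1:25) {
    tm <- random_tm()
    lt <- flat_life_table(stats::runif(1, 0, 0.5))
    state <- sample(c("NORMAL", "MILD", "MODERATE", "SEVERE", "DEAD"), 1)
    age <- sample(55:110, 1)
    expect_equal(sum(transition_row(tm, lt, state, age)), 1, tolerance = 1e-12)
  }
})

test_that("gradual ordering is enforced at construction", {
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- c(0.01, 0.05, 0.001)  # two-step jump more likely than one-step
  expect_error(transition_model(m), "gradual")
})

test_that("predicted prevalence follows the cohort recursion", {
  # initial condition and frozen cohort
  lt <- flat_life_table(0.02)
  tm0 <- single_rate_tm(0)
  expect_equal(unname(predicted_prevalence(tm0, lt, 55)), c(1, 0, 0, 0))
  expect_equal(unname(predicted_prevalence(tm0, lt, 90)), c(1, 0, 0, 0))

  # two cycles of a single 0.1 onset rate, no mortality: binomial survival
  tm <- single_rate_tm(0.1)
  prev <- predicted_prevalence(tm, zero_mortality_lt(), 57)
  expect_equal(prev[["NORMAL"]], 0.81)
  expect_equal(prev[["MILD"]], 0.19)

  # state-independent mortality cancels in the alive renormalisation
  expect_equal(predicted_prevalence(tm, flat_life_table(0.3), 70),
               predicted_prevalence(tm, zero_mortality_lt(), 70))

  expect_error(predicted_prevalence(tm, lt, 54), "start age")
})

test_that("any-hearing-loss prevalence is monotone in age and in scale", {
  lt <- test_bundle()$lt_male
  tm <- test_bundle()$tm_male
  prev <- vapply(55:100, function(a) 1 - predicted_prevalence(tm, lt, a)[["NORMAL"]],
                 numeric(1))
  expect_true(all(diff(prev) >= -1e-12))

  up <- tm; up$scale <- tm$scale * 1.5
  prev_up <- vapply(60:100, function(a) 1 - predicted_prevalence(up, lt, a)[["NORMAL"]],
                    numeric(1))
  expect_true(all(prev_up > prev[-(1:5)]))
})

test_that("calibration recovers closed-form and known scale factors", {
  lt0 <- zero_mortality_lt()

  # single onset rate, single target: p solves 1 - (1-p)^15 = 0.25
  tm <- calibrate_to_prevalence(single_rate_tm(0.05), lt0,
                                data.frame(age = 70, target = 0.25))
  expect_equal(tm$scale * 0.05, 1 - 0.75^(1 / 15), tolerance = 1e-6)

  # a model already meeting its targets keeps scale 1
  achieved <- 1 - predicted_prevalence(tm, lt0, 70)[["NORMAL"]]
  re <- calibrate_to_prevalence(tm, lt0, data.frame(age = 70, target = achieved))
  expect_equal(re$scale, tm$scale, tolerance = 1e-4)

  # zero targets drive the scale to zero
  z <- suppressWarnings(calibrate_to_prevalence(single_rate_tm(0.05), lt0,
                                                data.frame(age = c(65, 80), target = c(0, 0))))
  expect_lt(z$scale, 1e-4)

  # parameter recovery: calibrate against the prevalence of a known scaling
  base <- test_bundle()$tm_male; base$scale <- 1
  truth <- base; truth$scale <- 0.8
  lt <- test_bundle()$lt_male
  targets <- data.frame(
    age = c(70, 85),
    target = vapply(c(70, 85), function(a)
      1 - predicted_prevalence(truth, lt, a)[["NORMAL"]], numeric(1)))
  rec <- calibrate_to_prevalence(base, lt, targets)
  expect_equal(rec$scale, 0.8, tolerance = 1e-3)
})

test_that("jointly infeasible targets produce a diagnostic with best achievable", {
  lt0 <- zero_mortality_lt()
  # no single scale factor can keep prevalence near zero at 60 and reach
  # 90% one year later
  expect_warning(
    calibrate_to_prevalence(single_rate_tm(0.05), lt0,
                            data.frame(age = c(60, 61), target = c(0, 0.9))),
    "best achievable")
})

test_that("life tables validate range and horizon closure", {
  expect_error(life_table(55:110, rep(0.5, 56)), "q\\(110\\)")
  expect_error(life_table(60:110, c(rep(0.1, 50), 1)), "55")
  expect_error(life_table(55:110, c(rep(-0.1, 55), 1)), "\\[0,1\\]")
  lt <- flat_life_table(0.1)
  expect_error(hearcue:::lt_q(lt, 111), "range")
})

test_that("life table and transition model CSV round-trips preserve the model", {
  b <- test_bundle()
  flt <- withr::local_tempfile(fileext = ".csv")
  write_life_table(b$lt_female, flt)
  lt2 <- read_life_table(flt, "female")
  expect_equal(lt2$qx, b$lt_female$qx)

  ftm <- withr::local_tempfile(fileext = ".csv")
  write_transition_model(b$tm_male, ftm)
  tm2 <- read_transition_model(ftm)
  # written probabilities fold in the calibration scale
  for (age in c(60, 75)) {
    expect_equal(hearcue:::progression_matrix(tm2, age),
                 hearcue:::progression_matrix(b$tm_male, age),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})
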