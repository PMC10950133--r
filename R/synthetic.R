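# Synthetic stand-ins for the model's two external inputs: gender-specific
# life tables (Gompertz-Makeham adult-mortality hazards) and an annual
# hearing-loss progression model calibrated to population prevalence
# targets. Both are deterministic given their specification, and are
# emitted in the same CSV formats the loaders consume, so real national
# life tables or literature transition probabilities can be dropped in
# with no code change.

#' Gompertz-Makeham mortality curve specification
#'
#' Annual hazard `h(x) = a + b * exp(c * (x - 55))`, converted to annual
#' death probabilities `q(x) = 1 - exp(-h(x))`. The presets are shaped to
#' plausible adult mortality for a high-income population, with the female
#' preset yielding the longer life expectancy.
#'
#' @param gender `"male"` or `"female"` (selects the preset when `a`, `b`,
#'   `c` are not given).
#' @param a Background (age-independent) hazard, >= 0.
#' @param b Level of the senescent hazard at age 55, > 0.
#' @param c Exponential slope per year of age, > 0.
#' @return A list of class `ha_mortality_spec`.
#' @export
mortality_curve_spec <- function(gender = c("male", "female"),
                                 a = NULL, b = NULL, c = NULL) {
  gender <- match.arg(gender)
  preset <- if (gender == "male") {
    list(a = 2e-4, b = 3.5e-3, c = 0.095)
  } else {
    list(a = 1e-4, b = 1.8e-3, c = 0.103)
  }
  spec <- list(gender = gender,
               a = if (is.null(a)) preset$a else a,
               b = if (is.null(b)) preset$b else b,
               c = if (is.null(c)) preset$c else c)
  if (spec$a < 0 || spec$b <= 0 || spec$c <= 0)
    stop("invalid hazard parameters: need a >= 0, b > 0, c > 0", call. = FALSE)
  structure(spec, class = "ha_mortality_spec")
}

#' Synthesize a life table
#'
#' Builds annual death probabilities for ages 55..110 from a
#' Gompertz-Makeham hazard; `q(110)` is forced to 1 so the model horizon
#' closes. With positive level and slope the probabilities increase
#' strictly with age.
#'
#' @param spec An `ha_mortality_spec`; alternatively pass `gender` to use
#'   the preset.
#' @inheritParams mortality_curve_spec
#' @return An `ha_life_table`.
#' @examples
#' lt <- synth_life_table(gender = "female")
#' head(lt$qx)
#' @export
synth_life_table <- function(spec = NULL, gender = c("male", "female")) {
  if (is.null(spec)) spec <- mortality_curve_spec(match.arg(gender))
  stopifnot(inherits(spec, "ha_mortality_spec"))
  age <- 55:110
  h <- spec$a + spec$b * exp(spec$c * (age - 55))
  qx <- 1 - exp(-h)
  qx[age == 110] <- 1
  life_table(age, qx, spec$gender)
}

#' Hearing-loss progression specification
#'
#' Base annual, conditional-on-survival probabilities for the adjacent
#' steps of the progression chain (normal to mild, mild to moderate,
#' moderate to severe), with multi-step jumps expressed as fractions of the
#' next-shorter jump (`skip2`, `skip3` in \[0,1\]), which guarantees the
#' gradual ordering by construction. Progression accelerates at
#' `age_break` by the factor `late_multiplier`, reflecting the steeper
#' onset of hearing loss at older ages. The default base rates are chosen
#' so that, after calibration against the default prevalence targets (25\%
#' of survivors with any hearing loss at age 70, 50\% at age 85), the
#' calibration scale factor is close to 1.
#'
#' @param p_normal_mild,p_mild_moderate,p_moderate_severe Adjacent-step
#'   annual probabilities.
#' @param skip2,skip3 Two-step and three-step jump fractions.
#' @param age_break Age at which the late band starts.
#' @param late_multiplier Multiplier on all progression probabilities in
#'   the late band (>= 1).
#' @param targets Data frame of calibration targets (`age`, `target`
#'   proportion of survivors with any hearing loss).
#' @return A list of class `ha_progression_spec`.
#' @export
progression_spec <- function(p_normal_mild = 0.0145,
                             p_mild_moderate = 0.030,
                             p_moderate_severe = 0.020,
                             skip2 = 0.25, skip3 = 0.25,
                             age_break = 70, late_multiplier = 1.40,
                             targets = data.frame(age = c(70, 85),
                                                  target = c(0.25, 0.50))) {
  stopifnot(p_normal_mild >= 0, p_mild_moderate >= 0, p_moderate_severe >= 0,
            skip2 >= 0, skip2 <= 1, skip3 >= 0, skip3 <= 1,
            age_break > 55, age_break <= 110, late_multiplier >= 1)
  structure(list(p_normal_mild = p_normal_mild,
                 p_mild_moderate = p_mild_moderate,
                 p_moderate_severe = p_moderate_severe,
                 skip2 = skip2, skip3 = skip3,
                 age_break = age_break, late_multiplier = late_multiplier,
                 targets = targets),
            class = "ha_progression_spec")
}

#' Synthesize a calibrated hearing-loss transition model
#'
#' Builds the gradual-ordered progression matrix from a
#' [progression_spec()] and calibrates its global scale factor against the
#' spec's prevalence targets with [calibrate_to_prevalence()]. The result
#' is deterministic given the spec and life table.
#'
#' @param spec An `ha_progression_spec`.
#' @param lt An `ha_life_table` (used by the calibration cohort).
#' @param tolerance Calibration tolerance passed through (default 0.01).
#' @return A calibrated `ha_transition_model`.
#' @export
synth_transition_model <- function(spec = progression_spec(), lt, tolerance = 0.01) {
  stopifnot(inherits(spec, "ha_progression_spec"))
  base <- matrix(0, 4, 4, dimnames = list(HEARING_STATES, HEARING_STATES))
  base["NORMAL", "MILD"] <- spec$p_normal_mild
  base["NORMAL", "MODERATE"] <- spec$p_normal_mild * spec$skip2
  base["NORMAL", "SEVERE"] <- spec$p_normal_mild * spec$skip2 * spec$skip3
  base["MILD", "MODERATE"] <- spec$p_mild_moderate
  base["MILD", "SEVERE"] <- spec$p_mild_moderate * spec$skip2
  base["MODERATE", "SEVERE"] <- spec$p_moderate_severe
  tm0 <- transition_model(list(base, base * spec$late_multiplier),
                          age_breaks = spec$age_break)
  calibrate_to_prevalence(tm0, lt, spec$targets, tolerance = tolerance)
}

#' Build the full synthetic input bundle
#'
#' One call yields everything a model run needs: default parameter sets
#' for both genders, synthetic life tables, and transition models
#' calibrated per gender against the default prevalence targets. The
#' bundle is deterministic; the seed is recorded for provenance and for
#' any downstream stochastic analysis (e.g. probabilistic sensitivity
#' analysis) seeded from it.
#'
#' @param seed Integer seed recorded in the bundle.
#' @return A list of class `ha_fixture_bundle` with elements `params_male`,
#'   `params_female`, `lt_male`, `lt_female`, `tm` (male-calibrated model;
#'   identical to `tm_female` up to mortality effects on calibration),
#'   `tm_male`, `tm_female` and `seed`.
#' @examples
#' b <- fixture_bundle(seed = 42)
#' arms <- run_all_arms(b$params_male, b$tm_male, b$lt_male)
#' @export
fixture_bundle <- function(seed = 1) {
  lt_male <- synth_life_table(gender = "male")
  lt_female <- synth_life_table(gender = "female")
  tm_male <- synth_transition_model(progression_spec(), lt_male)
  tm_female <- synth_transition_model(progression_spec(), lt_female)
  structure(list(
    params_male = default_parameters("male"),
    params_female = default_parameters("female"),
    lt_male = lt_male, lt_female = lt_female,
    tm = tm_male, tm_male = tm_male, tm_female = tm_female,
    seed = as.integer(seed)
  ), class = "ha_fixture_bundle")
}

#' Write the synthetic bundle's external inputs to CSV
#'
#' Emits the life tables and transition models in the loader formats
#' ([read_life_table()], [read_transition_model()]) plus both parameter
#' configurations as YAML.
#'
#' @param bundle An `ha_fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    lt_male = file.path(dir, "life_table_male.csv"),
    lt_female = file.path(dir, "life_table_female.csv"),
    tm_male = file.path(dir, "transition_model_male.csv"),
    tm_female = file.path(dir, "transition_model_female.csv"),
    params_male = file.path(dir, "params_male.yaml"),
    params_female = file.path(dir, "params_female.yaml")
  )
  write_life_table(bundle$lt_male, paths[["lt_male"]])
  write_life_table(bundle$lt_female, paths[["lt_female"]])
  write_transition_model(bundle$tm_male, paths[["tm_male"]])
  write_transition_model(bundle$tm_female, paths[["tm_female"]])
  write_parameters(bundle$params_male, paths[["params_male"]])
  write_parameters(bundle$params_female, paths[["params_female"]])
  invisible(paths)
}
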