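#' @keywords internal
"_PACKAGE"

HL_SEVERITIES <- c("mild", "moderate", "severe")
HEALTH_STATES <- c("NORMAL", "MILD", "MODERATE", "SEVERE", "DEAD")
AID_STATUSES <- c("NAIVE", "DECLINED", "OWNER_NONCOMPLIANT", "USER_COMPLIANT")
ARM_KINDS <- c("no_treatment", "ha_alone", "ha_plus_pps")
COST_MIX_MODES <- c("base_mix", "private_only", "public_only", "public_at_private_price")

#' Default model parameters
#'
#' Builds the full default parameter set of the cohort model: economic
#' settings (willingness-to-pay threshold, discount rate, horizon), the
#' four-stage uptake-journey probabilities per hearing-loss severity,
#' utility weights (base-case set), unit costs, injurious-fall inputs and
#' productivity-loss inputs. Normal-hearing utility is anchored at 1.0, the
#' upper bound of the utility scale, so hearing-loss states are the only
#' quality-of-life decrements in the model.
#'
#' @param gender `"male"` or `"female"`. The parameter values themselves are
#'   gender-invariant; the field selects which life table a run is paired
#'   with and is carried through to results.
#' @return An object of class `ha_parameters`: a named list with components
#'   `economic`, `pathway`, `utilities`, `costs`, `falls`, `productivity`
#'   and `gender`.
#' @seealso [load_parameters()], [validate_parameters()], [utility_set()]
#' @examples
#' p <- default_parameters("female")
#' p$economic$wtp_per_qaly
#' p$pathway$completion[["severe"]]
#' @export
default_parameters <- function(gender = c("male", "female")) {
  gender <- match.arg(gender)
  p <- list(
    economic = list(
      wtp_per_qaly = 16265,
      annual_discount_rate = 0.03,
      start_age = 55,
      horizon_end_age = 110,
      cycle_length = 1
    ),
    pathway = list(
      completion   = c(mild = 0.2700, moderate = 0.2700, severe = 0.5400),
      prescription = c(mild = 0.7037, moderate = 0.7037, severe = 0.9259),
      purchase     = c(mild = 0.8421, moderate = 0.8421, severe = 0.9400),
      compliance   = c(mild = 0.9400, moderate = 0.9400, severe = 0.9400),
      pps_compliance_decrement = 0.3600,
      pps_decrement_mode = "relative"
    ),
    utilities = utility_set("base_case"),
    costs = list(
      first_visit_public = 29.00,
      first_visit_private = 125.00,
      followup_public = 17.00,
      followup_private = 75.00,
      public_visit_share = 0.5000,
      device_private_price = 1990.90,
      device_public_tariff = 672.50,
      device_replacement_interval = 5,
      transport_per_visit = 5.84,
      femur_drg_tariff = 6099.00,
      mercato_sociale_share = 0.2000,
      mercato_riconducibile_share = 0.2600,
      cost_mix_mode = "base_mix"
    ),
    falls = list(
      baseline_incidence = c("60_64" = 0.0035, "65_69" = 0.0052,
                             "70_74" = 0.0092, "75_plus" = 0.0369),
      or_unaided = 1.9700,
      hr_aided = 0.8700
    ),
    productivity = list(
      annual_excess_occupational_cost = 82.87,
      unemployment_unaided = c(moderate = 0.1070, severe = 0.1560),
      unemployment_aided   = c(moderate = 0.0540, severe = 0.0820),
      daily_gdp_per_capita = 71.73,
      productivity_age_limit = 64
    ),
    gender = gender
  )
  structure(p, class = "ha_parameters")
}

#' Utility-weight sets
#'
#' Two alternative utility-weight sets are supported: the base-case set
#' (EQ-5D-flavoured weights with aided gains concentrated in mild/moderate
#' loss) and an alternative set with flatter unaided decrements. Both share
#' the normal-hearing anchor of 1.0.
#'
#' @param label `"base_case"` or `"alternative"`.
#' @return A list with fields `label`, `normal_hearing`, `unaided` and
#'   `aided` (the latter two named by severity).
#' @export
utility_set <- function(label = c("base_case", "alternative")) {
  label <- match.arg(label)
  if (label == "base_case") {
    list(label = label, normal_hearing = 1.0,
         unaided = c(mild = 0.8000, moderate = 0.6500, severe = 0.4500),
         aided   = c(mild = 0.9300, moderate = 0.9300, severe = 0.6900))
  } else {
    list(label = label, normal_hearing = 1.0,
         unaided = c(mild = 0.8100, moderate = 0.7700, severe = 0.6200),
         aided   = c(mild = 0.9000, moderate = 0.8600, severe = 0.7100))
  }
}

# Flat key schema: maps config-file keys to paths inside the nested
# parameter list. `type` drives validation bounds and sensitivity-analysis
# defaults: prob/utility in [0,1], cost >= 0, or >= 1, hr in (0,1],
# rate in [0,1), count >= 1, age free, enum categorical.
# Built once per session (memoized; it sits on the hot path of the
# sensitivity analyses).
.hearcue_cache <- new.env(parent = emptyenv())

param_schema <- function() {
  if (!is.null(.hearcue_cache$schema)) return(.hearcue_cache$schema)
  .hearcue_cache$schema <- build_param_schema()
  .hearcue_cache$schema
}

build_param_schema <- function() {
  s <- function(key, path, type) data.frame(key = key, path = path, type = type)
  rbind(
    s("gender", "gender", "enum"),
    s("wtp_per_qaly", "economic.wtp_per_qaly", "cost_pos"),
    s("annual_discount_rate", "economic.annual_discount_rate", "rate"),
    s("start_age", "economic.start_age", "age"),
    s("horizon_end_age", "economic.horizon_end_age", "age"),
    s("cycle_length", "economic.cycle_length", "count"),
    s("p_journey_completion_mild", "pathway.completion.mild", "prob"),
    s("p_journey_completion_moderate", "pathway.completion.moderate", "prob"),
    s("p_journey_completion_severe", "pathway.completion.severe", "prob"),
    s("p_prescription_mild", "pathway.prescription.mild", "prob"),
    s("p_prescription_moderate", "pathway.prescription.moderate", "prob"),
    s("p_prescription_severe", "pathway.prescription.severe", "prob"),
    s("p_purchase_mild", "pathway.purchase.mild", "prob"),
    s("p_purchase_moderate", "pathway.purchase.moderate", "prob"),
    s("p_purchase_severe", "pathway.purchase.severe", "prob"),
    s("p_compliance_mild", "pathway.compliance.mild", "prob"),
    s("p_compliance_moderate", "pathway.compliance.moderate", "prob"),
    s("p_compliance_severe", "pathway.compliance.severe", "prob"),
    s("pps_compliance_decrement", "pathway.pps_compliance_decrement", "prob"),
    s("pps_decrement_mode", "pathway.pps_decrement_mode", "enum"),
    s("utility_set", "utilities.label", "enum"),
    s("utility_normal_hearing", "utilities.normal_hearing", "utility"),
    s("utility_unaided_mild", "utilities.unaided.mild", "utility"),
    s("utility_unaided_moderate", "utilities.unaided.moderate", "utility"),
    s("utility_unaided_severe", "utilities.unaided.severe", "utility"),
    s("utility_aided_mild", "utilities.aided.mild", "utility"),
    s("utility_aided_moderate", "utilities.aided.moderate", "utility"),
    s("utility_aided_severe", "utilities.aided.severe", "utility"),
    s("first_visit_public", "costs.first_visit_public", "cost"),
    s("first_visit_private", "costs.first_visit_private", "cost"),
    s("followup_public", "costs.followup_public", "cost"),
    s("followup_private", "costs.followup_private", "cost"),
    s("public_visit_share", "costs.public_visit_share", "prob"),
    s("device_private_price", "costs.device_private_price", "cost"),
    s("device_public_tariff", "costs.device_public_tariff", "cost"),
    s("device_replacement_interval", "costs.device_replacement_interval", "count"),
    s("transport_per_visit", "costs.transport_per_visit", "cost"),
    s("femur_drg_tariff", "costs.femur_drg_tariff", "cost"),
    s("mercato_sociale_share", "costs.mercato_sociale_share", "prob"),
    s("mercato_riconducibile_share", "costs.mercato_riconducibile_share", "prob"),
    s("cost_mix_mode", "costs.cost_mix_mode", "enum"),
    s("falls_incidence_60_64", "falls.baseline_incidence.60_64", "prob"),
    s("falls_incidence_65_69", "falls.baseline_incidence.65_69", "prob"),
    s("falls_incidence_70_74", "falls.baseline_incidence.70_74", "prob"),
    s("falls_incidence_75_plus", "falls.baseline_incidence.75_plus", "prob"),
    s("falls_or_unaided", "falls.or_unaided", "or"),
    s("falls_hr_aided", "falls.hr_aided", "hr"),
    s("annual_excess_occupational_cost", "productivity.annual_excess_occupational_cost", "cost"),
    s("unemployment_unaided_moderate", "productivity.unemployment_unaided.moderate", "prob"),
    s("unemployment_unaided_severe", "productivity.unemployment_unaided.severe", "prob"),
    s("unemployment_aided_moderate", "productivity.unemployment_aided.moderate", "prob"),
    s("unemployment_aided_severe", "productivity.unemployment_aided.severe", "prob"),
    s("daily_gdp_per_capita", "productivity.daily_gdp_per_capita", "cost"),
    s("productivity_age_limit", "productivity.productivity_age_limit", "age")
  )
}

param_get <- function(p, path) {
  for (part in strsplit(path, ".", fixed = TRUE)[[1]]) p <- p[[part]]
  p
}

param_set <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(x, parts) {
    if (length(parts) == 1L) {
      x[[parts]] <- value
      return(x)
    }
    x[[parts[1L]]] <- set_rec(x[[parts[1L]]], parts[-1L])
    x
  }
  set_rec(p, parts)
}

param_set_key <- function(p, key, value) {
  sch <- param_schema()
  row <- sch[sch$key == key, ]
  if (nrow(row) != 1L) stop("unknown parameter key: ", key, call. = FALSE)
  param_set(p, row$path, value)
}

param_get_key <- function(p, key) {
  sch <- param_schema()
  row <- sch[sch$key == key, ]
  if (nrow(row) != 1L) stop("unknown parameter key: ", key, call. = FALSE)
  param_get(p, row$path)
}

#' Load model parameters from a configuration file
#'
#' Reads a flat YAML mapping of parameter overrides. Any key absent from the
#' file keeps its default value; unknown keys are rejected by name. The key
#' `utility_set` (`base_case`/`alternative`) switches the whole
#' utility-weight set before individual utility overrides are applied. The
#' returned object is guaranteed to pass [validate_parameters()].
#'
#' @param path Path to a YAML file of `key: value` pairs. See
#'   [param_keys()] for the accepted keys.
#' @param gender Default gender when the file does not set one.
#' @return A validated `ha_parameters` object.
#' @export
load_parameters <- function(path, gender = c("male", "female")) {
  gender <- match.arg(gender)
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("parameter file must be a flat key-value mapping", call. = FALSE)
  sch <- param_schema()
  unknown <- setdiff(names(raw), sch$key)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- default_parameters(gender)
  # apply set switch first so individual utility overrides win over the set
  if (!is.null(raw$utility_set)) {
    if (!raw$utility_set %in% c("base_case", "alternative")) {
      stop("utility_set must be 'base_case' or 'alternative'", call. = FALSE)
    }
    p$utilities <- utility_set(raw$utility_set)
    raw$utility_set <- NULL
  }
  if (!is.null(raw$gender)) {
    p$gender <- raw$gender
    raw$gender <- NULL
  }
  for (key in names(raw)) {
    row <- sch[sch$key == key, ]
    value <- raw[[key]]
    if (row$type != "enum") {
      if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
        stop("parameter '", key, "' must be a single number", call. = FALSE)
      }
      nm <- names(param_get(p, row$path))
      if (!is.null(nm)) value <- stats::setNames(value, nm)
    }
    p <- param_set(p, row$path, value)
  }
  violations <- validate_parameters(p)
  if (length(violations)) {
    stop("invalid parameters in ", path, ":\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  p
}

#' Write model parameters to a configuration file
#'
#' Serialises a parameter object to the same flat YAML mapping accepted by
#' [load_parameters()]; `load_parameters(write_parameters(p, f))` restores an
#' equal object.
#'
#' @param p An `ha_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  sch <- param_schema()
  out <- lapply(seq_len(nrow(sch)), function(i) unname(param_get(p, sch$path[i])))
  names(out) <- sch$key
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Accepted configuration keys
#'
#' @return A data frame with one row per configuration key: the flat `key`
#'   used in parameter files, the `path` inside the nested parameter list
#'   and the value `type` that drives bound checks.
#' @export
param_keys <- function() param_schema()

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations as data rather than raising: an empty character vector means
#' the set is valid. Each violation names the field, the offending value and
#' the rule broken.
#'
#' Rules include: probabilities, shares and utilities in \[0,1\]; aided
#' utility at least the unaided utility in every state; utilities
#' non-increasing with severity within the aided and unaided sets; uptake
#' probabilities for severe loss at least those for milder loss (care
#' seeking rises with severity); the falls odds ratio at least 1 and the
#' aided hazard ratio at most 1; falls incidence non-decreasing with age
#' band; aided unemployment below unaided; non-negative costs; a positive
#' willingness-to-pay threshold and a discount rate in \[0,1).
#'
#' @param p An `ha_parameters` object.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  bad <- function(field, value, rule) {
    sprintf("%s = %s violates: %s", field, paste(signif(value, 6), collapse = ","), rule)
  }
  eco <- p$economic
  if (!isTRUE(eco$wtp_per_qaly > 0)) v <- c(v, bad("wtp_per_qaly", eco$wtp_per_qaly, "wtp_per_qaly > 0"))
  if (!isTRUE(eco$annual_discount_rate >= 0 && eco$annual_discount_rate < 1))
    v <- c(v, bad("annual_discount_rate", eco$annual_discount_rate, "0 <= rate < 1"))
  if (!isTRUE(eco$start_age < eco$horizon_end_age))
    v <- c(v, bad("start_age/horizon_end_age", c(eco$start_age, eco$horizon_end_age), "start_age < horizon_end_age"))
  if (!isTRUE(eco$cycle_length == 1))
    v <- c(v, bad("cycle_length", eco$cycle_length, "cycle_length = 1 (annual cycles)"))

  pw <- p$pathway
  for (nm in c("completion", "prescription", "purchase", "compliance")) {
    x <- pw[[nm]]
    if (any(x < 0 | x > 1))
      v <- c(v, bad(paste0("p_", nm), x, "probability in [0,1]"))
  }
  for (nm in c("completion", "prescription", "purchase")) {
    x <- pw[[nm]]
    if (x[["severe"]] < max(x[["mild"]], x[["moderate"]]) - 1e-12)
      v <- c(v, bad(paste0("p_", nm), x, "severe >= milder severities"))
  }
  if (pw$pps_compliance_decrement < 0 || pw$pps_compliance_decrement > 1)
    v <- c(v, bad("pps_compliance_decrement", pw$pps_compliance_decrement, "decrement magnitude in [0,1]"))
  if (!pw$pps_decrement_mode %in% c("relative", "absolute"))
    v <- c(v, sprintf("pps_decrement_mode = %s violates: one of relative, absolute", pw$pps_decrement_mode))

  u <- p$utilities
  allu <- c(normal_hearing = u$normal_hearing, u$unaided, u$aided)
  if (any(allu < 0 | allu > 1)) v <- c(v, bad("utilities", allu, "utility in [0,1]"))
  for (sev in HL_SEVERITIES) {
    if (u$aided[[sev]] < u$unaided[[sev]] - 1e-12)
      v <- c(v, bad(paste0("utility_aided_", sev), c(u$aided[[sev]], u$unaided[[sev]]),
                    "aided utility >= unaided utility"))
  }
  if (is.unsorted(rev(unname(u$unaided)), strictly = FALSE))
    v <- c(v, bad("utility_unaided", u$unaided, "non-increasing with severity"))
  if (is.unsorted(rev(unname(u$aided)), strictly = FALSE))
    v <- c(v, bad("utility_aided", u$aided, "non-increasing with severity"))

  co <- p$costs
  euro_fields <- c("first_visit_public", "first_visit_private", "followup_public",
                   "followup_private", "device_private_price", "device_public_tariff",
                   "transport_per_visit", "femur_drg_tariff")
  for (nm in euro_fields) {
    if (co[[nm]] < 0) v <- c(v, bad(nm, co[[nm]], "euro amount >= 0"))
  }
  for (nm in c("public_visit_share", "mercato_sociale_share", "mercato_riconducibile_share")) {
    if (co[[nm]] < 0 || co[[nm]] > 1) v <- c(v, bad(nm, co[[nm]], "share in [0,1]"))
  }
  if (co$device_replacement_interval < 1)
    v <- c(v, bad("device_replacement_interval", co$device_replacement_interval, "interval >= 1 year"))
  if (!co$cost_mix_mode %in% COST_MIX_MODES)
    v <- c(v, sprintf("cost_mix_mode = %s violates: one of %s", co$cost_mix_mode,
                      paste(COST_MIX_MODES, collapse = ", ")))

  fl <- p$falls
  if (any(fl$baseline_incidence < 0 | fl$baseline_incidence > 1))
    v <- c(v, bad("falls_incidence", fl$baseline_incidence, "probability in [0,1]"))
  if (is.unsorted(unname(fl$baseline_incidence), strictly = FALSE))
    v <- c(v, bad("falls_incidence", fl$baseline_incidence, "non-decreasing with age band"))
  if (fl$or_unaided < 1) v <- c(v, bad("falls_or_unaided", fl$or_unaided, "or_unaided >= 1"))
  if (fl$hr_aided > 1 || fl$hr_aided <= 0) v <- c(v, bad("falls_hr_aided", fl$hr_aided, "0 < hr_aided <= 1"))

  pr <- p$productivity
  if (pr$annual_excess_occupational_cost < 0)
    v <- c(v, bad("annual_excess_occupational_cost", pr$annual_excess_occupational_cost, "euro amount >= 0"))
  if (pr$daily_gdp_per_capita < 0)
    v <- c(v, bad("daily_gdp_per_capita", pr$daily_gdp_per_capita, "euro amount >= 0"))
  for (sev in c("moderate", "severe")) {
    ua <- pr$unemployment_unaided[[sev]]; aa <- pr$unemployment_aided[[sev]]
    if (any(c(ua, aa) < 0 | c(ua, aa) > 1))
      v <- c(v, bad(paste0("unemployment_", sev), c(ua, aa), "probability in [0,1]"))
    if (aa >= ua)
      v <- c(v, bad(paste0("unemployment_aided_", sev), c(aa, ua), "aided unemployment < unaided unemployment"))
  }
  if (!isTRUE(pr$productivity_age_limit == 64))
    v <- c(v, bad("productivity_age_limit", pr$productivity_age_limit, "working-age cutoff = 64"))
  if (!p$gender %in% c("male", "female"))
    v <- c(v, sprintf("gender = %s violates: one of male, female", p$gender))
  v
}

#' @export
print.ha_parameters <- function(x, ...) {
  cat("Hearing-aid cost-utility model parameters (", x$gender, " cohort)\n", sep = "")
  cat("  horizon: ages ", x$economic$start_age, "-", x$economic$horizon_end_age,
      ", discount ", x$economic$annual_discount_rate,
      ", WTP ", x$economic$wtp_per_qaly, " EUR/QALY\n", sep = "")
  cat("  utility set: ", x$utilities$label,
      "; cost mix: ", x$costs$cost_mix_mode, "\n", sep = "")
  invisible(x)
}
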