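# One-way deterministic sensitivity analysis, probabilistic sensitivity
# analysis and the scenario grid over cost mixes and dropout/compliance
# assumptions.

DROPOUT_SCENARIOS <- c("current", "no_dropout_partial_compliance",
                       "no_dropout_full_compliance")

# numeric parameter keys eligible for sensitivity analysis: every
# probability, utility, unit cost and effect ratio; structural settings
# (ages, cycle length, replacement interval, WTP) and the market-share
# parameters unused by the base cost mix are excluded.
sa_keys <- function() {
  sch <- param_schema()
  keep <- sch$type %in% c("prob", "utility", "cost", "or", "hr", "rate")
  drop <- c("mercato_sociale_share", "mercato_riconducibile_share")
  sch$key[keep & !(sch$key %in% drop)]
}

# Largest feasible step from the (valid) base value toward `proposed` for a
# single key: the feasible set in one coordinate is an interval containing
# the base, so bisection on the step fraction finds its boundary.
feasible_extreme <- function(p, key, proposed) {
  ok <- function(value) length(validate_parameters(param_set_key(p, key, value))) == 0L
  if (ok(proposed)) return(proposed)
  base <- param_get_key(p, key)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ok(base + mid * (proposed - base))) lo <- mid else hi <- mid
  }
  base + lo * (proposed - base)
}

#' Default deterministic sensitivity-analysis specification
#'
#' Each eligible parameter is varied to plus/minus 20\% of its base value
#' (`span = 0.2`), clipped first to its scale (probabilities and utilities
#' to \[0,1\], the odds ratio to at least 1, the hazard ratio to at most 1,
#' costs to non-negative) and then to the joint validity constraints of the
#' parameter set (e.g. aided utility at least unaided), so every low/high
#' value passes [validate_parameters()].
#'
#' @param params Base `ha_parameters` object.
#' @param span Relative half-width of the variation range (default 0.2).
#' @param keys Parameter keys to vary (default: all eligible keys, see the
#'   `key` column of [param_keys()]).
#' @return Data frame with columns `parameter`, `base`, `low`, `high`.
#' @export
dsa_spec <- function(params, span = 0.2, keys = sa_keys()) {
  sch <- param_schema()
  rows <- lapply(keys, function(key) {
    type <- sch$type[sch$key == key]
    base <- param_get_key(params, key)
    lo <- base * (1 - span); hi <- base * (1 + span)
    clip <- switch(type,
      prob = , utility = function(x) min(max(x, 0), 1),
      or = function(x) max(x, 1),
      hr = function(x) min(x, 1),
      rate = function(x) min(max(x, 0), 1 - 1e-9),
      function(x) max(x, 0))
    lo <- feasible_extreme(params, key, clip(lo))
    hi <- feasible_extreme(params, key, clip(hi))
    data.frame(parameter = key, base = base, low = lo, high = hi)
  })
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full model twice per parameter, once at the lower and once
#' at the upper limit of its range with everything else at base, and
#' records the incremental net monetary benefit of the arm pair each time.
#'
#' @param params Base `ha_parameters` object.
#' @param tm Calibrated `ha_transition_model`.
#' @param lt `ha_life_table`.
#' @param spec Range specification as from [dsa_spec()] (the default).
#' @param intervention,comparator Arm pair to compare.
#' @return Object of class `ha_dsa`: data frame with columns `parameter`,
#'   `base`, `low`, `high`, `inmb_low`, `inmb_high`, `width`
#'   (`|inmb_high - inmb_low|`), plus attribute `inmb_base`.
#' @export
one_way_dsa <- function(params, tm, lt, spec = NULL,
                        intervention = "ha_plus_pps", comparator = "no_treatment") {
  v <- validate_parameters(params)
  if (length(v)) stop("invalid base parameters:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  if (is.null(spec)) spec <- dsa_spec(params)
  pair_inmb <- function(p) {
    a <- run_arm(p, tm, lt, intervention, validate = FALSE, trace = FALSE)
    b <- run_arm(p, tm, lt, comparator, validate = FALSE, trace = FALSE)
    compare_arms(a, b)$inmb
  }
  inmb_base <- pair_inmb(params)
  res <- lapply(seq_len(nrow(spec)), function(i) {
    key <- spec$parameter[i]
    vals <- vapply(c(spec$low[i], spec$high[i]), function(value) {
      cand <- param_set_key(params, key, value)
      if (length(validate_parameters(cand))) {
        warning("skipping infeasible perturbation of ", key, " = ", value, call. = FALSE)
        return(NA_real_)
      }
      pair_inmb(cand)
    }, numeric(1))
    data.frame(parameter = key, base = spec$base[i], low = spec$low[i],
               high = spec$high[i], inmb_low = vals[1], inmb_high = vals[2],
               width = abs(vals[2] - vals[1]))
  })
  out <- do.call(rbind, res)
  attr(out, "inmb_base") <- inmb_base
  class(out) <- c("ha_dsa", "data.frame")
  out
}

#' Tornado ordering of a one-way sensitivity analysis
#'
#' Sorts parameters by descending influence on the incremental net monetary
#' benefit (bar width `|inmb_high - inmb_low|`); ties are broken
#' alphabetically by parameter name, so the ordering is invariant to the
#' input row order.
#'
#' @param dsa Result of [one_way_dsa()].
#' @return The same data frame, rows reordered for a tornado diagram.
#' @export
tornado_order <- function(dsa) {
  stopifnot(nrow(dsa) >= 1L)
  out <- dsa[order(-dsa$width, dsa$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Distribution families for probabilistic draws: Beta for probabilities and
# utilities (moment-matched; SE = se_prob * mean), Gamma for unit costs
# (SE = se_cost * mean), log-normal around the point estimate for the
# odds/hazard ratios. Degenerate inputs (zero SE, mean at a bound) yield
# point masses.
psa_draw <- function(type, mean, se_prob, se_cost, sdlog) {
  if (type %in% c("prob", "utility")) {
    sd <- se_prob * mean
    if (sd <= 0 || mean <= 0 || mean >= 1) return(mean)
    v <- min(sd^2, 0.95 * mean * (1 - mean))  # keep Beta well defined
    nu <- mean * (1 - mean) / v - 1
    stats::rbeta(1, mean * nu, (1 - mean) * nu)
  } else if (type == "cost") {
    if (se_cost <= 0 || mean <= 0) return(mean)
    shape <- 1 / se_cost^2
    stats::rgamma(1, shape = shape, scale = mean / shape)
  } else if (type %in% c("or", "hr")) {
    if (sdlog <= 0) return(mean)
    stats::rlnorm(1, meanlog = log(mean), sdlog = sdlog)
  } else {
    mean
  }
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation over parameter uncertainty: each iteration draws
#' an independent joint parameter set (Beta for probabilities and
#' utilities, moment-matched to the mean with a default standard error of
#' 10\% of the mean; Gamma for unit costs with 20\%; log-normal for the
#' falls odds and hazard ratios), enforces joint validity by redrawing
#' invalid sets, runs both arms and records the incremental cost and QALY
#' pair. Fully reproducible for a fixed seed.
#'
#' @inheritParams one_way_dsa
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed for the random draws.
#' @param keys Parameter keys to draw (default: all probabilities,
#'   utilities, unit costs and the falls odds/hazard ratio; the discount
#'   rate is excluded).
#' @param se_prob,se_cost Standard errors as fractions of the mean for
#'   probability/utility and cost parameters.
#' @param sdlog Log-scale standard deviation for the ratio parameters.
#' @param max_redraws Abort after this many consecutive invalid joint draws
#'   (diagnostic for misconfigured distributions).
#' @return Object of class `ha_psa_result`: list with `draws` (data frame
#'   `iteration`, `delta_cost`, `delta_qaly`), `n`, `seed`, `wtp`,
#'   `intervention`, `comparator`, `spec` (the draw specification) and
#'   `spec_hash`.
#' @export
run_psa <- function(params, tm, lt, n = 1000, seed = 1,
                    intervention = "ha_plus_pps", comparator = "no_treatment",
                    keys = NULL, se_prob = 0.10, se_cost = 0.20, sdlog = 0.10,
                    max_redraws = 1000) {
  v <- validate_parameters(params)
  if (length(v)) stop("invalid base parameters:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  sch <- param_schema()
  if (is.null(keys)) {
    keep <- sch$type %in% c("prob", "utility", "cost", "or", "hr")
    drop <- c("mercato_sociale_share", "mercato_riconducibile_share")
    keys <- sch$key[keep & !(sch$key %in% drop)]
  }
  types <- sch$type[match(keys, sch$key)]
  paths <- sch$path[match(keys, sch$key)]
  means <- vapply(keys, function(k) param_get_key(params, k), numeric(1))
  set.seed(seed)
  draws <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("delta_cost", "delta_qaly")))
  for (it in seq_len(n)) {
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      if (attempts > max_redraws)
        stop("PSA aborted: ", max_redraws, " consecutive invalid joint draws; ",
             "check the draw specification", call. = FALSE)
      cand <- params
      for (j in seq_along(keys)) {
        cand <- param_set(cand, paths[j],
                          psa_draw(types[j], means[j], se_prob, se_cost, sdlog))
      }
      if (length(validate_parameters(cand)) == 0L) break
    }
    a <- run_arm(cand, tm, lt, intervention, validate = FALSE, trace = FALSE)
    b <- run_arm(cand, tm, lt, comparator, validate = FALSE, trace = FALSE)
    draws[it, ] <- c(a$mean_cost - b$mean_cost, a$mean_qaly - b$mean_qaly)
  }
  spec <- list(keys = keys, types = types, means = unname(means),
               se_prob = se_prob, se_cost = se_cost, sdlog = sdlog, n = n)
  structure(list(
    draws = data.frame(iteration = seq_len(n), delta_cost = draws[, 1],
                       delta_qaly = draws[, 2]),
    n = n, seed = seed, wtp = params$economic$wtp_per_qaly,
    intervention = intervention, comparator = comparator,
    spec = spec, spec_hash = spec_hash(spec)
  ), class = "ha_psa_result")
}

# stable content fingerprint of the draw specification (polynomial rolling
# checksum over the serialized object; identification only, not cryptographic)
spec_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%010d", as.integer(h))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which the intervention has positive incremental net monetary benefit
#' (`wtp * delta_qaly - delta_cost > 0`).
#'
#' @param psa An `ha_psa_result`.
#' @param wtp_grid Vector of willingness-to-pay thresholds (euro/QALY).
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "ha_psa_result"), nrow(psa$draws) > 0)
  probability <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = probability)
}

#' Export the cost-effectiveness plane scatter
#'
#' @param psa An `ha_psa_result`.
#' @param path Output CSV path (columns `iteration`, `delta_cost`,
#'   `delta_qaly`).
#' @return `path`, invisibly.
#' @export
write_ce_plane <- function(psa, path) {
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}

apply_dropout_scenario <- function(params, scenario = DROPOUT_SCENARIOS) {
  scenario <- match.arg(scenario)
  if (scenario == "current") return(params)
  ones <- stats::setNames(rep(1, 3), HL_SEVERITIES)
  params$pathway$completion <- ones
  params$pathway$prescription <- ones
  params$pathway$purchase <- ones
  if (scenario == "no_dropout_full_compliance") {
    params$pathway$compliance <- ones
    params$pathway$pps_compliance_decrement <- 0
  }
  params
}

#' Scenario grid over cost mixes and dropout/compliance assumptions
#'
#' Crosses the four device/visit supply assumptions (base public/private
#' mix, private market only, public tariff only, public supply at the
#' private price) with three uptake assumptions: the current dropout mix;
#' no dropout with current compliance (journey completion, prescription and
#' purchase probabilities set to 1); and no dropout with full compliance
#' (additionally compliance set to 1 in both treatment arms). Each cell
#' reports the incremental results of both treatment arms against no
#' treatment.
#'
#' @inheritParams one_way_dsa
#' @param cost_mixes,dropouts Subsets of the grid axes to run.
#' @return Data frame with one row per (cost mix, dropout scenario,
#'   arm pair): `delta_cost`, `delta_qaly`, `icur`, `icur_flag`, `inmb`.
#' @export
run_scenarios <- function(params, tm, lt, cost_mixes = COST_MIX_MODES,
                          dropouts = DROPOUT_SCENARIOS) {
  rows <- list()
  for (mix in cost_mixes) {
    for (drp in dropouts) {
      p <- apply_dropout_scenario(params, drp)
      p$costs$cost_mix_mode <- mix
      v <- validate_parameters(p)
      if (length(v)) stop("scenario (", mix, ", ", drp, ") invalid:\n  ",
                          paste(v, collapse = "\n  "), call. = FALSE)
      arms <- run_all_arms(p, tm, lt, validate = FALSE)
      for (intervention in c("ha_plus_pps", "ha_alone")) {
        cmp <- compare_arms(arms[[intervention]], arms$no_treatment)
        rows[[length(rows) + 1L]] <- data.frame(
          cost_mix = mix, dropout = drp,
          intervention = intervention, comparator = "no_treatment",
          delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
          icur = cmp$icur, icur_flag = cmp$icur_flag, inmb = cmp$inmb
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.ha_psa_result <- function(x, ...) {
  p_ce <- mean(x$wtp * x$draws$delta_qaly - x$draws$delta_cost > 0)
  cat(sprintf("PSA: %d iterations (seed %d), %s vs %s; P(cost-effective at %.0f EUR/QALY) = %.3f\n",
              x$n, x$seed, x$intervention, x$comparator, x$wtp, p_ce))
  invisible(x)
}
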