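# Pairwise economic comparison of strategy arms.

#' Incremental cost-utility ratio
#'
#' `delta_cost / delta_qaly` when the QALY difference is non-zero. Instead
#' of returning infinities, degenerate sign patterns are flagged:
#' `"dominant"` (cheaper and more effective), `"dominated"` (costlier and
#' less effective), `"undefined"` (no QALY difference). The ratio value is
#' still reported alongside the dominant/dominated flags; it is `NA` only
#' when undefined.
#'
#' @param delta_cost Incremental cost (euro), intervention minus comparator.
#' @param delta_qaly Incremental QALYs.
#' @return List with `value` (euro/QALY or `NA`) and `flag` (one of
#'   `"well_defined"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icur <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(value = NA_real_, flag = "undefined"))
  }
  value <- delta_cost / delta_qaly
  flag <- if (delta_cost < 0 && delta_qaly > 0) "dominant"
          else if (delta_cost > 0 && delta_qaly < 0) "dominated"
          else "well_defined"
  list(value = value, flag = flag)
}

#' Incremental net monetary benefit
#'
#' Incremental QALYs valued at the willingness-to-pay threshold, net of
#' incremental costs: `wtp * delta_qaly - delta_cost`.
#'
#' @param wtp Willingness-to-pay threshold (euro/QALY, >= 0).
#' @param delta_qaly Incremental QALYs.
#' @param delta_cost Incremental cost (euro).
#' @return Euro.
#' @export
inmb <- function(wtp, delta_qaly, delta_cost) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Compare two strategy arms
#'
#' Incremental discounted costs and QALYs of `a` (intervention) over `b`
#' (comparator), with the resulting ICUR and INMB. Both results must come
#' from the same cohort (gender) and the same willingness-to-pay setting.
#'
#' @param a,b `ha_arm_result` objects (intervention, comparator).
#' @param wtp Willingness-to-pay threshold; defaults to the threshold the
#'   arms were run with.
#' @return An object of class `ha_comparison`: list with `intervention`,
#'   `comparator`, `delta_cost`, `delta_qaly`, `icur`, `icur_flag`, `inmb`
#'   and `wtp`.
#' @export
compare_arms <- function(a, b, wtp = NULL) {
  stopifnot(inherits(a, "ha_arm_result"), inherits(b, "ha_arm_result"))
  if (!identical(a$gender, b$gender))
    stop("cannot compare arms run on different cohorts (gender mismatch)", call. = FALSE)
  if (is.null(wtp)) {
    if (!isTRUE(all.equal(a$wtp, b$wtp)))
      stop("arms were run with different WTP settings; pass wtp explicitly", call. = FALSE)
    wtp <- a$wtp
  }
  delta_cost <- a$mean_cost - b$mean_cost
  delta_qaly <- a$mean_qaly - b$mean_qaly
  ic <- icur(delta_cost, delta_qaly)
  structure(list(
    intervention = a$arm, comparator = b$arm, gender = a$gender,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icur = ic$value, icur_flag = ic$flag,
    inmb = inmb(wtp, delta_qaly, delta_cost), wtp = wtp
  ), class = "ha_comparison")
}

#' Pairwise comparison table for the three strategies
#'
#' Builds the standard base-case results layout: each treatment strategy's
#' discounted means and net monetary benefit, with the three pairwise
#' incremental blocks (with-service vs alone, with-service vs none, alone
#' vs none).
#'
#' @param arms Named list as returned by [run_all_arms()].
#' @param wtp Optional willingness-to-pay override; the NMB columns are
#'   recomputed at the effective threshold.
#' @return Data frame with one row per ordered arm pair: mean costs/QALYs/
#'   LYs and NMB of both arms plus incremental cost, QALYs, ICUR and INMB.
#' @export
comparison_table <- function(arms, wtp = NULL) {
  pairs <- list(c("ha_plus_pps", "ha_alone"),
                c("ha_plus_pps", "no_treatment"),
                c("ha_alone", "no_treatment"))
  rows <- lapply(pairs, function(pr) {
    cmp <- compare_arms(arms[[pr[1]]], arms[[pr[2]]], wtp = wtp)
    a <- arms[[pr[1]]]; b <- arms[[pr[2]]]
    data.frame(
      gender = a$gender, intervention = pr[1], comparator = pr[2],
      mean_cost_intervention = a$mean_cost, mean_cost_comparator = b$mean_cost,
      mean_ly_intervention = a$mean_ly, mean_ly_comparator = b$mean_ly,
      mean_qaly_intervention = a$mean_qaly, mean_qaly_comparator = b$mean_qaly,
      nmb_intervention = cmp$wtp * a$mean_qaly - a$mean_cost,
      nmb_comparator = cmp$wtp * b$mean_qaly - b$mean_cost,
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
      icur = cmp$icur, icur_flag = cmp$icur_flag, inmb = cmp$inmb,
      wtp = cmp$wtp
    )
  })
  do.call(rbind, rows)
}

#' @export
print.ha_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): dCost %.2f EUR, dQALY %.4f, ICUR %s, INMB %.2f EUR\n",
              x$intervention, x$comparator, x$gender, x$delta_cost, x$delta_qaly,
              if (x$icur_flag == "well_defined") sprintf("%.0f EUR/QALY", x$icur) else x$icur_flag,
              x$inmb))
  invisible(x)
}
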