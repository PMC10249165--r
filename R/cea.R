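#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes incremental cost, QALYs and life-years of a comparator strategy
#' relative to a reference (deltas are `comp - ref`; in the embedded
#' glottic-cancer analysis the reference is HYPOFRT and the comparator
#' CFRT, so Table-style rows read "CFRT relative to HYPOFRT"), the signed
#' ICERs per QALY and per life-year, the dominance class, and each
#' strategy's net monetary benefit at the configured willingness-to-pay.
#'
#' The ICER is reported signed even under dominance, with the dominance
#' flag alongside: a dominated comparison's ICER is not decision-relevant
#' on its own, but the signed value matches how such results are commonly
#' tabulated.
#'
#' @param ref,comp `cea_run` objects from identically configured models
#'   differing only in strategy.
#' @return A `cea_comparison` object.
#' @export
incremental_analysis <- function(ref, comp) {
  d_cost <- comp$total_cost - ref$total_cost
  d_qaly <- comp$total_qaly - ref$total_qaly
  d_lyg <- comp$total_lyg - ref$total_lyg
  dominance <- if (d_qaly > 0 && d_cost < 0) {
    "intervention_dominated"
  } else if (d_qaly < 0 && d_cost > 0) {
    "comparator_dominated"
  } else if (d_qaly == 0 && d_cost != 0) {
    if (d_cost > 0) "comparator_dominated" else "intervention_dominated"
  } else {
    "tradeoff"
  }
  wtp <- ref$model$wtp_qaly %||% 40000
  structure(
    list(
      reference = ref$strategy,
      comparator = comp$strategy,
      perspective = ref$perspective,
      ref = ref,
      comp = comp,
      delta_cost = d_cost,
      delta_qaly = d_qaly,
      delta_lyg = d_lyg,
      icer_qaly = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
      icer_lyg = if (d_lyg != 0) d_cost / d_lyg else NA_real_,
      icer_defined = d_qaly != 0,
      dominance = dominance,
      wtp_qaly = wtp,
      nmb_ref = nmb(ref, wtp),
      nmb_comp = nmb(comp, wtp)
    ),
    class = "cea_comparison"
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`, the monetary value of a strategy's health
#' output at a given willingness-to-pay threshold.
#'
#' @param run A `cea_run`.
#' @param wtp Willingness-to-pay (currency per unit effect), >= 0; may be a
#'   vector.
#' @param effect `"qaly"` (default) or `"lyg"`.
#' @return Numeric vector of NMB values, one per `wtp`.
#' @export
nmb <- function(run, wtp, effect = c("qaly", "lyg")) {
  stopifnot(all(wtp >= 0))
  effect <- match.arg(effect)
  eff <- if (effect == "qaly") run$total_qaly else run$total_lyg
  wtp * eff - run$total_cost
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(
    "<cea_comparison> ", x$comparator, " vs ", x$reference,
    " (", x$perspective, ")\n",
    sprintf(
      "  dCost %.2f  dQALY %.4f  dLYG %.4f\n  ICER %s/QALY, %s/LYG  [%s]\n",
      x$delta_cost, x$delta_qaly, x$delta_lyg,
      if (x$icer_defined) sprintf("%.2f", x$icer_qaly) else "undefined",
      if (!is.na(x$icer_lyg)) sprintf("%.2f", x$icer_lyg) else "undefined",
      x$dominance
    ),
    sep = ""
  )
  invisible(x)
}

#' @describeIn incremental_analysis Two-row tibble of per-strategy totals
#'   and NMB, in the layout of a base-case results table.
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cea_comparison <- function(x, ...) {
  tibble(
    strategy = c(x$reference, x$comparator),
    perspective = x$perspective,
    total_cost = c(x$ref$total_cost, x$comp$total_cost),
    total_qaly = c(x$ref$total_qaly, x$comp$total_qaly),
    total_lyg = c(x$ref$total_lyg, x$comp$total_lyg),
    incremental_cost = c(NA, x$delta_cost),
    incremental_qaly = c(NA, x$delta_qaly),
    incremental_lyg = c(NA, x$delta_lyg),
    icer_qaly = c(NA, x$icer_qaly),
    icer_lyg = c(NA, x$icer_lyg),
    nmb = c(x$nmb_ref, x$nmb_comp)
  )
}

#' @describeIn incremental_analysis One-row summary of the incremental
#'   results.
#' @exportS3Method generics::glance
glance.cea_comparison <- function(x, ...) {
  tibble(
    reference = x$reference,
    comparator = x$comparator,
    perspective = x$perspective,
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    delta_lyg = x$delta_lyg,
    icer_qaly = x$icer_qaly,
    icer_lyg = x$icer_lyg,
    dominance = x$dominance,
    wtp_qaly = x$wtp_qaly,
    nmb_reference = x$nmb_ref,
    nmb_comparator = x$nmb_comp
  )
}
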