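#' Default one-way sensitivity ranges
#'
#' Cost parameters (gamma-distributed in the PSA) are varied to 60% and
#' 140% of their base values; probabilities and utilities
#' (beta-distributed) to mean +/- 1.96 SD, clamped to `[0, 1]`. Time-indexed
#' vectors move jointly: every year is set to its own bound at once, so the
#' year-to-year shape is preserved.
#'
#' @param model A `cea_model` with populated `psa_specs`.
#' @return A tibble with one row per parameter: `parameter`, `source`
#'   (`"pct40"` or `"confidence_interval"`), and list-columns `base`,
#'   `low`, `high`.
#' @export
default_ranges <- function(model) {
  rows <- imap(model$psa_specs, function(spec, id) {
    base <- spec$mean
    if (spec$family == "gamma") {
      low <- 0.6 * base
      high <- 1.4 * base
      src <- "pct40"
    } else {
      low <- pmax(0, base - 1.96 * spec$sd)
      high <- pmin(1, base + 1.96 * spec$sd)
      src <- "confidence_interval"
    }
    tibble(
      parameter = id, source = src,
      base = list(base), low = list(low), high = list(high)
    )
  })
  list_rbind(unname(rows))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the two-strategy comparison with one parameter moved to its low
#' and high bounds, in one arm only or in both. Perturbed probabilities
#' that would push a row's explicit mass above 1 are clamped back onto the
#' simplex (with the event recorded) rather than erroring, so tornado runs
#' always complete.
#'
#' @param ref,comp `cea_model` objects for the reference and comparator
#'   strategies (same perspective).
#' @param parameter Parameter id (see [param_ids()]).
#' @param low,high Bound values (scalar or per-year vector matching the
#'   base).
#' @param arm Which arm to perturb: a strategy label, or `"both"`.
#' @return One-row tibble: `parameter`, `arm`, `icer_base`, `icer_low`,
#'   `icer_high`, `span`.
#' @export
one_way <- function(ref, comp, parameter, low, high, arm = "both") {
  perturb <- function(model, value) {
    if (arm == "both" || identical(arm, model$strategy)) {
      param_set(model, parameter, value)
    } else {
      model
    }
  }
  icer_at <- function(value) {
    cmp <- incremental_analysis(
      run_model(perturb(ref, value), clamp = TRUE),
      run_model(perturb(comp, value), clamp = TRUE)
    )
    cmp$icer_qaly
  }
  base <- incremental_analysis(run_model(ref), run_model(comp))$icer_qaly
  il <- icer_at(low)
  ih <- icer_at(high)
  tibble(
    parameter = parameter, arm = arm,
    icer_base = base, icer_low = il, icer_high = ih,
    span = abs(ih - il)
  )
}

#' Tornado analysis over all default ranges
#'
#' Runs [one_way()] for every parameter in each arm separately (matching
#' the convention of varying, e.g., "the initial cost of CFRT" on its own),
#' using each arm's own [default_ranges()], and ranks entries by descending
#' ICER span.
#'
#' @inheritParams one_way
#' @param ranges_ref,ranges_comp Range tables; computed from each model's
#'   `psa_specs` if not supplied.
#' @return A `tornado` tibble sorted by descending `span`.
#' @export
run_tornado <- function(ref, comp,
                        ranges_ref = default_ranges(ref),
                        ranges_comp = default_ranges(comp)) {
  entries <- list()
  for (side in list(list(m = ref, rg = ranges_ref),
                    list(m = comp, rg = ranges_comp))) {
    for (i in seq_len(nrow(side$rg))) {
      entries[[length(entries) + 1L]] <- one_way(
        ref, comp,
        parameter = side$rg$parameter[i],
        low = side$rg$low[[i]],
        high = side$rg$high[[i]],
        arm = side$m$strategy
      )
    }
  }
  out <- arrange(list_rbind(entries), desc(.data$span))
  class(out) <- c("tornado", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.tornado <- function(object, ...) {
  dat <- mutate(
    object,
    label = paste0(.data$parameter, " (", .data$arm, ")"),
    label = factor(.data$label, levels = rev(unique(.data$label)))
  )
  ggplot(dat) +
    geom_segment(aes(
      x = .data$icer_low, xend = .data$icer_high,
      y = .data$label, yend = .data$label
    ), linewidth = 3, colour = "steelblue") +
    geom_vline(
      aes(xintercept = .data$icer_base[1]), linetype = "dashed"
    ) +
    labs(x = "ICER (currency/QALY)", y = NULL, title = "One-way sensitivity")
}
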