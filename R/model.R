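#' Construct a Markov cost-effectiveness model definition
#'
#' A `cea_model` is a complete declarative description of one
#' strategy-perspective Markov cohort model: health states, time-indexed
#' transition probabilities, per-state yearly cost schedules, utilities,
#' discounting and horizon, plus the distributional assumptions used by the
#' probabilistic sensitivity analysis.
#'
#' Time-indexed quantities are vectors over years 1..K; beyond year K the
#' last value is carried forward (constant extension). Each quantity carries
#' a `clock`: `"model_time"` (indexed by cycle number) or `"time_in_state"`
#' (indexed by years since entering the state, implemented via tunnel
#' states, see [expand_states()]).
#'
#' Transitions not listed explicitly are covered by *residual rules*: for a
#' state with a residual rule, the probability mass left over after all
#' explicit outgoing transitions flows to `residual_to` (which may be the
#' state itself, i.e. "stay").
#'
#' @param strategy,perspective Labels for the treatment strategy and payer
#'   perspective (the embedded fixture uses `"HYPOFRT"`/`"CFRT"` and
#'   `"public"`/`"private"`).
#' @param states Data frame with columns `name`, `absorbing` (logical),
#'   `utility` (in `[0, 1]`; 0 for the dead state).
#' @param transitions Data frame with columns `from`, `to`, `clock`, and a
#'   list-column `probability` of per-year numeric vectors.
#' @param residual_rules Data frame with columns `from`, `residual_to`.
#' @param cost_schedules Data frame with columns `state`, `clock`, and a
#'   list-column `yearly_costs` (currency units per year).
#' @param initial_one_time_cost One-time cost applied undiscounted to the
#'   whole cohort at model entry (e.g. the radiotherapy course itself).
#' @param discount_rate Yearly discount rate (fraction, default 0.05).
#' @param horizon_cycles Number of cycles to simulate (default 15).
#' @param cycle_length_years Cycle length in years (default 1).
#' @param start_distribution Named vector of starting occupancy over states;
#'   defaults to all mass in the first state.
#' @param wtp_qaly,wtp_lyg Willingness-to-pay thresholds (currency per QALY
#'   and per life-year gained).
#' @param psa_specs Named list of distribution specifications, keyed by
#'   parameter id (see [param_ids()]); each element a list with `family`
#'   (`"beta"`, `"gamma"` or `"fixed"`), `mean` (scalar or per-year vector)
#'   and `sd`.
#' @param half_cycle_correction Average start- and end-of-cycle occupancy
#'   when accruing payoffs? Default `FALSE`.
#' @param discount_first_cycle If `FALSE` (default) cycle t is discounted by
#'   `(1+r)^-(t-1)`; if `TRUE`, by `(1+r)^-t`.
#' @param metadata Free-form list of annotations carried through
#'   serialization (e.g. static currency-conversion notes).
#'
#' @return An object of class `cea_model`.
#' @seealso [validate_model()], [read_model()], [esgc_model()]
#' @export
cea_model <- function(strategy,
                      perspective = "public",
                      states,
                      transitions,
                      residual_rules = NULL,
                      cost_schedules = NULL,
                      initial_one_time_cost = 0,
                      discount_rate = 0.05,
                      horizon_cycles = 15L,
                      cycle_length_years = 1,
                      start_distribution = NULL,
                      wtp_qaly = 40000,
                      wtp_lyg = 35000,
                      psa_specs = list(),
                      half_cycle_correction = FALSE,
                      discount_first_cycle = FALSE,
                      metadata = list()) {
  states <- as_tibble(states)
  transitions <- as_tibble(transitions)
  transitions$probability <- lapply(transitions$probability, as.numeric)
  residual_rules <- if (is.null(residual_rules)) {
    tibble(from = character(), residual_to = character())
  } else {
    as_tibble(residual_rules)
  }
  cost_schedules <- if (is.null(cost_schedules)) {
    tibble(state = character(), clock = character(), yearly_costs = list())
  } else {
    cs <- as_tibble(cost_schedules)
    cs$yearly_costs <- lapply(cs$yearly_costs, as.numeric)
    cs
  }
  if (is.null(start_distribution)) {
    start_distribution <- setNames(
      c(1, rep(0, nrow(states) - 1L)), states$name
    )
  }
  model <- structure(
    list(
      strategy = strategy,
      perspective = perspective,
      states = states,
      transitions = transitions,
      residual_rules = residual_rules,
      cost_schedules = cost_schedules,
      initial_one_time_cost = initial_one_time_cost,
      discount_rate = discount_rate,
      horizon_cycles = as.integer(horizon_cycles),
      cycle_length_years = cycle_length_years,
      start_distribution = start_distribution,
      wtp_qaly = wtp_qaly,
      wtp_lyg = wtp_lyg,
      psa_specs = psa_specs,
      half_cycle_correction = isTRUE(half_cycle_correction),
      discount_first_cycle = isTRUE(discount_first_cycle),
      metadata = metadata
    ),
    class = "cea_model"
  )
  validate_model(model)
}

#' Look up a time-indexed value with constant extension
#'
#' Year `t` beyond the last tabulated year returns the last value.
#'
#' @param values Numeric vector over years 1..K.
#' @param year Year index (>= 1), any length.
#' @return Numeric vector of the same length as `year`.
#' @export
time_value <- function(values, year) {
  stopifnot(length(values) >= 1L, all(year >= 1))
  values[pmin(as.integer(year), length(values))]
}

#' Validate a model definition
#'
#' Checks structural integrity (state references, unique absorbing state),
#' value ranges (probabilities and utilities in `[0, 1]`, non-negative
#' costs), probability-simplex closure (explicit outgoing mass must not
#' exceed 1 in any year, so every residual is non-negative), the start
#' distribution, and feasibility of the PSA distribution specifications.
#'
#' @param model A `cea_model`.
#' @return The model, invisibly usable in a pipe (returned unchanged).
#' @export
validate_model <- function(model) {
  st <- model$states
  fail <- function(...) abort(paste0(...), class = "fracCEA_validation_error")
  if (anyDuplicated(st$name)) fail("states: duplicated state names")
  if (sum(st$absorbing) != 1L) {
    fail("states: exactly one absorbing (dead) state is required")
  }
  dead <- st$name[st$absorbing]
  if (st$utility[st$absorbing] != 0) {
    fail("states[", dead, "]: absorbing state must have utility 0")
  }
  bad_u <- st$name[st$utility < 0 | st$utility > 1]
  if (length(bad_u)) {
    fail("states[", bad_u[1], "]: utility outside [0,1]")
  }
  refs <- c(
    model$transitions$from, model$transitions$to,
    model$residual_rules$from, model$residual_rules$residual_to,
    model$cost_schedules$state, names(model$start_distribution)
  )
  unknown <- setdiff(refs, st$name)
  if (length(unknown)) fail("unknown state referenced: ", unknown[1])
  if (any(model$transitions$from == dead)) {
    fail("transitions: the absorbing state cannot have outgoing transitions")
  }
  for (i in seq_len(nrow(model$transitions))) {
    p <- model$transitions$probability[[i]]
    key <- paste0(
      "transitions[", model$transitions$from[i], "->",
      model$transitions$to[i], "]"
    )
    if (length(p) < 1L) fail(key, ": empty probability vector")
    if (any(p < 0 | p > 1)) fail(key, ": probability outside [0,1]")
    if (!model$transitions$clock[i] %in% c("model_time", "time_in_state")) {
      fail(key, ": unknown clock '", model$transitions$clock[i], "'")
    }
  }
  for (i in seq_len(nrow(model$cost_schedules))) {
    cvec <- model$cost_schedules$yearly_costs[[i]]
    key <- paste0("cost_schedules[", model$cost_schedules$state[i], "]")
    if (any(cvec < 0)) fail(key, ": negative cost")
    if (!model$cost_schedules$clock[i] %in% c("model_time", "time_in_state")) {
      fail(key, ": unknown clock")
    }
  }
  # simplex closure: explicit outgoing mass <= 1 for every combination of
  # model year and time-in-state year that can co-occur
  ymax <- max(1L, vapply(model$transitions$probability, length, 1L))
  for (s in setdiff(st$name, dead)) {
    idx <- which(model$transitions$from == s)
    if (!length(idx)) next
    for (my in seq_len(ymax)) {
      for (ty in seq_len(ymax)) {
        tot <- sum(vapply(idx, function(i) {
          y <- if (model$transitions$clock[i] == "model_time") my else ty
          time_value(model$transitions$probability[[i]], y)
        }, 0))
        if (tot > 1 + 1e-9) {
          fail(
            "transitions[", s, "]: explicit outgoing probabilities sum to ",
            format(tot), " in year ", max(my, ty),
            " (negative residual probability)"
          )
        }
      }
    }
  }
  sd_tot <- sum(model$start_distribution)
  if (abs(sd_tot - 1) > 1e-9) {
    fail("start_distribution: sums to ", format(sd_tot), ", expected 1")
  }
  if (model$horizon_cycles < 1L) fail("horizon_cycles: must be >= 1")
  if (model$discount_rate < 0) fail("discount_rate: must be >= 0")
  for (id in names(model$psa_specs)) {
    spec <- model$psa_specs[[id]]
    if (!spec$family %in% c("beta", "gamma", "fixed")) {
      fail("psa_specs[", id, "]: unknown family '", spec$family, "'")
    }
    if (spec$sd < 0) fail("psa_specs[", id, "]: sd must be >= 0")
    if (spec$family == "beta" && any(spec$mean <= 0 | spec$mean >= 1)) {
      fail("psa_specs[", id, "]: beta mean must lie in (0,1)")
    }
    if (spec$family == "gamma" && any(spec$mean <= 0)) {
      fail("psa_specs[", id, "]: gamma mean must be > 0")
    }
  }
  invisible(model)
}

#' Resolve a transition probability at a given clock year
#'
#' Explicit transitions are looked up in their time-indexed vector with
#' constant extension beyond the last tabulated year; a transition covered
#' by a residual rule returns 1 minus the sum of the explicit outgoing
#' probabilities of `from` at that year.
#'
#' @param model A validated `cea_model`.
#' @param from,to State names.
#' @param year Clock year (>= 1); interpreted under the transition's own
#'   clock.
#' @return A single probability.
#' @export
resolve_probability <- function(model, from, to, year) {
  stopifnot(year >= 1)
  tr <- model$transitions
  hit <- which(tr$from == from & tr$to == to)
  if (length(hit)) {
    return(time_value(tr$probability[[hit[1]]], year))
  }
  rr <- model$residual_rules
  rhit <- which(rr$from == from & rr$residual_to == to)
  if (!length(rhit)) {
    abort(paste0("no transition or residual rule for ", from, " -> ", to))
  }
  idx <- which(tr$from == from)
  1 - sum(vapply(
    idx, function(i) time_value(tr$probability[[i]], year), 0
  ))
}

#' Read and write model definitions as JSON
#'
#' The on-disk format is plain JSON mirroring the `cea_model` fields;
#' `write_model()` followed by `read_model()` reproduces an equal model.
#'
#' @param path File path.
#' @param model A `cea_model`.
#' @return `read_model()` returns a validated `cea_model`; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  row_tbl <- function(rows, vec_fields = character()) {
    if (length(rows) == 0) return(NULL)
    list_rbind(map(rows, function(r) {
      for (f in vec_fields) r[[f]] <- list(as.numeric(r[[f]]))
      as_tibble(r)
    }))
  }
  cea_model(
    strategy = raw$strategy,
    perspective = raw$perspective,
    states = row_tbl(raw$states),
    transitions = row_tbl(raw$transitions, "probability"),
    residual_rules = row_tbl(raw$residual_rules),
    cost_schedules = row_tbl(raw$cost_schedules, "yearly_costs"),
    initial_one_time_cost = raw$initial_one_time_cost,
    discount_rate = raw$discount_rate,
    horizon_cycles = raw$horizon_cycles,
    cycle_length_years = raw$cycle_length_years,
    start_distribution = unlist(raw$start_distribution),
    wtp_qaly = raw$wtp_qaly,
    wtp_lyg = raw$wtp_lyg,
    psa_specs = map(raw$psa_specs, function(s) {
      list(family = s$family, mean = as.numeric(s$mean), sd = s$sd)
    }),
    half_cycle_correction = raw$half_cycle_correction,
    discount_first_cycle = raw$discount_first_cycle,
    metadata = raw$metadata %||% list()
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  row_list <- function(tb) {
    lapply(seq_len(nrow(tb)), function(i) {
      as.list(tb[i, ])
    })
  }
  out <- list(
    strategy = model$strategy,
    perspective = model$perspective,
    states = row_list(model$states),
    transitions = row_list(model$transitions),
    residual_rules = row_list(model$residual_rules),
    cost_schedules = row_list(model$cost_schedules),
    initial_one_time_cost = model$initial_one_time_cost,
    discount_rate = model$discount_rate,
    horizon_cycles = model$horizon_cycles,
    cycle_length_years = model$cycle_length_years,
    start_distribution = as.list(model$start_distribution),
    wtp_qaly = model$wtp_qaly,
    wtp_lyg = model$wtp_lyg,
    psa_specs = model$psa_specs,
    half_cycle_correction = model$half_cycle_correction,
    discount_first_cycle = model$discount_first_cycle,
    metadata = model$metadata
  )
  jsonlite::write_json(
    out, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' @export
print.cea_model <- function(x, ...) {
  cat(
    "<cea_model> ", x$strategy, " / ", x$perspective, "\n",
    "  states: ", paste(x$states$name, collapse = ", "), "\n",
    "  horizon: ", x$horizon_cycles, " cycles of ", x$cycle_length_years,
    " year(s); discount ", 100 * x$discount_rate, "%/yr\n",
    "  initial one-time cost: ", format(x$initial_one_time_cost), "\n",
    sep = ""
  )
  invisible(x)
}
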