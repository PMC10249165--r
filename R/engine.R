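#' Expand tunnel states
#'
#' States carrying any time-in-state-clocked quantity (transition
#' probability or cost schedule) are expanded into K tunnel copies, where K
#' is the longest time-in-state vector in the model; the K-th copy is
#' self-referential under "stay", so occupants beyond K years keep the
#' year-K values (constant extension). States whose quantities are all
#' clocked by model time remain single; the absorbing state is never
#' tunnelled.
#'
#' @param model A validated `cea_model`.
#' @return A tibble with one row per expanded state: `label`, `state` (base
#'   state), `tunnel` (year index, `NA` for untunnelled states),
#'   `absorbing`, `utility`; the tunnel length K is attached as attribute
#'   `"tunnel_length"`.
#' @export
expand_states <- function(model) {
  tis_tr <- model$transitions$from[model$transitions$clock == "time_in_state"]
  tis_cs <- model$cost_schedules$state[
    model$cost_schedules$clock == "time_in_state"
  ]
  tunnelled <- union(tis_tr, tis_cs)
  k_lens <- c(
    vapply(
      model$transitions$probability[model$transitions$clock == "time_in_state"],
      length, 1L
    ),
    vapply(
      model$cost_schedules$yearly_costs[
        model$cost_schedules$clock == "time_in_state"
      ],
      length, 1L
    )
  )
  k <- if (length(k_lens)) max(k_lens) else 1L
  label <- character()
  state <- character()
  tunnel <- integer()
  for (i in seq_len(nrow(model$states))) {
    nm <- model$states$name[i]
    if (nm %in% tunnelled && !model$states$absorbing[i]) {
      label <- c(label, if (k == 1L) nm else paste0(nm, "_", seq_len(k)))
      state <- c(state, rep(nm, k))
      tunnel <- c(tunnel, seq_len(k))
    } else {
      label <- c(label, nm)
      state <- c(state, nm)
      tunnel <- c(tunnel, NA_integer_)
    }
  }
  i <- match(state, model$states$name)
  out <- tibble(
    label = label, state = state, tunnel = tunnel,
    absorbing = model$states$absorbing[i],
    utility = model$states$utility[i]
  )
  attr(out, "tunnel_length") <- k
  out
}

#' Per-cycle transition matrix over the expanded state space
#'
#' Model-time-clocked probabilities are evaluated at `cycle`; tunnel copy j
#' of a state evaluates its time-in-state-clocked probabilities at year j
#' and routes its "stay" mass to copy `min(j + 1, K)`. Residual rules
#' receive whatever mass the explicit transitions leave. Rows whose sum
#' drifts from 1 by no more than 1e-9 are renormalized; larger violations
#' raise an error naming the state and cycle, unless `clamp = TRUE`, in
#' which case explicit mass above 1 is scaled back onto the simplex and the
#' event recorded in the `"clamp_events"` attribute (used by sensitivity
#' analyses so perturbed runs complete).
#'
#' @param model A validated `cea_model`.
#' @param cycle Cycle number (1-based).
#' @param space Expanded state space from [expand_states()]; computed if
#'   missing.
#' @param clamp Clamp infeasible rows instead of erroring?
#' @return A square row-stochastic matrix with dimnames from
#'   `space$label`.
#' @export
transition_matrix <- function(model, cycle, space = expand_states(model),
                              clamp = FALSE) {
  stopifnot(cycle >= 1)
  ns <- nrow(space)
  k <- attr(space, "tunnel_length") %||% 1L
  m <- matrix(0, ns, ns, dimnames = list(space$label, space$label))
  tr_from <- model$transitions$from
  tr_to <- model$transitions$to
  tr_clock <- model$transitions$clock
  tr_prob <- model$transitions$probability
  rr_from <- model$residual_rules$from
  rr_to <- model$residual_rules$residual_to
  clamp_state <- character()
  clamp_excess <- double()
  for (r in seq_len(ns)) {
    if (space$absorbing[r]) {
      m[r, r] <- 1
      next
    }
    s <- space$state[r]
    j <- space$tunnel[r]
    idx <- which(tr_from == s)
    p <- numeric(length(idx))
    for (q in seq_along(idx)) {
      i <- idx[q]
      y <- if (tr_clock[i] == "model_time") cycle else j
      v <- tr_prob[[i]]
      p[q] <- v[min(y, length(v))]
    }
    tot <- sum(p)
    if (tot > 1 + 1e-9) {
      if (!clamp) {
        abort(paste0(
          "infeasible row: explicit outgoing mass ", format(tot),
          " > 1 for state ", space$label[r], " at cycle ", cycle
        ), class = "fracCEA_infeasible_row")
      }
      clamp_state <- c(clamp_state, space$label[r])
      clamp_excess <- c(clamp_excess, tot - 1)
      p <- p / tot
      tot <- 1
    }
    stay_col <- if (is.na(j)) {
      r
    } else {
      which(space$state == s & space$tunnel == min(j + 1L, k))[1]
    }
    for (q in seq_along(idx)) {
      to <- tr_to[idx[q]]
      dcol <- if (to == s) stay_col else match(to, space$state)
      m[r, dcol] <- m[r, dcol] + p[q]
    }
    resid <- 1 - tot
    if (resid > 1e-12) {
      rr <- which(rr_from == s)
      if (!length(rr)) {
        abort(paste0(
          "state ", s, " leaves residual probability ", format(resid),
          " at cycle ", cycle, " but has no residual rule"
        ))
      }
      to <- rr_to[rr[1]]
      dcol <- if (to == s) stay_col else match(to, space$state)
      m[r, dcol] <- m[r, dcol] + resid
    }
    rs <- sum(m[r, ])
    if (abs(rs - 1) > 1e-9) {
      abort(paste0("row ", space$label[r], " sums to ", format(rs)))
    }
    m[r, ] <- m[r, ] / rs
  }
  attr(m, "clamp_events") <- if (length(clamp_state)) {
    data.frame(state = clamp_state, cycle = cycle, excess = clamp_excess)
  } else {
    NULL
  }
  m
}

# matrices for cycles 1..horizon, reusing the matrix once all
# model-time-clocked probabilities have passed their last tabulated year
cycle_matrices <- function(model, space, clamp = FALSE) {
  h <- model$horizon_cycles
  mt_lens <- vapply(
    model$transitions$probability[model$transitions$clock == "model_time"],
    length, 1L
  )
  l_mt <- if (length(mt_lens)) max(mt_lens) else 1L
  uniq <- min(h, l_mt)
  mats <- lapply(seq_len(uniq), function(t) {
    transition_matrix(model, t, space, clamp = clamp)
  })
  mats[seq_len(h)] <- mats[pmin(seq_len(h), uniq)]
  mats
}

collect_clamps <- function(mats) {
  ev <- Filter(Negate(is.null), lapply(mats, attr, "clamp_events"))
  if (length(ev)) {
    as_tibble(do.call(rbind, ev))
  } else {
    tibble(state = character(), cycle = integer(), excess = double())
  }
}

#' Run the cohort simulation
#'
#' Advances the start distribution through `horizon_cycles` per-cycle
#' transition matrices over the expanded state space. Row t of the trace is
#' the occupancy at the end of cycle t (row 0 is the start distribution).
#'
#' @inheritParams transition_matrix
#' @return A `cohort_trace` object: list with `trace` (matrix, rows 0..H),
#'   `space`, `clamp_events`, and the `model`.
#' @export
run_cohort <- function(model, clamp = FALSE, space = NULL) {
  if (is.null(space)) space <- expand_states(model)
  mats <- cycle_matrices(model, space, clamp = clamp)
  h <- model$horizon_cycles
  ns <- nrow(space)
  trace <- matrix(0, h + 1L, ns, dimnames = list(0:h, space$label))
  start <- numeric(ns)
  # start mass of a tunnelled state enters its first copy
  for (s in names(model$start_distribution)) {
    start[match(s, space$state)] <- model$start_distribution[[s]]
  }
  trace[1L, ] <- start
  for (t in seq_len(h)) {
    trace[t + 1L, ] <- trace[t, ] %*% mats[[t]]
  }
  structure(
    list(
      trace = trace, space = space,
      clamp_events = collect_clamps(mats), model = model
    ),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(
    "<cohort_trace> ", nrow(x$trace) - 1L, " cycles x ", ncol(x$trace),
    " expanded states (", x$model$strategy, "/", x$model$perspective, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn run_cohort Long-format tidy trace: one row per cycle and
#'   expanded state, with the base state and occupancy fraction.
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cohort_trace <- function(x, ...) {
  as_tibble(x$trace, rownames = "cycle") |>
    mutate(cycle = as.integer(.data$cycle)) |>
    pivot_longer(-"cycle", names_to = "label", values_to = "occupancy") |>
    left_join(
      select(x$space, "label", "state", "tunnel"),
      by = "label"
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_trace <- function(object, ...) {
  tidy(object) |>
    group_by(.data$cycle, .data$state) |>
    summarise(occupancy = sum(.data$occupancy), .groups = "drop") |>
    ggplot(aes(.data$cycle, .data$occupancy, colour = .data$state)) +
    geom_line() +
    labs(
      x = "cycle (years)", y = "cohort fraction",
      title = paste(object$model$strategy, object$model$perspective, sep = " / ")
    )
}

# per-expanded-state yearly costs for cycles 1..h (ns x h matrix)
cost_matrix <- function(model, space) {
  h <- model$horizon_cycles
  ns <- nrow(space)
  out <- matrix(0, ns, h)
  ci <- match(space$state, model$cost_schedules$state)
  for (i in seq_len(ns)) {
    if (is.na(ci[i])) next
    v <- model$cost_schedules$yearly_costs[[ci[i]]]
    if (model$cost_schedules$clock[ci[i]] == "model_time") {
      out[i, ] <- v[pmin(seq_len(h), length(v))]
    } else {
      out[i, ] <- v[min(space$tunnel[i], length(v))]
    }
  }
  out
}

#' Accumulate discounted costs, QALYs and life-years over a trace
#'
#' Cycle t (t = 1..H) accrues, over the occupancy at the start of the cycle
#' (or the average of start and end occupancy when the half-cycle
#' correction is enabled), the state's yearly cost at its clock year, the
#' state utility times the cycle length, and one cycle length of life-years
#' for alive states, each weighted by the discount factor
#' `(1+r)^-(t-1)` (or `(1+r)^-t` when `discount_first_cycle` is set). The
#' initial one-time cost is added undiscounted at entry.
#'
#' @param model A validated `cea_model`.
#' @param trace A `cohort_trace` from [run_cohort()] on the same model.
#' @return A `cea_run` object with totals (`total_cost`, `total_qaly`,
#'   `total_lyg`) and a per-cycle breakdown tibble.
#' @export
accumulate <- function(model, trace) {
  space <- trace$space
  h <- model$horizon_cycles
  r <- model$discount_rate
  cl <- model$cycle_length_years
  util <- space$utility
  alive <- as.numeric(!space$absorbing)
  costs <- cost_matrix(model, space)
  occ <- trace$trace[seq_len(h), , drop = FALSE]
  if (model$half_cycle_correction) {
    occ <- (occ + trace$trace[seq_len(h) + 1L, , drop = FALSE]) / 2
  }
  w <- (1 + r)^-((seq_len(h) - 1 + model$discount_first_cycle) * cl)
  cost_c <- w * rowSums(occ * t(costs))
  qaly_c <- w * as.numeric(occ %*% util) * cl
  lyg_c <- w * as.numeric(occ %*% alive) * cl
  rows <- tibble(
    cycle = seq_len(h), discount_weight = w,
    cost = cost_c, qaly = qaly_c, lyg = lyg_c
  )
  structure(
    list(
      strategy = model$strategy,
      perspective = model$perspective,
      total_cost = model$initial_one_time_cost + sum(cost_c),
      total_qaly = sum(qaly_c),
      total_lyg = sum(lyg_c),
      initial_one_time_cost = model$initial_one_time_cost,
      cycles = rows,
      clamp_events = trace$clamp_events,
      model = model
    ),
    class = "cea_run"
  )
}

#' Run a model end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accumulate()].
#'
#' @inheritParams transition_matrix
#' @return A `cea_run`.
#' @export
run_model <- function(model, clamp = FALSE, space = NULL) {
  accumulate(model, run_cohort(model, clamp = clamp, space = space))
}

#' @export
print.cea_run <- function(x, ...) {
  cat(
    "<cea_run> ", x$strategy, "/", x$perspective,
    sprintf(
      ": cost %.2f, QALY %.4f, LYG %.4f\n",
      x$total_cost, x$total_qaly, x$total_lyg
    ),
    sep = ""
  )
  invisible(x)
}

#' @describeIn accumulate Per-cycle discounted accrual tibble.
#' @param x A `cea_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cea_run <- function(x, ...) {
  mutate(x$cycles, strategy = x$strategy, perspective = x$perspective)
}

#' @describeIn accumulate One-row summary of the run totals.
#' @exportS3Method generics::glance
glance.cea_run <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    perspective = x$perspective,
    total_cost = x$total_cost,
    total_qaly = x$total_qaly,
    total_lyg = x$total_lyg,
    horizon_cycles = x$model$horizon_cycles,
    discount_rate = x$model$discount_rate
  )
}
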