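#' Generate a random valid model configuration
#'
#' Draws a random Markov cost-effectiveness model for property testing:
#' 2-5 transient states feeding forward (state i can move to any later
#' state or death), one absorbing dead state, row-stochastic time-indexed
#' transition vectors built by Dirichlet-style allocation (so the residual
#' "stay" probability is non-negative by construction), positive
#' gamma-scale costs, and utilities in `[0, 1]`. Roughly half the transient
#' states are clocked by time in state, exercising tunnel expansion.
#' Generated models pass [validate_model()] by construction and are
#' deterministic under `seed`.
#'
#' @param n_transient_states Number of transient states (2-5).
#' @param tunnel_length Length of time-indexed vectors (1-6).
#' @param seed Integer seed.
#' @param cost_scale Scale of yearly costs.
#' @param utility_range Range to draw utilities from.
#' @param horizon_cycles,discount_rate Passed to the model.
#' @return A validated `cea_model`.
#' @export
random_model <- function(n_transient_states = 3L, tunnel_length = 3L,
                         seed = 1L, cost_scale = 1000,
                         utility_range = c(0.3, 0.95),
                         horizon_cycles = 12L, discount_rate = 0.05) {
  stopifnot(
    n_transient_states >= 2L, n_transient_states <= 5L,
    tunnel_length >= 1L, tunnel_length <= 6L
  )
  set.seed(seed)
  nt <- n_transient_states
  k <- tunnel_length
  names_t <- paste0("state_", seq_len(nt))
  states <- tibble(
    name = c(names_t, "dead"),
    absorbing = c(rep(FALSE, nt), TRUE),
    utility = c(
      sort(runif(nt, utility_range[1], utility_range[2]), decreasing = TRUE),
      0
    )
  )
  clocks <- ifelse(runif(nt) < 0.5, "time_in_state", "model_time")
  tr_from <- character()
  tr_to <- character()
  tr_clock <- character()
  tr_p <- list()
  for (i in seq_len(nt)) {
    targets <- c(names_t[seq_len(nt)][-seq_len(i)], "dead")
    # per-year Dirichlet allocation over (stay, targets); stay is residual
    alloc <- vapply(seq_len(k), function(y) {
      g <- rgamma(length(targets) + 1L, shape = c(8, rep(1, length(targets))))
      (g / sum(g))[-1L]
    }, numeric(length(targets)))
    alloc <- matrix(alloc, nrow = length(targets))
    for (q in seq_along(targets)) {
      tr_from <- c(tr_from, names_t[i])
      tr_to <- c(tr_to, targets[q])
      tr_clock <- c(tr_clock, clocks[i])
      tr_p <- c(tr_p, list(round(alloc[q, ], 6)))
    }
  }
  transitions <- tibble(
    from = tr_from, to = tr_to, clock = tr_clock, probability = tr_p
  )
  residual_rules <- tibble(from = names_t, residual_to = names_t)
  cost_schedules <- tibble(
    state = names_t,
    clock = clocks,
    yearly_costs = map(seq_len(nt), ~ round(
      rgamma(k, shape = 2, scale = cost_scale / 2), 2
    ))
  )
  psa_specs <- list()
  for (i in seq_len(nt)) {
    cvec <- cost_schedules$yearly_costs[[i]]
    psa_specs[[paste0("cost:", names_t[i])]] <- list(
      family = "gamma", mean = cvec, sd = round(0.2 * mean(cvec) + 1, 2)
    )
    u <- states$utility[i]
    psa_specs[[paste0("utility:", names_t[i])]] <- list(
      family = "beta", mean = u, sd = round(0.3 * sqrt(u * (1 - u)), 4)
    )
  }
  for (i in seq_len(nrow(transitions))) {
    p <- transitions$probability[[i]]
    if (any(p <= 0) || any(p >= 1)) next
    psa_specs[[paste0("p:", transitions$from[i], ":", transitions$to[i])]] <-
      list(
        family = "beta", mean = p,
        sd = round(0.3 * min(sqrt(p * (1 - p))), 6)
      )
  }
  psa_specs[["initial_cost"]] <- list(
    family = "gamma", mean = round(rgamma(1, 4, scale = cost_scale), 2),
    sd = round(0.4 * cost_scale, 2)
  )
  cea_model(
    strategy = paste0("synthetic_", seed),
    perspective = "synthetic",
    states = states,
    transitions = transitions,
    residual_rules = residual_rules,
    cost_schedules = cost_schedules,
    initial_one_time_cost = psa_specs[["initial_cost"]]$mean,
    discount_rate = discount_rate,
    horizon_cycles = horizon_cycles,
    start_distribution = setNames(c(1, rep(0, nt)), states$name),
    psa_specs = psa_specs,
    metadata = list(generator = "random_model", seed = seed)
  )
}

#' Individual-level microsimulation of a model
#'
#' Simulates `n_patients` independent trajectories through the expanded
#' state space using the same per-cycle transition matrices as the cohort
#' engine, accruing the same discounted payoffs per patient, and
#' aggregates them. The per-patient mean is an unbiased estimator of the
#' cohort-model totals, which makes this an independent oracle for
#' validating the cohort engine: the two share only the model definition
#' and the matrix-builder contract, not the trace code path.
#'
#' @param model A validated `cea_model`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @return A `microsim_result`: tibble-backed list with per-payoff `mean`,
#'   `sd` and standard error (`se = sd / sqrt(n)`; `NA` when
#'   `n_patients = 1`), plus `n_patients` and `seed`.
#' @export
microsimulate <- function(model, n_patients, seed = 1L) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  space <- expand_states(model)
  mats <- cycle_matrices(model, space)
  ns <- nrow(space)
  h <- model$horizon_cycles
  r <- model$discount_rate
  cl <- model$cycle_length_years
  util <- space$utility
  alive <- as.numeric(!space$absorbing)
  cost_mat <- vapply(seq_len(h), function(t) {
    vapply(seq_len(ns), function(i) {
      ci <- match(space$state[i], model$cost_schedules$state)
      if (is.na(ci)) return(0)
      y <- if (model$cost_schedules$clock[ci] == "model_time") {
        t
      } else {
        space$tunnel[i]
      }
      time_value(model$cost_schedules$yearly_costs[[ci]], y)
    }, 0)
  }, numeric(ns))
  start_p <- setNames(rep(0, ns), space$label)
  for (s in names(model$start_distribution)) {
    start_p[match(s, space$state)] <- model$start_distribution[[s]]
  }
  state <- sample.int(ns, n_patients, replace = TRUE, prob = start_p)
  cost <- rep(model$initial_one_time_cost, n_patients)
  qaly <- numeric(n_patients)
  lyg <- numeric(n_patients)
  half <- model$half_cycle_correction
  for (t in seq_len(h)) {
    w <- (1 + r)^-((t - 1 + model$discount_first_cycle) * cl)
    m <- mats[[t]]
    nxt <- state
    for (i in unique(state)) {
      sel <- state == i
      nxt[sel] <- sample.int(ns, sum(sel), replace = TRUE, prob = m[i, ])
    }
    acc <- function(v) if (half) (v[state] + v[nxt]) / 2 else v[state]
    cost <- cost + w * acc(cost_mat[, t])
    qaly <- qaly + w * acc(util) * cl
    lyg <- lyg + w * acc(alive) * cl
    state <- nxt
  }
  summarise_payoff <- function(v, name) {
    tibble(
      payoff = name,
      mean = mean(v),
      sd = if (n_patients > 1) sd(v) else NA_real_,
      se = if (n_patients > 1) sd(v) / sqrt(n_patients) else NA_real_
    )
  }
  structure(
    list(
      summary = bind_rows(
        summarise_payoff(cost, "cost"),
        summarise_payoff(qaly, "qaly"),
        summarise_payoff(lyg, "lyg")
      ),
      n_patients = n_patients,
      seed = seed,
      strategy = model$strategy
    ),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> n = ", x$n_patients, " (", x$strategy, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn microsimulate Summary tibble (payoff, mean, sd, se).
#' @param x A `microsim_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.microsim_result <- function(x, ...) x$summary
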