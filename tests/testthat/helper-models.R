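# small models built in code for unit and property tests

# one alive state that never dies (dead present but unreachable)
immortal_model <- function(discount_rate = 0.05, horizon = 15L,
                           utility = 1, yearly_cost = 0) {
  cea_model(
    strategy = "immortal",
    perspective = "test",
    states = tibble::tibble(
      name = c("alive", "dead"),
      absorbing = c(FALSE, TRUE),
      utility = c(utility, 0)
    ),
    transitions = tibble::tibble(
      from = "alive", to = "dead", clock = "model_time",
      probability = list(0)
    ),
    residual_rules = tibble::tibble(from = "alive", residual_to = "alive"),
    cost_schedules = tibble::tibble(
      state = "alive", clock = "model_time", yearly_costs = list(yearly_cost)
    ),
    discount_rate = discount_rate,
    horizon_cycles = horizon,
    start_distribution = c(alive = 1, dead = 0)
  )
}

# deterministic: certain death after the first cycle
certain_death_model <- function(horizon = 5L, discount_rate = 0.05) {
  cea_model(
    strategy = "certain_death",
    perspective = "test",
    states = tibble::tibble(
      name = c("alive", "dead"),
      absorbing = c(FALSE, TRUE),
      utility = c(0.8, 0)
    ),
    transitions = tibble::tibble(
      from = "alive", to = "dead", clock = "model_time",
      probability = list(1)
    ),
    cost_schedules = tibble::tibble(
      state = "alive", clock = "model_time", yearly_costs = list(100)
    ),
    initial_one_time_cost = 50,
    discount_rate = discount_rate,
    horizon_cycles = horizon,
    start_distribution = c(alive = 1, dead = 0)
  )
}

# the same two-state decaying model expressed with a length-1
# time-in-state vector (tunnelled) and with a model_time clock
degenerate_tunnel_pair <- function() {
  base <- function(clock) {
    cea_model(
      strategy = paste0("clock_", clock),
      perspective = "test",
      states = tibble::tibble(
        name = c("a", "b", "dead"),
        absorbing = c(FALSE, FALSE, TRUE),
        utility = c(0.9, 0.5, 0)
      ),
      transitions = tibble::tibble(
        from = c("a", "b"), to = c("b", "dead"), clock = clock,
        probability = list(0.2, 0.3)
      ),
      residual_rules = tibble::tibble(
        from = c("a", "b"), residual_to = c("a", "b")
      ),
      cost_schedules = tibble::tibble(
        state = c("a", "b"), clock = clock, yearly_costs = list(10, 20)
      ),
      discount_rate = 0.05,
      horizon_cycles = 10L,
      start_distribution = c(a = 1, b = 0, dead = 0)
    )
  }
  list(tunnelled = base("time_in_state"), flat = base("model_time"))
}

fixture_pair <- function(perspective = "public") {
  list(
    ref = esgc_model("HYPOFRT", perspective),
    comp = esgc_model("CFRT", perspective)
  )
}
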