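# Canonical early-stage glottic cancer model inputs: yearly transition
# probabilities (derived from the Yamazaki trial control rates), EQ-5D/TTO
# utilities, and 2022 Brazilian reimbursement costs (SUS public table /
# CBHPM private table), with the sampling SDs used in sensitivity analyses.

.esgc <- list(
  stay_cd = list(
    HYPOFRT = list(mean = c(0.97, 0.96, 0.94, 0.94, 0.93), sd = 0.014),
    CFRT    = list(mean = c(0.94, 0.90, 0.85, 0.81, 0.77), sd = 0.07)
  ),
  cd_death = list(mean = 0.03, sd = 0.014),
  lf_df    = list(mean = c(0.008, 0.017, 0.026, 0.034, 0.043), sd = 0.013),
  lf_death = list(mean = c(0.025, 0.049, 0.073, 0.09, 0.12), sd = 0.037),
  df_death = list(mean = c(0.601893, 0.84, 0.93, 0.97, 0.99), sd = 0.14),
  utility = list(
    controlled_disease = list(mean = 0.85, sd = 0.017),
    local_failure      = list(mean = 0.57, sd = 0.060),
    distant_failure    = list(mean = 0.42, sd = 0.006)
  ),
  initial_cost = list(
    public  = list(mean = 4168.00, sd = 1667.2),
    private = list(mean = 37396.24, sd = 14958.49)
  ),
  state_costs = list(
    public = list(
      controlled_disease = list(
        mean = c(823.92, 707.16, 220.41, 220.41, 220.41), sd = 301.42
      ),
      local_failure = list(
        mean = c(1804.23, 707.16, 220.41, 220.41, 220.41), sd = 687.01
      ),
      distant_failure = list(
        mean = c(5400.76, 484.00, 220.41, 220.41, 220.41), sd = 2371.48
      )
    ),
    private = list(
      controlled_disease = list(
        mean = c(14611.79, 13919.07, 2897.68, 2897.68, 2897.68), sd = 6231.18
      ),
      local_failure = list(
        mean = c(20838.67, 13919.07, 2897.68, 2897.68, 2897.68), sd = 8300.39
      ),
      distant_failure = list(
        mean = c(24211.79, 13919.07, 2897.68, 2897.68, 2897.68), sd = 9573.99
      )
    )
  ),
  # static annotations only; conversions were made with an external
  # GDP-deflator/PPP tool and are never recomputed here
  usd = list(year = 2022, note = "R$ converted to US$ via CCEMG/PPP tool")
)

#' The embedded early-stage glottic cancer model
#'
#' Builds the complete canonical model for one strategy and payer
#' perspective: a four-state Markov model (controlled disease, local
#' failure, distant failure, dead) over 15 yearly cycles discounted at 5%.
#' Controlled-disease "stay" probabilities differ between the
#' hypofractionated (HYPOFRT) and conventionally fractionated (CFRT)
#' schedules; the local/distant-failure process and all utilities are
#' shared. Failure-state probabilities and costs are clocked by time in
#' state (tunnel states); controlled-disease quantities by model time
#' (the state is never re-entered, so the two clocks coincide).
#'
#' The controlled-disease to local-failure probability is not an input: it
#' is the residual 1 - P(stay) - P(background death), the only closure of
#' the probability simplex consistent with the model topology. Background
#' mortality (0.03/yr) applies in controlled disease only; the failure
#' states use their own all-cause death probabilities.
#'
#' @param strategy `"HYPOFRT"` or `"CFRT"`.
#' @param perspective `"public"` or `"private"` payer perspective.
#' @return A validated `cea_model`.
#' @export
esgc_model <- function(strategy = c("HYPOFRT", "CFRT"),
                         perspective = c("public", "private")) {
  strategy <- match.arg(strategy)
  perspective <- match.arg(perspective)
  e <- .esgc
  states <- tibble(
    name = c("controlled_disease", "local_failure", "distant_failure", "dead"),
    absorbing = c(FALSE, FALSE, FALSE, TRUE),
    utility = c(
      e$utility$controlled_disease$mean,
      e$utility$local_failure$mean,
      e$utility$distant_failure$mean,
      0
    )
  )
  transitions <- tibble(
    from = c("controlled_disease", "controlled_disease", "local_failure",
             "local_failure", "distant_failure"),
    to = c("controlled_disease", "dead", "distant_failure", "dead", "dead"),
    clock = c("model_time", "model_time", "time_in_state", "time_in_state",
              "time_in_state"),
    probability = list(
      e$stay_cd[[strategy]]$mean,
      e$cd_death$mean,
      e$lf_df$mean,
      e$lf_death$mean,
      e$df_death$mean
    )
  )
  residual_rules <- tibble(
    from = c("controlled_disease", "local_failure", "distant_failure"),
    residual_to = c("local_failure", "local_failure", "distant_failure")
  )
  sc <- e$state_costs[[perspective]]
  cost_schedules <- tibble(
    state = c("controlled_disease", "local_failure", "distant_failure"),
    clock = c("model_time", "time_in_state", "time_in_state"),
    yearly_costs = list(
      sc$controlled_disease$mean, sc$local_failure$mean,
      sc$distant_failure$mean
    )
  )
  psa_specs <- list(
    "initial_cost" = list(
      family = "gamma",
      mean = e$initial_cost[[perspective]]$mean,
      sd = e$initial_cost[[perspective]]$sd
    ),
    "cost:controlled_disease" = list(
      family = "gamma", mean = sc$controlled_disease$mean,
      sd = sc$controlled_disease$sd
    ),
    "cost:local_failure" = list(
      family = "gamma", mean = sc$local_failure$mean, sd = sc$local_failure$sd
    ),
    "cost:distant_failure" = list(
      family = "gamma", mean = sc$distant_failure$mean,
      sd = sc$distant_failure$sd
    ),
    "utility:controlled_disease" = list(
      family = "beta", mean = e$utility$controlled_disease$mean,
      sd = e$utility$controlled_disease$sd
    ),
    "utility:local_failure" = list(
      family = "beta", mean = e$utility$local_failure$mean,
      sd = e$utility$local_failure$sd
    ),
    "utility:distant_failure" = list(
      family = "beta", mean = e$utility$distant_failure$mean,
      sd = e$utility$distant_failure$sd
    ),
    "p:controlled_disease:controlled_disease" = list(
      family = "beta", mean = e$stay_cd[[strategy]]$mean,
      sd = e$stay_cd[[strategy]]$sd
    ),
    "p:controlled_disease:dead" = list(
      family = "beta", mean = e$cd_death$mean, sd = e$cd_death$sd
    ),
    "p:local_failure:distant_failure" = list(
      family = "beta", mean = e$lf_df$mean, sd = e$lf_df$sd
    ),
    "p:local_failure:dead" = list(
      family = "beta", mean = e$lf_death$mean, sd = e$lf_death$sd
    ),
    "p:distant_failure:dead" = list(
      family = "beta", mean = e$df_death$mean, sd = e$df_death$sd
    )
  )
  cea_model(
    strategy = strategy,
    perspective = perspective,
    states = states,
    transitions = transitions,
    residual_rules = residual_rules,
    cost_schedules = cost_schedules,
    initial_one_time_cost = e$initial_cost[[perspective]]$mean,
    discount_rate = 0.05,
    horizon_cycles = 15L,
    cycle_length_years = 1,
    start_distribution = c(
      controlled_disease = 1, local_failure = 0, distant_failure = 0, dead = 0
    ),
    wtp_qaly = 40000,
    wtp_lyg = 35000,
    psa_specs = psa_specs,
    metadata = list(currency = "BRL", usd_conversion = e$usd)
  )
}

#' Write the four canonical model configurations to disk
#'
#' One JSON file per strategy-perspective combination, named
#' `esgc_<strategy>_<perspective>.json`.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_fixture_models <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (s in c("HYPOFRT", "CFRT")) {
    for (p in c("public", "private")) {
      path <- file.path(dir, paste0("esgc_", s, "_", p, ".json"))
      write_model(esgc_model(s, p), path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
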