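test_that("tunnel expansion produces the expected state space", {
  m <- esgc_model("HYPOFRT", "public")
  sp <- expand_states(m)
  expect_equal(nrow(sp), 12L)
  expect_setequal(
    sp$label,
    c("controlled_disease", paste0("local_failure_", 1:5),
      paste0("distant_failure_", 1:5), "dead")
  )
  expect_equal(attr(sp, "tunnel_length"), 5L)
  # untunnelled model keeps its base space
  sp_flat <- expand_states(immortal_model())
  expect_equal(sp_flat$label, c("alive", "dead"))
})

test_that("transition matrices are row-stochastic with the expected rows", {
  cf <- esgc_model("CFRT", "public")
  sp <- expand_states(cf)
  for (cycle in c(1, 3, 7)) {
    tm <- transition_matrix(cf, cycle, sp)
    expect_true(all(abs(rowSums(tm) - 1) < 1e-12))
    expect_true(all(tm >= 0 & tm <= 1))
  }
  tm1 <- transition_matrix(cf, 1, sp)
  expect_equal(tm1["controlled_disease", "controlled_disease"], 0.94)
  expect_equal(tm1["controlled_disease", "local_failure_1"], 0.03)
  expect_equal(tm1["controlled_disease", "dead"], 0.03)
  # terminal tunnel copy is self-referential under stay
  expect_equal(tm1["distant_failure_5", "distant_failure_5"], 0.01)
  expect_equal(tm1["distant_failure_5", "dead"], 0.99)
  # tunnel copy j routes stay mass to copy j+1
  expect_equal(
    tm1["local_failure_2", "local_failure_3"], 1 - 0.017 - 0.049
  )
  expect_equal(tm1["local_failure_2", "distant_failure_1"], 0.017)
  # absorbing row is identity
  expect_equal(unname(tm1["dead", ]), c(rep(0, 11), 1))
})

test_that("infeasible explicit mass errors unless clamped", {
  m <- degenerate_tunnel_pair()$flat
  m$transitions$probability[[1]] <- 0.9
  m$transitions$probability[[2]] <- 1.3
  expect_error(transition_matrix(m, 1), class = "fracCEA_infeasible_row")
  tm <- transition_matrix(m, 1, clamp = TRUE)
  expect_equal(unname(tm["b", "dead"]), 1)
  expect_equal(attr(tm, "clamp_events")$state, "b")
})

test_that("cohort trace conserves mass and death is monotone", {
  for (m in list(esgc_model("HYPOFRT", "public"),
                 esgc_model("CFRT", "private"),
                 random_model(seed = 5L))) {
    tr <- run_cohort(m)
    expect_true(all(abs(rowSums(tr$trace) - 1) < 1e-9))
    dead_col <- tr$space$absorbing
    expect_true(all(diff(tr$trace[, dead_col]) >= -1e-12))
  }
  # single-step hand computation: background mortality only in year 1
  tr <- run_cohort(esgc_model("HYPOFRT", "public"))
  expect_equal(tr$trace["1", "dead"], 0.03)
  expect_equal(tr$trace["1", "controlled_disease"], 0.97)
})

test_that("a conserved immortal cohort accrues closed-form annuities", {
  m0 <- immortal_model(discount_rate = 0)
  r0 <- run_model(m0)
  expect_equal(r0$total_lyg, 15)
  expect_equal(r0$total_qaly, 15)
  tr <- run_cohort(m0)
  expect_true(all(tr$trace[, "alive"] == 1))

  m <- immortal_model(discount_rate = 0.05)
  r <- run_model(m)
  annuity_due <- sum(1.05^-(0:14))
  expect_equal(r$total_lyg, annuity_due, tolerance = 1e-12)
  expect_equal(r$total_qaly, annuity_due, tolerance = 1e-12)

  # discounting the first cycle shifts every weight by one year
  m2 <- m
  m2$discount_first_cycle <- TRUE
  r2 <- run_model(m2)
  expect_equal(r2$total_lyg, annuity_due / 1.05, tolerance = 1e-12)
})

test_that("zero discount recovers undiscounted sums exactly", {
  m <- esgc_model("CFRT", "public")
  m$discount_rate <- 0
  run <- run_model(m)
  tr <- run_cohort(m)
  alive <- as.numeric(!tr$space$absorbing)
  expect_equal(run$total_lyg, sum(tr$trace[1:15, ] %*% alive))
  expect_equal(
    run$total_qaly, sum(tr$trace[1:15, ] %*% tr$space$utility)
  )
})

test_that("QALYs never exceed life-years when utilities are <= 1", {
  for (seed in c(2L, 9L, 17L)) {
    run <- run_model(random_model(seed = seed))
    expect_lte(run$total_qaly, run$total_lyg + 1e-12)
    expect_gte(run$total_qaly, 0)
  }
})

test_that("raising background mortality weakly lowers QALYs and LYG", {
  m <- esgc_model("HYPOFRT", "public")
  base <- run_model(m)
  prev_q <- base$total_qaly
  prev_l <- base$total_lyg
  for (p_death in c(0.05, 0.1, 0.2)) {
    run <- run_model(param_set(m, "p:controlled_disease:dead", p_death),
                     clamp = TRUE)
    expect_lt(run$total_qaly, prev_q)
    expect_lt(run$total_lyg, prev_l)
    prev_q <- run$total_qaly
    prev_l <- run$total_lyg
  }
})

test_that("length-1 tunnels reproduce the untunnelled model exactly", {
  pair <- degenerate_tunnel_pair()
  rt <- run_model(pair$tunnelled)
  rf <- run_model(pair$flat)
  expect_equal(nrow(expand_states(pair$tunnelled)), 3L)
  expect_equal(rt$total_cost, rf$total_cost)
  expect_equal(rt$total_qaly, rf$total_qaly)
  expect_equal(rt$total_lyg, rf$total_lyg)
})

test_that("half-cycle correction averages start and end occupancy", {
  m <- certain_death_model(horizon = 1L, discount_rate = 0)
  full <- run_model(m)
  expect_equal(full$total_lyg, 1) # start-of-cycle accrual
  m$half_cycle_correction <- TRUE
  half <- run_model(m)
  expect_equal(half$total_lyg, 0.5)
  expect_equal(half$total_cost, 50 + 100 * 0.5)
})

test_that("tidy trace and glance totals are consistent with the run", {
  m <- esgc_model("HYPOFRT", "public")
  tr <- run_cohort(m)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16 * 12)
  occ1 <- td[td$cycle == 1 & td$label == "dead", ]$occupancy
  expect_equal(occ1, 0.03)
  g <- glance(run_model(m))
  expect_equal(g$total_cost, accumulate(m, tr)$total_cost)
})
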