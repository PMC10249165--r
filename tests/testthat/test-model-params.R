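test_that("embedded fixture reproduces the tabulated inputs", {
  hyp_pub <- esgc_model("HYPOFRT", "public")
  cf_pub <- esgc_model("CFRT", "public")
  hyp_priv <- esgc_model("HYPOFRT", "private")

  expect_equal(hyp_pub$initial_one_time_cost, 4168.00)
  expect_equal(hyp_priv$initial_one_time_cost, 37396.24)
  # initial radiotherapy reimbursement is schedule-independent
  expect_equal(hyp_pub$initial_one_time_cost, cf_pub$initial_one_time_cost)

  expect_equal(param_get(cf_pub, "p:controlled_disease:controlled_disease")[5],
               0.77)
  expect_equal(param_get(hyp_pub, "p:controlled_disease:controlled_disease"),
               c(0.97, 0.96, 0.94, 0.94, 0.93))
  expect_equal(param_get(hyp_pub, "utility:controlled_disease"), 0.85)
  expect_equal(param_get(hyp_pub, "cost:distant_failure")[1], 5400.76)
  expect_error(esgc_model("IMRT", "public"))
  expect_error(esgc_model("HYPOFRT", "out_of_pocket"))
})

test_that("residual rule closes the probability simplex", {
  cf <- esgc_model("CFRT", "public")
  hyp <- esgc_model("HYPOFRT", "public")
  # stay + background death + residual local failure = 1
  expect_equal(
    resolve_probability(cf, "controlled_disease", "local_failure", 5),
    1 - 0.77 - 0.03
  )
  expect_equal(
    resolve_probability(hyp, "controlled_disease", "local_failure", 1),
    0
  )
  # explicit + residual sums to exactly 1 for every state and year
  for (m in list(cf, hyp)) {
    for (s in c("controlled_disease", "local_failure", "distant_failure")) {
      to_res <- m$residual_rules$residual_to[m$residual_rules$from == s]
      for (y in 1:8) {
        expl <- sum(vapply(
          which(m$transitions$from == s),
          function(i) time_value(m$transitions$probability[[i]], y), 0
        ))
        expect_equal(
          expl + resolve_probability(m, s, to_res, y), 1,
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("probabilities extend constant beyond the tabulated years", {
  m <- esgc_model("HYPOFRT", "public")
  expect_equal(resolve_probability(m, "distant_failure", "dead", 9), 0.99)
  for (y in 5:30) {
    expect_equal(
      resolve_probability(m, "controlled_disease", "controlled_disease", y),
      0.93
    )
  }
  expect_equal(time_value(c(1, 2, 3), 100), 3)
})

test_that("validation rejects malformed models with named errors", {
  m <- esgc_model("HYPOFRT", "public")

  bad_u <- m
  bad_u$states$utility[1] <- 1.2
  expect_error(validate_model(bad_u), "utility outside",
               class = "fracCEA_validation_error")

  # each value is a valid probability but the year-2 mass is 1.01:
  # the error must name the year
  bad_p <- param_set(m, "p:controlled_disease:controlled_disease",
                     c(0.96, 0.98, 0.94, 0.94, 0.93))
  expect_error(validate_model(bad_p), "sum to 1.01 in year 2",
               class = "fracCEA_validation_error")
  bad_p2 <- param_set(m, "p:local_failure:dead",
                      c(0.025, 0.049, 0.073, 0.09, 0.99))
  expect_error(validate_model(bad_p2), "local_failure",
               class = "fracCEA_validation_error")

  bad_sd <- m
  bad_sd$start_distribution["dead"] <- 0.5
  expect_error(validate_model(bad_sd), "start_distribution")

  bad_state <- m
  bad_state$transitions$to[1] <- "remission"
  expect_error(validate_model(bad_state), "unknown state")
})

test_that("serialization round-trips every fixture and a random model", {
  models <- c(
    lapply(c("HYPOFRT", "CFRT"), function(s) {
      lapply(c("public", "private"), function(p) esgc_model(s, p))
    }) |> unlist(recursive = FALSE),
    list(random_model(seed = 11L))
  )
  for (m in models) {
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    write_model(m, p1)
    m2 <- read_model(p1)
    write_model(m2, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(m2$states, m$states)
    expect_equal(m2$transitions$probability, m$transitions$probability)
    expect_equal(m2$psa_specs, m$psa_specs)
    expect_equal(m2$start_distribution, m$start_distribution)
  }
  expect_error(read_model("/nonexistent/model.json"), "no such file")
})
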