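test_that("method-of-moments fits invert their source moments exactly", {
  b <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(b$alpha, 1, tolerance = 1e-9)
  expect_equal(b$beta, 1, tolerance = 1e-9)

  b2 <- beta_from_moments(0.85, 0.017)
  expect_equal(b2$alpha / (b2$alpha + b2$beta), 0.85, tolerance = 1e-12)
  fitted_var <- with(b2, alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)))
  expect_equal(sqrt(fitted_var), 0.017, tolerance = 1e-9)

  g <- gamma_from_moments(4168.00, 1667.2)
  expect_equal(g$shape, 6.25)
  expect_equal(g$scale, 666.88)
  expect_equal(g$shape * g$scale, 4168.00, tolerance = 1e-9)
  expect_equal(sqrt(g$shape) * g$scale, 1667.2, tolerance = 1e-9)

  # an SD of 40% of the mean always gives shape 1/0.4^2
  g2 <- gamma_from_moments(37396.24, 14958.49)
  expect_equal(g2$shape, 6.25, tolerance = 1e-6)
  # mean = sd is the exponential limit
  expect_equal(gamma_from_moments(7, 7)$shape, 1)

  # vectorised over a time-indexed mean
  bv <- beta_from_moments(c(0.2, 0.4, 0.6), 0.05)
  expect_equal(bv$alpha / (bv$alpha + bv$beta), c(0.2, 0.4, 0.6))
})

test_that("infeasible moments are rejected or clamped on request", {
  expect_error(beta_from_moments(0.5, 0.6), "infeasible",
               class = "fracCEA_moment_error")
  expect_error(gamma_from_moments(-1, 2))
  expect_error(gamma_from_moments(5, 0))
  # printed SD 0.14 exceeds the Bernoulli bound at mean 0.99
  clamped <- beta_from_moments(c(0.97, 0.99), 0.14, clamp_sd = TRUE)
  expect_equal(clamped$sd[1], 0.14)
  expect_lt(clamped$sd[2], sqrt(0.99 * 0.01))
})

test_that("shared-quantile draws preserve year ordering and determinism", {
  m <- esgc_model("CFRT", "public")
  set.seed(7)
  d1 <- draw_parameter_set(m)
  set.seed(7)
  d2 <- draw_parameter_set(m)
  expect_identical(attr(d1, "draws"), attr(d2, "draws"))
  # one shared quantile keeps the monotone failure process monotone across
  # the central quantile range ...
  for (id in c("p:local_failure:distant_failure", "p:local_failure:dead")) {
    spec <- m$psa_specs[[id]]
    fit <- beta_from_moments(spec$mean, spec$sd, clamp_sd = TRUE)
    for (u in seq(0.02, 0.98, by = 0.04)) {
      expect_true(all(diff(q_fitted(fit, u)) >= 0))
    }
  }
  # ... and produces far fewer ordering inversions than per-year draws
  inversions <- function(mode) {
    n_inv <- 0L
    set.seed(5)
    for (s in 1:200) {
      v <- attr(draw_parameter_set(m, sampling = mode),
                "draws")[["p:local_failure:dead"]]
      n_inv <- n_inv + any(diff(v) < 0)
    }
    n_inv
  }
  expect_lt(inversions("shared_quantile") + 20L, inversions("independent"))
  # degenerate SDs reproduce the base configuration
  m0 <- m
  for (id in names(m0$psa_specs)) m0$psa_specs[[id]]$sd <- 0
  d0 <- draw_parameter_set(m0)
  expect_equal(param_get(d0, "cost:local_failure"),
               param_get(m, "cost:local_failure"))
  expect_equal(param_get(d0, "p:controlled_disease:controlled_disease"),
               param_get(m, "p:controlled_disease:controlled_disease"))
})

test_that("sampled parameters reproduce their source moments", {
  spec <- esgc_model("HYPOFRT", "public")$psa_specs[["utility:controlled_disease"]]
  fit <- beta_from_moments(spec$mean, spec$sd)
  set.seed(123)
  draws <- q_fitted(fit, runif(10000))
  se <- 0.017 / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.85), 3 * se)
  expect_equal(sd(draws), 0.017, tolerance = 0.05)
})

test_that("PSA output is seed-reproducible and internally coherent", {
  pair <- fixture_pair("public")
  grid <- seq(0, 50000, by = 10000)
  p1 <- run_psa(pair$ref, pair$comp, n = 60, seed = 99, wtp_grid = grid)
  p2 <- run_psa(pair$ref, pair$comp, n = 60, seed = 99, wtp_grid = grid)
  expect_identical(p1$iterations, p2$iterations)
  expect_identical(p1$ceac, p2$ceac)
  expect_identical(p1$clamp_count, p2$clamp_count)

  # the two strategies' acceptability sums to 1 at every threshold
  tot <- dplyr::summarise(
    dplyr::group_by(p1$ceac, wtp), total = sum(probability)
  )
  expect_true(all(tot$total == 1))
  expect_true(all(p1$ceac$probability >= 0 & p1$ceac$probability <= 1))
  expect_equal(p1$n, 60)

  # mean NMB curves are linear combinations of the recorded iterations
  at <- function(tbl, l, s) tbl[tbl$wtp == l & tbl$strategy == s, ][[3]]
  expect_equal(
    at(p1$nmb_curves, 10000, "HYPOFRT"),
    mean(10000 * p1$iterations$ref_qaly - p1$iterations$ref_cost)
  )
})

test_that("a single-iteration CEAC is degenerate", {
  pair <- fixture_pair("public")
  p <- run_psa(pair$ref, pair$comp, n = 1, seed = 3,
               wtp_grid = c(0, 2000, 40000))
  expect_true(all(p$ceac$probability %in% c(0, 1)))
})

test_that("with vanishing parameter uncertainty the PSA collapses to base", {
  pair <- fixture_pair("public")
  shrink <- function(m) {
    for (id in names(m$psa_specs)) m$psa_specs[[id]]$sd <- 0
    m
  }
  base <- incremental_analysis(run_model(pair$ref), run_model(pair$comp))
  p <- run_psa(shrink(pair$ref), shrink(pair$comp), n = 5, seed = 1,
               wtp_grid = c(0, 2000))
  expect_equal(unique(p$iterations$delta_cost), base$delta_cost,
               tolerance = 1e-9)
  expect_equal(unique(p$iterations$delta_qaly), base$delta_qaly,
               tolerance = 1e-9)
})
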