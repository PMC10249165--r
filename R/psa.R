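#' Method-of-moments distribution fitting
#'
#' Fits a beta or gamma distribution whose analytic mean and SD equal the
#' supplied values exactly. For a time-indexed parameter vector, `mean` may
#' be a vector (one distribution per year, sharing the SD).
#'
#' For the beta family the moments are feasible only when
#' `sd^2 < mean * (1 - mean)` (the Bernoulli variance bound). With
#' `clamp_sd = TRUE` an infeasible SD is clamped per year to 99.9% of the
#' bound instead of erroring — used when sampling tabulated inputs whose
#' printed SD exceeds the bound in some years.
#'
#' @param mean Mean(s): in (0, 1) for beta, > 0 for gamma.
#' @param sd Standard deviation (> 0 for gamma, >= 0 for beta).
#' @param clamp_sd Clamp infeasible beta SDs instead of erroring?
#' @return A `fitted_distribution`: list with `family`, the shape
#'   parameters (`alpha`/`beta`, or `shape`/`scale`), and the source
#'   moments.
#' @export
beta_from_moments <- function(mean, sd, clamp_sd = FALSE) {
  stopifnot(all(mean > 0), all(mean < 1), sd >= 0)
  bound <- sqrt(mean * (1 - mean))
  sd_y <- rep(sd, length(mean))
  if (any(sd_y >= bound)) {
    if (!clamp_sd) {
      abort(paste0(
        "infeasible beta variance: sd ", format(sd),
        " >= sqrt(mean*(1-mean)) = ", format(min(bound)),
        "; clamp the SD below the Bernoulli bound"
      ), class = "fracCEA_moment_error")
    }
    sd_y <- pmin(sd_y, 0.999 * bound)
  }
  nu <- mean * (1 - mean) / sd_y^2 - 1
  structure(
    list(
      family = "beta", alpha = mean * nu, beta = (1 - mean) * nu,
      mean = mean, sd = sd_y
    ),
    class = "fitted_distribution"
  )
}

#' @rdname beta_from_moments
#' @export
gamma_from_moments <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  structure(
    list(
      family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
      mean = mean, sd = rep(sd, length(mean))
    ),
    class = "fitted_distribution"
  )
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat("<fitted_distribution> ", x$family, ", ", length(x$mean),
      " component(s)\n", sep = "")
  invisible(x)
}

#' Quantile function of a fitted distribution
#'
#' With a scalar quantile `u` and a per-year fitted vector, every year is
#' mapped through the same quantile (shared-quantile sampling), preserving
#' the year ordering of the base vector.
#'
#' @param dist A `fitted_distribution`.
#' @param u Quantile(s) in (0, 1): scalar, or one per year.
#' @return Numeric vector of sampled values, one per year.
#' @export
q_fitted <- function(dist, u) {
  switch(dist$family,
    beta = qbeta(u, dist$alpha, dist$beta),
    gamma = qgamma(u, shape = dist$shape, scale = dist$scale),
    abort(paste0("no quantile function for family ", dist$family))
  )
}

# fit the distribution declared in a psa spec (fixed / sd 0 -> NULL)
fit_spec <- function(spec) {
  if (spec$family == "fixed" || spec$sd == 0) return(NULL)
  switch(spec$family,
    beta = beta_from_moments(spec$mean, spec$sd, clamp_sd = TRUE),
    gamma = gamma_from_moments(spec$mean, spec$sd)
  )
}

#' Draw one perturbed parameter set
#'
#' Every parameter with a PSA distribution specification is replaced by a
#' draw from its method-of-moments distribution. Under the default
#' shared-quantile sampling, a time-indexed vector uses a single uniform
#' draw mapped through each year's distribution, so the clinically
#' monotone year-to-year ordering is preserved; `sampling = "independent"`
#' draws each year separately. Draws that break the probability simplex
#' are clamped at run time (see [transition_matrix()]).
#'
#' @param model A `cea_model`.
#' @param u Optional named list of pre-drawn uniforms (one scalar per
#'   parameter, or one per year under independent sampling); drawn from
#'   the session RNG when `NULL`.
#' @param sampling `"shared_quantile"` (default) or `"independent"`.
#' @return The perturbed `cea_model`; the realised draws are attached as
#'   attribute `"draws"`.
#' @export
draw_parameter_set <- function(model, u = NULL,
                               sampling = c("shared_quantile", "independent")) {
  sampling <- match.arg(sampling)
  draws <- list()
  for (id in names(model$psa_specs)) {
    spec <- model$psa_specs[[id]]
    dist <- fit_spec(spec)
    if (is.null(dist)) {
      draws[[id]] <- spec$mean
      next
    }
    ui <- u[[id]] %||% if (sampling == "shared_quantile") {
      runif(1)
    } else {
      runif(length(spec$mean))
    }
    val <- q_fitted(dist, ui)
    draws[[id]] <- val
    model <- param_set(model, id, val)
  }
  attr(model, "draws") <- draws
  model
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over joint parameter draws: each iteration draws one
#' parameter set (parameters shared between the strategies — utilities,
#' failure-process probabilities, state costs, the initial cost — use the
#' same draw in both arms; strategy-specific parameters draw
#' independently), re-runs both cohort models, and records per-strategy
#' discounted cost, QALYs and life-years. From the iterations it derives
#' the cost-effectiveness acceptability curve (CEAC: the fraction of
#' iterations in which each strategy has the highest net monetary benefit)
#' and mean-NMB curves over a willingness-to-pay grid.
#'
#' @param ref,comp `cea_model` objects (reference and comparator).
#' @param n Number of Monte Carlo iterations (the canonical analysis uses
#'   10,000).
#' @param seed Integer seed; the run is reproducible byte-for-byte.
#' @param wtp_grid Willingness-to-pay grid (currency/QALY); the default
#'   covers 0 to 50,000 in steps of 500.
#' @param sampling Passed to [draw_parameter_set()].
#' @return A `psa_result`: list with `iterations` (tibble), `ceac`,
#'   `nmb_curves`, `n`, `seed`, `wtp_grid`, `sampling`, `clamp_count`.
#' @export
run_psa <- function(ref, comp, n = 10000, seed = 1L,
                    wtp_grid = seq(0, 50000, by = 500),
                    sampling = c("shared_quantile", "independent")) {
  stopifnot(n >= 1)
  sampling <- match.arg(sampling)
  set.seed(seed)
  space_ref <- expand_states(ref)
  space_comp <- expand_states(comp)
  # distribution fits and the shared-parameter set are draw-invariant
  fits_ref <- map(ref$psa_specs, fit_spec)
  fits_comp <- map(comp$psa_specs, fit_spec)
  shared <- intersect(names(ref$psa_specs), names(comp$psa_specs))
  shared <- shared[vapply(
    shared,
    function(id) identical(ref$psa_specs[[id]], comp$psa_specs[[id]]),
    TRUE
  )]
  apply_draws <- function(model, fits, u) {
    for (id in names(fits)) {
      if (is.null(fits[[id]])) next
      model <- param_set(model, id, q_fitted(fits[[id]], u[[id]]))
    }
    model
  }
  res <- matrix(0, n, 6L)
  clamp_count <- 0L
  for (it in seq_len(n)) {
    u_ref <- list()
    u_comp <- list()
    for (id in union(names(ref$psa_specs), names(comp$psa_specs))) {
      nu <- function(m) {
        if (sampling == "shared_quantile") 1L else length(m$psa_specs[[id]]$mean)
      }
      if (id %in% shared) {
        uu <- runif(nu(ref))
        u_ref[[id]] <- uu
        u_comp[[id]] <- uu
      } else {
        if (id %in% names(ref$psa_specs)) u_ref[[id]] <- runif(nu(ref))
        if (id %in% names(comp$psa_specs)) u_comp[[id]] <- runif(nu(comp))
      }
    }
    r_ref <- run_model(apply_draws(ref, fits_ref, u_ref),
                       clamp = TRUE, space = space_ref)
    r_comp <- run_model(apply_draws(comp, fits_comp, u_comp),
                        clamp = TRUE, space = space_comp)
    clamp_count <- clamp_count +
      nrow(r_ref$clamp_events) + nrow(r_comp$clamp_events)
    res[it, ] <- c(
      r_ref$total_cost, r_ref$total_qaly, r_ref$total_lyg,
      r_comp$total_cost, r_comp$total_qaly, r_comp$total_lyg
    )
  }
  iterations <- tibble(
    iteration = seq_len(n),
    ref_cost = res[, 1], ref_qaly = res[, 2], ref_lyg = res[, 3],
    comp_cost = res[, 4], comp_qaly = res[, 5], comp_lyg = res[, 6],
    delta_cost = res[, 4] - res[, 1],
    delta_qaly = res[, 5] - res[, 2]
  )
  ceac <- list_rbind(map(wtp_grid, function(l) {
    nmb_ref <- l * iterations$ref_qaly - iterations$ref_cost
    nmb_comp <- l * iterations$comp_qaly - iterations$comp_cost
    p_ref <- mean(nmb_ref >= nmb_comp)
    tibble(
      wtp = l,
      strategy = c(ref$strategy, comp$strategy),
      probability = c(p_ref, 1 - p_ref)
    )
  }))
  nmb_curves <- list_rbind(map(wtp_grid, function(l) {
    tibble(
      wtp = l,
      strategy = c(ref$strategy, comp$strategy),
      mean_nmb = c(
        mean(l * iterations$ref_qaly - iterations$ref_cost),
        mean(l * iterations$comp_qaly - iterations$comp_cost)
      )
    )
  }))
  structure(
    list(
      reference = ref$strategy,
      comparator = comp$strategy,
      perspective = ref$perspective,
      iterations = iterations,
      ceac = ceac,
      nmb_curves = nmb_curves,
      n = n, seed = seed, wtp_grid = wtp_grid,
      sampling = sampling, clamp_count = clamp_count
    ),
    class = "psa_result"
  )
}

#' Probability a strategy is cost-effective at a threshold
#'
#' Reads the CEAC of a [run_psa()] result at the willingness-to-pay value
#' closest to `wtp`.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold.
#' @param strategy Strategy label; defaults to the reference.
#' @return A probability in `[0, 1]`.
#' @export
ceac_at <- function(psa, wtp, strategy = psa$reference) {
  sub <- filter(psa$ceac, .data$strategy == !!strategy)
  sub$probability[which.min(abs(sub$wtp - wtp))]
}

#' @export
print.psa_result <- function(x, ...) {
  cat(
    "<psa_result> ", x$comparator, " vs ", x$reference, " (", x$perspective,
    "), n = ", x$n, ", seed = ", x$seed, "\n",
    "  P(", x$reference, " cost-effective) at max WTP: ",
    format(ceac_at(x, max(x$wtp_grid))), "\n",
    "  simplex clamp events: ", x$clamp_count, "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn run_psa Per-iteration tibble of strategy totals and deltas.
#' @param x A `psa_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.psa_result <- function(x, ...) x$iterations

#' @describeIn run_psa One-row summary: mean deltas, CEAC at the grid ends.
#' @exportS3Method generics::glance
glance.psa_result <- function(x, ...) {
  tibble(
    reference = x$reference,
    comparator = x$comparator,
    perspective = x$perspective,
    n = x$n,
    seed = x$seed,
    mean_delta_cost = mean(x$iterations$delta_cost),
    mean_delta_qaly = mean(x$iterations$delta_qaly),
    clamp_count = x$clamp_count
  )
}

#' Plot a PSA result
#'
#' @param object A `psa_result`.
#' @param type `"plane"` (incremental cost-effectiveness plane), `"ceac"`,
#'   or `"nmb"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psa_result <- function(object, type = c("plane", "ceac", "nmb"),
                                ...) {
  type <- match.arg(type)
  switch(type,
    plane = ggplot(object$iterations, aes(-.data$delta_qaly, -.data$delta_cost)) +
      geom_point(alpha = 0.2, size = 0.5) +
      geom_hline(yintercept = 0) + geom_vline(xintercept = 0) +
      labs(
        x = paste("incremental QALY,", object$reference, "vs", object$comparator),
        y = "incremental cost"
      ),
    ceac = ggplot(object$ceac, aes(.data$wtp, .data$probability,
                                   colour = .data$strategy)) +
      geom_line() +
      scale_y_continuous(limits = c(0, 1)) +
      labs(x = "willingness-to-pay (per QALY)",
           y = "P(highest net monetary benefit)"),
    nmb = ggplot(object$nmb_curves, aes(.data$wtp, .data$mean_nmb,
                                        colour = .data$strategy)) +
      geom_line() +
      labs(x = "willingness-to-pay (per QALY)", y = "mean net monetary benefit")
  )
}
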