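#' Write analysis outputs to disk
#'
#' Plain CSV/JSON writers for every result type, used by the command-line
#' wrapper and convenient for archiving runs: `write_trace()` (long-format
#' cohort trace), `write_totals()` (run totals as JSON),
#' `write_summary()` (incremental comparison, dominance, and an NMB grid),
#' `write_tornado()` (sorted one-way sensitivity table), and
#' `write_psa_outputs()` (per-iteration samples, CEAC, and NMB curves).
#'
#' @param trace A `cohort_trace`.
#' @param path,dir Output file path / directory.
#' @return The path(s) written, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    select(tidy(trace), cycle = "cycle", expanded_state = "label",
           occupancy = "occupancy"),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname writers
#' @param run A `cea_run`.
#' @export
write_totals <- function(run, path) {
  jsonlite::write_json(
    list(
      strategy = run$strategy,
      perspective = run$perspective,
      total_cost = run$total_cost,
      total_qaly = run$total_qaly,
      total_lyg = run$total_lyg,
      initial_one_time_cost = run$initial_one_time_cost
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname writers
#' @param comparison A `cea_comparison`.
#' @param wtp_grid Willingness-to-pay grid for the NMB block.
#' @export
write_summary <- function(comparison, path,
                          wtp_grid = seq(0, 50000, by = 500)) {
  g <- glance(comparison)
  out <- c(
    as.list(g),
    list(
      totals = tidy(comparison),
      nmb_grid = tibble(
        wtp = wtp_grid,
        nmb_reference = nmb(comparison$ref, wtp_grid),
        nmb_comparator = nmb(comparison$comp, wtp_grid)
      )
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname writers
#' @param tornado A `tornado` tibble from [run_tornado()].
#' @export
write_tornado <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param psa A `psa_result`.
#' @export
write_psa_outputs <- function(psa, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- bind_rows(
    tibble(
      iteration = psa$iterations$iteration, strategy = psa$reference,
      cost = psa$iterations$ref_cost, qaly = psa$iterations$ref_qaly
    ),
    tibble(
      iteration = psa$iterations$iteration, strategy = psa$comparator,
      cost = psa$iterations$comp_cost, qaly = psa$iterations$comp_qaly
    )
  )
  p1 <- file.path(dir, "psa_samples.csv")
  utils::write.csv(samples, p1, row.names = FALSE)
  ceac_wide <- tidyr::pivot_wider(
    psa$ceac,
    names_from = "strategy", values_from = "probability",
    names_prefix = "p_"
  )
  p2 <- file.path(dir, "ceac.csv")
  utils::write.csv(ceac_wide, p2, row.names = FALSE)
  nmb_wide <- tidyr::pivot_wider(
    psa$nmb_curves,
    names_from = "strategy", values_from = "mean_nmb",
    names_prefix = "nmb_"
  )
  p3 <- file.path(dir, "nmb.csv")
  utils::write.csv(nmb_wide, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Write a run manifest
#'
#' Records, next to any written output, what produced it: subcommand,
#' configuration paths, seed, convention toggles, package version and
#' timestamp. Re-running the subcommand with the same manifest settings
#' reproduces identical outputs.
#'
#' @param path Output path for `manifest.json`.
#' @param subcommand Name of the operation.
#' @param config_paths Character vector of input configuration paths.
#' @param seed Integer seed (or `NA` for deterministic operations).
#' @param toggles Named list of convention toggles in effect.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, config_paths = character(),
                           seed = NA_integer_, toggles = list()) {
  jsonlite::write_json(
    list(
      subcommand = subcommand,
      config_paths = config_paths,
      seed = seed,
      toggles = toggles,
      package = "fracCEA",
      version = as.character(utils::packageVersion("fracCEA")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, null = "null", na = "null"
  )
  invisible(path)
}
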