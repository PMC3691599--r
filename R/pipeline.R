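#' Configure a full analysis run
#'
#' Bundles every knob of the generate - fit - classify - correlate -
#' simulate - growth pipeline under a single root seed, so that a run
#' is a pure function of its configuration. Per-stage seeds are derived
#' deterministically from the root seed.
#'
#' @param seed Root integer seed.
#' @param panel A [panel_config()]; its seed is overridden by the
#'   derived panel seed.
#' @param thresholds [run_thresholds()].
#' @param quantities Quantities entering the correlation screen.
#' @param ode_modes Model modes to simulate (see [ode_parameters()]).
#' @param ode_pre_days,ode_treat_days,ode_post_days,ode_t_step Scenario
#'   timing for [simulate_treatment_response()].
#' @param growth_g,growth_d Named per-condition true rates used to
#'   simulate cell counts for each cell line (small per-line jitter is
#'   added under the derived seed).
#' @param growth_days Counting days for the cell-count series.
#' @param growth_noise_sd_rel Relative noise of the counts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       panel = panel_config(),
                       thresholds = run_thresholds(),
                       quantities = default_screen_quantities,
                       ode_modes = c("non_cimp", "cimp"),
                       ode_pre_days = 400,
                       ode_treat_days = 3,
                       ode_post_days = 97,
                       ode_t_step = 0.1,
                       growth_g = c(control = 0.35, treated = 0.25),
                       growth_d = c(control = 0.05, treated = 0.10),
                       growth_days = seq(0, 6, by = 1),
                       growth_noise_sd_rel = 0.05) {
  seed <- as.integer(seed)
  panel$seed <- seed * 13L + 1L
  structure(
    list(
      seed = seed,
      panel = panel,
      thresholds = thresholds,
      quantities = quantities,
      ode_modes = ode_modes,
      ode_pre_days = ode_pre_days,
      ode_treat_days = ode_treat_days,
      ode_post_days = ode_post_days,
      ode_t_step = ode_t_step,
      growth_g = growth_g,
      growth_d = growth_d,
      growth_days = growth_days,
      growth_noise_sd_rel = growth_noise_sd_rel,
      growth_seed = seed * 13L + 2L
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic panel: simulates the panel,
#' fits and classifies all runs, screens the successful runs for
#' pairwise correlations (with the square p-value grid and per-cell-line
#' means), simulates the mechanistic model for the configured modes with
#' one treatment course and extracts recovery metrics, simulates and
#' fits cell-count kinetics per cell line, and writes every table as
#' CSV plus a machine-readable JSON summary. Identical configurations
#' produce byte-identical summaries.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The summary, invisibly (a list; also written as
#'   `summary.json`).
#' @export
#' @examples
#' \donttest{
#' res <- run_full_analysis(run_config(seed = 1), out_dir = tempfile())
#' res$counts
#' }
run_full_analysis <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("could not create output directory.")
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating methylation panel (seed %d)", config$panel$seed)
  panel <- simulate_methylation_panel(config$panel)
  write_panel(panel, file.path(out_dir, "panel.csv"),
              truth_path = file.path(out_dir, "panel_truth.csv"))

  say("fitting %d runs", nrow(panel_truth(panel)))
  fits <- fit_methylation_panel(panel, thresholds = config$thresholds)
  readr::write_csv(fits, file.path(out_dir, "run_fits.csv"))
  excluded <- dplyr::filter(fits, .data$status != "successful")
  for (k in seq_len(nrow(excluded))) {
    say("excluded %s / %s: %s (%s)", excluded$cell_line[k],
        excluded$locus[k], excluded$status[k], excluded$reason[k])
  }

  say("correlation screen over %d successful runs",
      sum(fits$status == "successful"))
  screen <- pairwise_correlations(fits, quantities = config$quantities)
  readr::write_csv(screen, file.path(out_dir, "correlations.csv"))
  grid <- p_value_grid(screen)
  write_p_value_grid(grid, file.path(out_dir, "p_value_grid.csv"))
  means <- aggregate_by_cell_line(fits)
  readr::write_csv(means, file.path(out_dir, "cell_line_means.csv"))
  headline <- headline_tests(fits)

  say("simulating mechanistic model (%s)",
      paste(config$ode_modes, collapse = ", "))
  recov <- purrr::map(config$ode_modes, function(mode) {
    traj <- simulate_treatment_response(
      ode_parameters(mode = mode),
      pre_days = config$ode_pre_days,
      treat_days = config$ode_treat_days,
      post_days = config$ode_post_days,
      t_step = config$ode_t_step
    )
    readr::write_csv(traj,
                     file.path(out_dir, sprintf("trajectory_%s.csv", mode)))
    dplyr::bind_cols(tibble::tibble(mode = mode), recovery_metrics(traj))
  }) |> purrr::list_rbind()
  readr::write_csv(recov, file.path(out_dir, "recovery_metrics.csv"))

  say("simulating and fitting cell-count kinetics")
  lines <- unique(panel_truth(panel)$cell_line)
  counts <- withr::with_seed(config$growth_seed, {
    purrr::map(seq_along(lines), function(i) {
      purrr::map(names(config$growth_g), function(cond) {
        simulate_cell_counts(
          g = config$growth_g[[cond]] * exp(rnorm(1, 0, 0.1)),
          d = config$growth_d[[cond]] * exp(rnorm(1, 0, 0.1)),
          A0 = 1000, days = config$growth_days,
          noise_sd_rel = config$growth_noise_sd_rel,
          cell_line = lines[i], condition = cond
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  write_cell_counts(counts, file.path(out_dir, "cell_counts.csv"))
  rates <- fit_growth_kinetics(counts)
  readr::write_csv(rates, file.path(out_dir, "growth_rates.csv"))
  rate_cor <- rates_vs_methylation(rates, panel_baselines(panel))
  readr::write_csv(rate_cor, file.path(out_dir, "rates_vs_methylation.csv"))

  counts_by_status <- as.list(table(fits$status))
  summary <- list(
    seed = config$seed,
    counts = c(list(runs_total = nrow(fits)), counts_by_status),
    headline_tests = headline,
    cell_line_means = means,
    recovery_metrics = recov,
    growth_rates = rates
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; outputs in %s", out_dir)
  invisible(summary)
}

#' Read a run configuration from YAML or JSON
#'
#' Scalars in the file override the defaults of [run_config()] and
#' [panel_config()]; unknown keys are rejected.
#'
#' @param path A `.yaml`/`.yml` or `.json` file with optional top-level
#'   blocks `panel`, `thresholds`, and scalar pipeline settings.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  panel_args <- raw$panel %||% list()
  thr_args <- raw$thresholds %||% list()
  top <- raw[setdiff(names(raw), c("panel", "thresholds"))]
  known <- names(formals(run_config))
  bad <- setdiff(names(top), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  args <- c(
    top,
    list(panel = do.call(panel_config, panel_args),
         thresholds = do.call(run_thresholds, thr_args))
  )
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
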