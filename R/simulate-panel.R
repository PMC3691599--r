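canonical_loci <- c("ALU", "LINE-1", "APC1", "RASSF2-1", "HPP1", "SFRP2", "MGMT")

#' Simulate a panel of remethylation time series
#'
#' Generates one percent-methylation time series per (cell line, locus)
#' pair. Each series follows the delayed-tanh recovery curve
#' `f(t) = y0 + y1 tanh(m (t - b'))` evaluated at the configured
#' sampling days, plus independent Gaussian measurement noise, clipped
#' to \[0, 100\]. CIMP lines get high true baselines and near-immediate
#' onsets; non-CIMP lines get low baselines and delayed onsets; across
#' the panel the true (`B`, `log m`) pairs correlate at the planted
#' coefficient (see [panel_config()]).
#'
#' The true generating parameters of every run are retained in the
#' `"truth"` attribute (see [panel_truth()]) so that downstream fitting
#' can be validated by parameter recovery.
#'
#' @param config A [panel_config()].
#' @return A tibble with columns `cell_line`, `locus`, `day`,
#'   `methylation_pct`, `baseline_pct` and `cimp`, one row per
#'   measurement, with attributes `truth` (per-run true parameters) and
#'   `config`.
#' @export
#' @examples
#' panel <- simulate_methylation_panel(panel_config(seed = 7))
#' dplyr::count(panel, cell_line, cimp)
#' panel_truth(panel)
simulate_methylation_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  withr::with_seed(config$seed, {
    truth <- draw_true_parameters(config)
    obs <- truth |>
      dplyr::mutate(data = purrr::pmap(
        list(.data$y0, .data$y1, .data$m, .data$b),
        function(y0, y1, m, b) {
          tibble::tibble(
            day = config$sample_days,
            methylation_pct = eval_tanh(y0, y1, m, b, config$sample_days)
          )
        }
      )) |>
      dplyr::select("cell_line", "locus", "baseline_pct", "cimp", "data") |>
      tidyr::unnest("data")
    if (config$noise_sd > 0) {
      obs$methylation_pct <- obs$methylation_pct +
        rnorm(nrow(obs), 0, config$noise_sd)
    }
    obs$methylation_pct <- pmin(pmax(obs$methylation_pct, 0), 100)
  })
  obs <- obs[, c("cell_line", "locus", "day", "methylation_pct",
                 "baseline_pct", "cimp")]
  attr(obs, "truth") <- truth
  attr(obs, "config") <- config
  class(obs) <- c("meth_panel", class(obs))
  obs
}

# Draw per-run true parameters. The rate-baseline association is planted
# through log m = alpha + beta * B + eps, with beta and var(eps) solved so
# that the population correlation of (B, log m) equals the requested value.
draw_true_parameters <- function(config) {
  lines <- if (config$n_cell_lines <= 26) {
    paste0("line_", LETTERS[seq_len(config$n_cell_lines)])
  } else {
    sprintf("line_%03d", seq_len(config$n_cell_lines))
  }
  loci <- if (config$n_loci == length(canonical_loci)) {
    canonical_loci
  } else {
    paste0("locus_", seq_len(config$n_loci))
  }
  p_cimp <- mean(config$cimp_flags)
  d_mu <- config$baseline_mean_cimp - config$baseline_mean_non_cimp
  var_b <- p_cimp * (1 - p_cimp) * d_mu^2 +
    config$baseline_sd_line^2 + config$baseline_sd_locus^2
  mu_b <- p_cimp * config$baseline_mean_cimp +
    (1 - p_cimp) * config$baseline_mean_non_cimp
  rho <- config$planted_rate_base_correlation
  beta <- rho * config$log_m_sd / sqrt(var_b)
  sd_eps <- config$log_m_sd * sqrt(1 - rho^2)

  line_mean <- ifelse(config$cimp_flags,
                      config$baseline_mean_cimp,
                      config$baseline_mean_non_cimp) +
    rnorm(config$n_cell_lines, 0, config$baseline_sd_line)

  grid <- tidyr::expand_grid(
    line_idx = seq_len(config$n_cell_lines),
    locus = loci
  )
  n_run <- nrow(grid)
  cimp <- config$cimp_flags[grid$line_idx]
  baseline <- pmin(pmax(
    line_mean[grid$line_idx] + rnorm(n_run, 0, config$baseline_sd_locus),
    1), 99)
  m <- exp(config$log_m_mean + beta * (baseline - mu_b) +
             rnorm(n_run, 0, sd_eps))
  b_prime <- ifelse(
    cimp,
    runif(n_run, config$delay_range_cimp[1], config$delay_range_cimp[2]),
    runif(n_run, config$delay_range_non_cimp[1], config$delay_range_non_cimp[2])
  )
  drop_frac <- runif(n_run, 0.70, 0.95)
  initial <- baseline * (1 - drop_frac)
  target <- pmin(baseline * runif(n_run, 0.85, 1.05), 99)
  target <- pmax(target, initial + 1)
  b <- m * b_prime
  y1 <- (target - initial) / (1 + tanh(b))
  y0 <- target - y1

  tibble::tibble(
    cell_line = lines[grid$line_idx],
    locus = grid$locus,
    cimp = cimp,
    baseline_pct = baseline,
    m = m,
    b = b,
    b_prime = b_prime,
    y0 = y0,
    y1 = y1,
    initial_level = initial,
    target_level = target
  )
}

#' True generating parameters of a synthetic panel
#'
#' @param panel A panel from [simulate_methylation_panel()].
#' @return A tibble with one row per (cell line, locus) run: `cimp`,
#'   `baseline_pct` (B), `m`, `b`, `b_prime`, `y0`, `y1`,
#'   `initial_level`, `target_level`.
#' @export
panel_truth <- function(panel) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) {
    abort("`panel` carries no truth attribute; was it simulated by `simulate_methylation_panel()`?")
  }
  truth
}

#' Baseline methylation levels of a panel
#'
#' One row per run with the pre-treatment baseline level `B`, in the
#' shape expected by [fit_methylation_panel()].
#'
#' @param panel A panel tibble carrying `baseline_pct` per run (as
#'   produced by [simulate_methylation_panel()] or read from CSV).
#' @return A tibble with columns `cell_line`, `locus`, `baseline_pct`.
#' @export
panel_baselines <- function(panel) {
  panel |>
    dplyr::distinct(.data$cell_line, .data$locus, .data$baseline_pct)
}

#' Write / read a methylation panel as CSV
#'
#' `write_panel()` writes the measurements (`cell_line`, `locus`, `day`,
#' `methylation_pct`, `baseline_pct`, `cimp`) and, optionally, the
#' companion table of true generating parameters. `read_methylation_panel()`
#' reads a measurements CSV back. Files are UTF-8 with a header row and
#' '.' as decimal separator.
#'
#' @param panel Panel tibble.
#' @param path Output CSV path for the measurements.
#' @param truth_path Optional output CSV path for the true parameters.
#' @return `panel`, invisibly (for `write_panel`); a tibble (for
#'   `read_methylation_panel`).
#' @export
write_panel <- function(panel, path, truth_path = NULL) {
  readr::write_csv(as.data.frame(panel), path)
  if (!is.null(truth_path)) {
    readr::write_csv(panel_truth(panel), truth_path)
  }
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_methylation_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Plot a methylation panel
#'
#' Percent methylation against day, one facet per locus, coloured by
#' cell line, with the baseline level of each run drawn as a horizontal
#' dashed line.
#'
#' @param panel Panel tibble.
#' @return A ggplot object.
#' @export
plot_methylation_panel <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(.data$day, .data$methylation_pct,
                                      colour = .data$cell_line)) +
    ggplot2::geom_hline(
      data = panel_baselines(panel) |>
        dplyr::left_join(dplyr::distinct(panel, .data$cell_line, .data$locus),
                         by = c("cell_line", "locus")),
      ggplot2::aes(yintercept = .data$baseline_pct, colour = .data$cell_line),
      linetype = 2, alpha = 0.6
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~locus) +
    ggplot2::labs(x = "Days post-treatment", y = "Methylation (%)",
                  colour = "Cell line") +
    ggplot2::ylim(0, 100)
}
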