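#' Fit exponential net growth to live cell counts
#'
#' Least-squares fit of `x(t) = A0 * exp(g * t)` to the live counts on
#' the natural scale (a log-linear regression only provides the
#' starting values, so the estimate minimises squared error of the
#' exponential itself, not of its logarithm).
#'
#' @param counts Tibble with columns `day` and `live` (one cell line /
#'   condition), all live counts positive.
#' @return A one-row tibble with `A0` and `g`.
#' @export
#' @examples
#' cc <- simulate_cell_counts(g = 0.3, d = 0, A0 = 1000, days = 0:5)
#' fit_growth_rate(cc)
fit_growth_rate <- function(counts) {
  t <- as.numeric(counts$day)
  y <- as.numeric(counts$live)
  if (length(t) < 3) abort("at least 3 live counts are required.")
  if (any(y <= 0)) abort("all live counts must be positive.")
  if (diff(range(t)) <= 0) abort("degenerate time grid.")
  ll <- lm(log(y) ~ t)
  start <- list(A0 = exp(unname(coef(ll)[1])), g = unname(coef(ll)[2]))
  fit <- tryCatch(
    nls(y ~ A0 * exp(g * t), start = start,
        control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                     minFactor = 1e-10)),
    error = function(e) NULL
  )
  est <- if (is.null(fit)) start else as.list(coef(fit))
  tibble::tibble(A0 = est$A0, g = est$g)
}

#' Estimate the death rate from interval dead counts
#'
#' Between consecutive counts the dead cells accumulate as
#' `y(t_i) = (d * A0 / g) * (exp(g * t_i) - exp(g * t_{i-1}))` (dead
#' cells are removed at every count, so each interval restarts from
#' zero; the bracket has the analytic limit `A0 * (t_i - t_{i-1})` as
#' `g -> 0`). The model is linear in `d`, so the least-squares estimate
#' is the exact ratio `sum(y_obs * phi) / sum(phi^2)` with `phi` the
#' bracketed factor. Negative estimates are truncated to zero with a
#' warning (they indicate model misfit).
#'
#' @param counts Tibble with columns `day` and `dead_interval` (the
#'   first day's entry, with no preceding interval, may be `NA`).
#' @param A0,g Estimates from [fit_growth_rate()].
#' @return The death rate `d`, per day.
#' @export
estimate_death_rate <- function(counts, A0, g) {
  t <- as.numeric(counts$day)
  yd <- as.numeric(counts$dead_interval)
  ord <- order(t)
  t <- t[ord]; yd <- yd[ord]
  phi <- dead_interval_factor(g, A0, t)
  yd <- yd[-1]
  ok <- !is.na(yd)
  phi <- phi[ok]; yd <- yd[ok]
  if (length(phi) == 0 || sum(phi^2) == 0) {
    abort("no usable dead-count intervals.")
  }
  d <- sum(yd * phi) / sum(phi^2)
  if (d < 0) {
    warn(sprintf("negative death-rate estimate (%.4g) truncated to 0; the interval model does not fit these counts.", d))
    d <- 0
  }
  d
}

#' Estimate growth, death and division rates per cell line
#'
#' Applies [fit_growth_rate()] and [estimate_death_rate()] to each
#' (cell line, condition) group of a tidy count table and reports the
#' division rate `div = g + d` (net growth is division minus death).
#'
#' @param counts Tibble with columns `cell_line`, `condition`, `day`,
#'   `live`, `dead_interval`.
#' @return A tibble with one row per (cell line, condition): `A0`, `g`,
#'   `d`, `div`.
#' @export
#' @examples
#' cc <- simulate_cell_counts(g = 0.3, d = 0.05, A0 = 1000, days = 0:6)
#' fit_growth_kinetics(cc)
fit_growth_kinetics <- function(counts) {
  counts |>
    dplyr::group_by(.data$cell_line, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      gr <- fit_growth_rate(df)
      d <- estimate_death_rate(df, gr$A0, gr$g)
      dplyr::mutate(gr, d = d, div = .data$g + d)
    }) |>
    dplyr::ungroup()
}

#' Correlate kinetic rates with baseline methylation
#'
#' Tests whether the division and death rates of the cell lines covary
#' with their mean baseline methylation level, per condition, using the
#' same Pearson/Spearman machinery as the methylation screen. With the
#' typical handful of cell lines these tests carry very little power;
#' rows with `n < 5` are flagged `wide_uncertainty`.
#'
#' @param rates Output of [fit_growth_kinetics()].
#' @param baselines Tibble with `cell_line` and `baseline_pct` (per-run
#'   baselines are averaged per line).
#' @return A tibble of correlation rows (one per rate x condition) with
#'   `label`, `n` and the usual test columns.
#' @export
rates_vs_methylation <- function(rates, baselines) {
  mean_b <- baselines |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(mean_B = mean(.data$baseline_pct), .groups = "drop")
  joined <- dplyr::inner_join(rates, mean_b, by = "cell_line")
  if (dplyr::n_distinct(joined$cell_line) < 4) {
    abort("at least 4 cell lines are required.")
  }
  tidyr::expand_grid(
    rate = c("div", "d"),
    cond = unique(joined$condition)
  ) |>
    purrr::pmap(function(rate, cond) {
      df <- dplyr::filter(joined, .data$condition == cond)
      res <- correlate_pair(df$mean_B, df[[rate]])
      dplyr::bind_cols(
        tibble::tibble(
          label = sprintf("%s rate (%s) vs mean baseline",
                          if (rate == "div") "division" else "death", cond)
        ),
        res
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::mutate(wide_uncertainty = .data$n < 5)
}

#' Write / read cell-count tables
#'
#' CSV with columns `cell_line`, `condition`, `day`, `live`,
#' `dead_interval`.
#'
#' @param counts Count tibble.
#' @param path CSV path.
#' @export
write_cell_counts <- function(counts, path) {
  readr::write_csv(counts, path)
  invisible(counts)
}

#' @rdname write_cell_counts
#' @export
read_cell_counts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
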