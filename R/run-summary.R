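#' Exclusion thresholds for run classification
#'
#' Runs are excluded from the correlation screen when their baseline is
#' too low to quantify, when treatment failed to deplete methylation, or
#' when no recovery climb is observed. The thresholds are conventions
#' (logged with every classified run), not measured constants.
#'
#' @param base_threshold Minimum baseline `B`, percentage points.
#' @param drop_threshold Minimum relative treatment drop `(B - A)/B`.
#' @param climb_threshold Minimum fitted net climb over the observation
#'   window, percentage points.
#' @return A named list.
#' @export
run_thresholds <- function(base_threshold = 5,
                           drop_threshold = 0.10,
                           climb_threshold = 5) {
  list(
    base_threshold = base_threshold,
    drop_threshold = drop_threshold,
    climb_threshold = climb_threshold
  )
}

#' Classify a remethylation run
#'
#' Assigns exactly one status, checked in order: `base_too_low` when the
#' baseline `B` is below `base_threshold`; `insufficient_drop` when the
#' relative treatment drop `(B - A)/B` is below `drop_threshold`;
#' `no_reclimb` when the series trend is negative or the fitted net
#' climb over the observation window is below `climb_threshold`;
#' `erratic` when the fit did not converge; otherwise `successful`.
#' `A` is read as the first post-treatment observation.
#'
#' @param data One run (columns `day` and the level column).
#' @param fit The [fit_tanh()] result for the run.
#' @param baseline_pct The pre-treatment baseline `B`, percent.
#' @param thresholds See [run_thresholds()].
#' @inheritParams fit_tanh
#' @return A one-row tibble with `status` and `reason`.
#' @export
classify_run <- function(data, fit, baseline_pct,
                         thresholds = run_thresholds(),
                         day = "day", level = "methylation_pct") {
  t <- as.numeric(data[[day]])
  y <- as.numeric(data[[level]])
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  B <- baseline_pct
  A <- y[1]

  status <- NULL
  reason <- NULL
  if (is.na(B) || B <= 0) {
    status <- "base_too_low"
    reason <- "baseline missing or zero; relative quantities undefined"
  } else if (B < thresholds$base_threshold) {
    status <- "base_too_low"
    reason <- sprintf("baseline %.2f%% below threshold %g%%",
                      B, thresholds$base_threshold)
  } else if ((B - A) / B < thresholds$drop_threshold) {
    status <- "insufficient_drop"
    reason <- sprintf("relative drop %.3f below threshold %g",
                      (B - A) / B, thresholds$drop_threshold)
  } else {
    trend <- unname(coef(lm(y ~ t))[2])
    fitted_climb <- eval_tanh(fit$y0, fit$y1, fit$m, fit$b, max(t)) -
      eval_tanh(fit$y0, fit$y1, fit$m, fit$b, min(t))
    if (trend < 0) {
      status <- "no_reclimb"
      reason <- sprintf("negative series trend (%.3f %%/day)", trend)
    } else if (fit$converged && fitted_climb < thresholds$climb_threshold) {
      status <- "no_reclimb"
      reason <- sprintf("fitted net climb %.2f below threshold %g",
                        fitted_climb, thresholds$climb_threshold)
    } else if (!fit$converged) {
      status <- "erratic"
      reason <- "fitting procedure failed to converge"
    } else {
      status <- "successful"
      reason <- ""
    }
  }
  tibble::tibble(status = status, reason = reason)
}

#' Summarise one successful run for the correlation screen
#'
#' Collects the fitted quantities (`m`, `b`, `b' = b/m`, `y0`, `y1`,
#' `target = y0 + y1`) and the directly read quantities: the baseline
#' `B`; the first post-treatment level `A`; the relative treatment drop
#' `(B - A)/B`; the last observed level `L`; and its relative value
#' `L/B`.
#'
#' @inheritParams classify_run
#' @return A one-row tibble.
#' @export
derive_run_summary <- function(data, fit, baseline_pct,
                               day = "day", level = "methylation_pct") {
  if (!fit$converged) {
    warn("summarising a non-converged fit; fitted quantities may be unreliable.")
  }
  t <- as.numeric(data[[day]])
  y <- as.numeric(data[[level]])
  ord <- order(t)
  y <- y[ord]
  B <- baseline_pct
  A <- y[1]
  L <- y[length(y)]
  if (is.na(B) || B == 0) {
    abort("baseline B is zero; relative quantities are undefined (run excluded).")
  }
  tibble::tibble(
    B = B, A = A, rel_drop = (B - A) / B, L = L, rel_final = L / B,
    m = fit$m, b = fit$b, b_prime = fit$b_prime,
    y0 = fit$y0, y1 = fit$y1, target = fit$target_level,
    rss = fit$rss, converged = fit$converged
  )
}

#' Fit and classify every run of a methylation panel
#'
#' Maps [fit_tanh()], [classify_run()] and [derive_run_summary()] over
#' all (cell line, locus) runs of a tidy panel.
#'
#' @param panel Tidy panel tibble (`cell_line`, `locus`, `day`,
#'   `methylation_pct`), e.g. from [simulate_methylation_panel()] or
#'   [read_methylation_panel()].
#' @param baselines Tibble with `cell_line`, `locus`, `baseline_pct`.
#'   Defaults to [panel_baselines()] of the panel itself.
#' @param thresholds See [run_thresholds()].
#' @return A tibble with one row per run: labels, `status`, `reason`,
#'   and the run-summary quantities (fitted columns are `NA` where the
#'   fit was not attempted or meaningless).
#' @export
#' @examples
#' panel <- simulate_methylation_panel(panel_config(seed = 7))
#' fits <- fit_methylation_panel(panel)
#' dplyr::count(fits, status)
fit_methylation_panel <- function(panel,
                                  baselines = panel_baselines(panel),
                                  thresholds = run_thresholds()) {
  runs <- panel |>
    dplyr::select(dplyr::any_of(c("cell_line", "locus", "cimp")),
                  "day", "methylation_pct") |>
    tidyr::nest(data = c("day", "methylation_pct")) |>
    dplyr::left_join(baselines, by = c("cell_line", "locus"))

  purrr::pmap(runs, function(cell_line, locus, data, baseline_pct, ...) {
    fit <- fit_tanh(data)
    cls <- classify_run(data, fit, baseline_pct, thresholds)
    summ <- if (!is.na(baseline_pct) && baseline_pct > 0) {
      suppressWarnings(derive_run_summary(data, fit, baseline_pct))
    } else {
      tibble::tibble(B = baseline_pct)
    }
    dplyr::bind_cols(
      tibble::tibble(cell_line = cell_line, locus = locus),
      cls, summ
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(
      dplyr::distinct(dplyr::select(
        panel, dplyr::any_of(c("cell_line", "locus", "cimp")))),
      by = intersect(c("cell_line", "locus"), names(panel))
    )
}
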