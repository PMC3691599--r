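#' Configure a synthetic methylation panel
#'
#' Describes a panel of remethylation experiments: a set of cell lines
#' (each flagged CIMP or non-CIMP), a set of loci assayed per line, the
#' days on which percent methylation is sampled, the measurement noise,
#' and the correlation planted between the true remethylation rate `m`
#' and the true baseline methylation level `B` across the panel.
#'
#' The default layout mirrors a typical demethylation--recovery study:
#' 4 cell lines (2 CIMP, 2 non-CIMP) x 7 loci, sampled on 10 days over a
#' 50-day window. CIMP lines receive high baselines and near-zero
#' recovery delays; non-CIMP lines receive low baselines and delays of
#' roughly one to two weeks. The rate--baseline association is realised
#' by drawing `log m` as a linear function of the true baseline plus
#' Gaussian noise, with the regression coefficient and residual variance
#' solved so the population correlation of (`B`, `log m`) equals
#' `planted_rate_base_correlation`; keeping the rate on the log scale
#' guarantees `m > 0`.
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_loci Number of loci assayed per cell line.
#' @param cimp_flags Logical vector of length `n_cell_lines`; `TRUE`
#'   marks a CIMP line.
#' @param sample_days Strictly increasing vector of sampling days
#'   (days post-treatment), first day >= 0.
#' @param noise_sd Gaussian measurement noise, in percentage points.
#' @param planted_rate_base_correlation Target correlation between the
#'   true baseline `B` and `log m` across the panel, in \[-1, 1\].
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param baseline_mean_cimp,baseline_mean_non_cimp Mean baseline
#'   methylation (percent) for each group.
#' @param baseline_sd_line,baseline_sd_locus Between-line and
#'   between-locus standard deviations of the baseline (percentage
#'   points).
#' @param log_m_mean,log_m_sd Panel-level mean and standard deviation of
#'   `log m` (per-day rate on the log scale).
#' @param delay_range_cimp,delay_range_non_cimp Ranges (days) from which
#'   the true onset delay `b' = b/m` is drawn uniformly, per group.
#'
#' @return A `panel_config` list.
#' @seealso [simulate_methylation_panel()]
#' @export
#' @examples
#' cfg <- panel_config(seed = 7)
#' cfg$n_cell_lines
panel_config <- function(n_cell_lines = 4,
                         n_loci = 7,
                         cimp_flags = rep(c(TRUE, FALSE), length.out = n_cell_lines),
                         sample_days = c(0, 3, 7, 10, 14, 21, 28, 35, 42, 50),
                         noise_sd = 2,
                         planted_rate_base_correlation = -0.6,
                         seed = 1L,
                         baseline_mean_cimp = 70,
                         baseline_mean_non_cimp = 35,
                         baseline_sd_line = 5,
                         baseline_sd_locus = 10,
                         log_m_mean = log(0.12),
                         log_m_sd = 0.4,
                         delay_range_cimp = c(0, 1.5),
                         delay_range_non_cimp = c(6, 15)) {
  if (n_cell_lines < 1 || n_loci < 1) {
    abort("`n_cell_lines` and `n_loci` must be at least 1.")
  }
  if (length(cimp_flags) != n_cell_lines || !is.logical(cimp_flags)) {
    abort("`cimp_flags` must be a logical vector of length `n_cell_lines`.")
  }
  if (length(sample_days) < 2 || any(diff(sample_days) <= 0)) {
    abort("`sample_days` must be strictly increasing.")
  }
  if (sample_days[1] < 0) {
    abort("`sample_days` must start at day 0 or later.")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.")
  }
  if (abs(planted_rate_base_correlation) > 1) {
    abort("`planted_rate_base_correlation` must lie in [-1, 1].")
  }
  structure(
    list(
      n_cell_lines = as.integer(n_cell_lines),
      n_loci = as.integer(n_loci),
      cimp_flags = cimp_flags,
      sample_days = as.numeric(sample_days),
      noise_sd = noise_sd,
      planted_rate_base_correlation = planted_rate_base_correlation,
      seed = as.integer(seed),
      baseline_mean_cimp = baseline_mean_cimp,
      baseline_mean_non_cimp = baseline_mean_non_cimp,
      baseline_sd_line = baseline_sd_line,
      baseline_sd_locus = baseline_sd_locus,
      log_m_mean = log_m_mean,
      log_m_sd = log_m_sd,
      delay_range_cimp = delay_range_cimp,
      delay_range_non_cimp = delay_range_non_cimp
    ),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf(
    "<panel_config> %d cell lines (%d CIMP) x %d loci, %d sampling days over %g d, noise sd %g, planted r(B, log m) = %g, seed %d\n",
    x$n_cell_lines, sum(x$cimp_flags), x$n_loci, length(x$sample_days),
    max(x$sample_days), x$noise_sd, x$planted_rate_base_correlation, x$seed
  ))
  invisible(x)
}
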