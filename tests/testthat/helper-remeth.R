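# Shared fixtures, built in code.

# Canonical noiseless tanh run: y0 = 30, y1 = 20, m = 0.2 /d, b = 2
# (b' = 10 d), sampled every 5 days over 50 days.
canonical_run <- function(noise_sd = 0, seed = 1,
                          days = seq(0, 50, by = 5)) {
  y <- eval_tanh(30, 20, 0.2, 2, days)
  if (noise_sd > 0) {
    y <- withr::with_seed(seed, y + rnorm(length(days), 0, noise_sd))
  }
  tibble::tibble(day = days, methylation_pct = y)
}

small_panel <- function(seed = 7, ...) {
  simulate_methylation_panel(panel_config(seed = seed, ...))
}

# Brute-force grid search over (m, b) with (y0, y1) solved analytically
# by linear regression on tanh(m t - b); independent of the fitting path.
grid_search_tanh <- function(t, y, m_grid, b_grid) {
  best <- list(rss = Inf)
  for (m in m_grid) {
    # columns: one b per column
    arg <- outer(t, b_grid, function(tt, bb) tanh(m * tt - bb))
    for (j in seq_along(b_grid)) {
      z <- arg[, j]
      fit <- stats::lm.fit(cbind(1, z), y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(
          rss = rss, m = m, b = b_grid[j],
          y0 = fit$coefficients[1], y1 = fit$coefficients[2]
        )
      }
    }
  }
  best
}
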