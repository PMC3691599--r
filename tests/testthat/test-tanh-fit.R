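test_that("eval_tanh matches hand arithmetic and saturates", {
  expect_equal(eval_tanh(30, 20, 0.2, 2, 1e6), 50)
  expect_equal(eval_tanh(30, 20, 0.2, 2, 10), 30)
  expect_equal(eval_tanh(30, 20, 0.2, 2, 0), 30 - 20 * tanh(2))
})

test_that("eval_tanh is monotone increasing and bounded for m, y1 > 0", {
  for (par in list(c(30, 20, 0.2, 2), c(50, 40, 0.05, -1), c(10, 5, 1, 4))) {
    # grid spanning the transition region (argument within +/- 8)
    t <- (par[4] + seq(-8, 8, length.out = 2001)) / par[3]
    v <- eval_tanh(par[1], par[2], par[3], par[4], t)
    expect_true(all(diff(v) > 0))
    expect_true(all(v > par[1] - par[2] & v < par[1] + par[2]))
  }
})

test_that("noiseless series are recovered to optimizer precision", {
  fit <- fit_tanh(canonical_run())
  expect_true(fit$converged)
  expect_equal(fit$y0, 30, tolerance = 1e-6)
  expect_equal(fit$y1, 20, tolerance = 1e-6)
  expect_equal(fit$m, 0.2, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$b_prime, 10, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-10)
})

test_that("refitting the model's own fitted curve is a fixed point", {
  noisy <- canonical_run(noise_sd = 2, seed = 3)
  f1 <- fit_tanh(noisy)
  clean <- tibble::tibble(
    day = noisy$day,
    methylation_pct = eval_tanh(f1$y0, f1$y1, f1$m, f1$b, noisy$day)
  )
  f2 <- fit_tanh(clean)
  expect_equal(f2$m, f1$m, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
})

test_that("derived quantities respect their identities", {
  fit <- fit_tanh(canonical_run())
  expect_equal(fit$b_prime, fit$b / fit$m)
  expect_equal(fit$initial_level, fit$y0 - fit$y1 * tanh(fit$b))
  expect_equal(fit$target_level, fit$y0 + fit$y1)
  expect_lte(fit$initial_level, fit$target_level)
})

test_that("fitted rss never exceeds the initialization rss", {
  for (s in 1:20) {
    noisy <- canonical_run(noise_sd = 3, seed = s)
    fit <- fit_tanh(noisy)
    expect_lte(fit$rss, fit$init_rss)
  }
})

test_that("the noisy fit agrees with a brute-force grid-search oracle", {
  noisy <- canonical_run(noise_sd = 1, seed = 42)
  fit <- fit_tanh(noisy)
  oracle <- grid_search_tanh(
    noisy$day, noisy$methylation_pct,
    m_grid = seq(0.05, 0.5, by = 0.001),
    b_grid = seq(0, 4, by = 0.001)
  )
  expect_lt(abs(fit$m - oracle$m) / oracle$m, 0.10)
  expect_lte(fit$rss, oracle$rss + 1e-6)
})

test_that("fit_tanh rejects degenerate input", {
  expect_error(fit_tanh(tibble::tibble(day = 1:4, methylation_pct = 1:4)),
               "5 time points")
  expect_error(
    fit_tanh(tibble::tibble(day = rep(1, 6), methylation_pct = 1:6)),
    "identical"
  )
})

test_that("tidy, glance and autoplot views expose the fit", {
  fit <- fit_tanh(canonical_run())
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "m"], fit$m)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("run classification applies the exclusion rules in order", {
  thresholds <- run_thresholds()
  run <- canonical_run()
  fit <- fit_tanh(run)
  # prototypical accepted run (climb 10 -> 50, baseline 50)
  expect_equal(classify_run(run, fit, baseline_pct = 50)$status, "successful")
  # baseline below 5% threshold
  expect_equal(classify_run(run, fit, baseline_pct = 1)$status, "base_too_low")
  # no real drop relative to baseline: first point 10.7 vs B = 11
  expect_equal(classify_run(run, fit, baseline_pct = 11)$status,
               "insufficient_drop")
  # declining series
  down <- tibble::tibble(day = seq(0, 50, 5),
                         methylation_pct = seq(60, 20, length.out = 11))
  fit_down <- fit_tanh(down)
  expect_equal(classify_run(down, fit_down, baseline_pct = 70)$status,
               "no_reclimb")
  # flat series: fitted climb below the climb threshold
  flat <- tibble::tibble(
    day = seq(0, 50, 5),
    methylation_pct = 20 + withr::with_seed(1, rnorm(11, 0, 0.3))
  )
  fit_flat <- fit_tanh(flat)
  cls <- classify_run(flat, fit_flat, baseline_pct = 60)
  expect_true(cls$status %in% c("no_reclimb", "erratic"))
})

test_that("run summaries report the directly read quantities", {
  run <- canonical_run()
  fit <- fit_tanh(run)
  sm <- derive_run_summary(run, fit, baseline_pct = 50)
  expect_equal(sm$A, run$methylation_pct[1])
  expect_equal(sm$rel_drop, (50 - sm$A) / 50)
  expect_equal(sm$L, tail(run$methylation_pct, 1))
  expect_equal(sm$rel_final, sm$L / 50)
  expect_equal(sm$b_prime, sm$b / sm$m)
  expect_error(derive_run_summary(run, fit, baseline_pct = 0), "undefined")
})

test_that("parameter recovery holds over noisy replicates", {
  errs <- vapply(1:100, function(s) {
    noisy <- canonical_run(noise_sd = 1, seed = s,
                           days = seq(0, 50, by = 5))
    fit <- fit_tanh(noisy)
    c(abs(fit$m - 0.2) / 0.2, abs(fit$b_prime - 10) / 10)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.20)
})

test_that("fit_methylation_panel fits and classifies every run", {
  panel <- small_panel(seed = 7)
  fits <- fit_methylation_panel(panel)
  expect_equal(nrow(fits), 28)
  expect_true(all(fits$status %in% c("successful", "base_too_low",
                                     "insufficient_drop", "no_reclimb",
                                     "erratic")))
  succ <- dplyr::filter(fits, status == "successful")
  truth <- panel_truth(panel)
  j <- dplyr::inner_join(succ, truth, by = c("cell_line", "locus"),
                         suffix = c("", ".true"))
  expect_gt(nrow(j), 20)
  expect_lt(median(abs(j$m - j$m.true) / j$m.true), 0.35)
  expect_equal(j$B, j$baseline_pct)
})
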