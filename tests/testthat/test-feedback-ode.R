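ref_params <- function(...) ode_parameters(...)

test_that("parameter validation enforces the model's constraints", {
  expect_error(ode_parameters(lam = -1), "non-negative")
  expect_error(ode_parameters(k1 = 0), "positive")
  expect_error(ode_parameters(c = 200), "k2")
  expect_error(ode_parameters(n_stages = 0), "at least 1")
  expect_error(treatment_protocol(c(5, 3)), "end > start")
  expect_error(treatment_protocol(list(c(0, 5), c(4, 8))), "overlap")
})

test_that("production switches off at the feedback threshold, or stays constant", {
  p <- ref_params()
  expect_equal(production_rate(4, p), 12)     # 2 * (10 - 4)
  expect_equal(production_rate(10, p), 0)
  expect_equal(production_rate(15, p), 0)
  pc <- ref_params(mode = "cimp")
  expect_equal(production_rate(c(0, 4, 50), pc), c(2, 2, 2))
})

test_that("no production means no methylation", {
  traj <- simulate_feedback_model(ref_params(eta = 0), t_max = 50, t_step = 1)
  expect_true(all(abs(traj$x) < 1e-12))
  expect_true(all(abs(traj$w) < 1e-12))
})

test_that("the untreated non-CIMP model reaches the closed-form steady state", {
  p <- ref_params()
  frac <- steady_state_fraction(p)
  expect_equal(frac, 1 - 0.9^12.5, tolerance = 1e-12)
  traj <- simulate_feedback_model(p, t_max = 1500, t_step = 5)
  expect_equal(tail(traj$x_pct, 1), 100 * frac, tolerance = 1e-4)
  # degenerate thresholds
  expect_equal(steady_state_fraction(ref_params(c = 0)), 0)
  expect_equal(steady_state_fraction(ref_params(c = 100)), 1)
  expect_error(steady_state_fraction(ref_params(mode = "cimp")), "non_cimp")
})

test_that("the final level is independent of cascade length", {
  finals <- vapply(c(2, 3, 5), function(n) {
    traj <- simulate_feedback_model(ref_params(n_stages = n),
                                    t_max = 1500, t_step = 5)
    tail(traj$x_pct, 1)
  }, numeric(1))
  expect_lt(max(finals) - min(finals), 0.2)
})

test_that("states stay within their physical bounds", {
  for (mode in c("non_cimp", "cimp")) {
    traj <- simulate_treatment_response(ref_params(mode = mode),
                                        pre_days = 100, post_days = 60,
                                        t_step = 0.5)
    expect_true(all(traj$x >= -1e-6 & traj$x <= ref_params()$k1 + 1e-6))
    expect_true(all(traj$w >= -1e-6 & traj$w <= ref_params()$k2 + 1e-6))
    expect_true(all(traj$y1 >= -1e-9 & traj$y3 >= -1e-9))
  }
})

test_that("the sensor barely overshoots the feedback threshold", {
  p <- ref_params()
  traj <- simulate_feedback_model(p, t_max = 1500, t_step = 1)
  expect_lt(max(traj$w) - p$c, 0.005 * p$c)
})

test_that("the fast-decay cascade is quasi-steady at P/delta in CIMP mode", {
  p <- ref_params(mode = "cimp")
  traj <- simulate_feedback_model(p, t_max = 100, t_step = 1)
  yn <- tail(traj$y3, 1)
  expect_lt(abs(yn - p$eta / p$delta) / (p$eta / p$delta), 0.02)
})

test_that("treatment depletes methylation and recovery stabilizes below baseline", {
  traj <- simulate_treatment_response(ref_params(), pre_days = 400,
                                      post_days = 150, t_step = 0.25)
  pre <- traj$x_pct[which.min(abs(traj$time - 400))]
  trough <- min(traj$x_pct[traj$time >= 400 & traj$time <= 404])
  final <- tail(traj$x_pct, 1)
  expect_gt(pre, 70)
  expect_lt(trough, 5)
  expect_gt(final, 40)
  expect_lt(final, pre)   # sensors demethylate less than the locus
})

test_that("recovery metrics capture the delayed non-CIMP burst vs immediate CIMP climb", {
  non <- simulate_treatment_response(ref_params(), t_step = 0.1)
  cimp <- simulate_treatment_response(ref_params(mode = "cimp"), t_step = 0.1)
  mn <- recovery_metrics(non)
  mc <- recovery_metrics(cimp)
  expect_true(mn$defined && mc$defined)
  expect_gt(mn$onset_delay_days, 0)
  expect_lt(mc$onset_delay_days, 0.5)
  expect_gt(mn$max_slope_pct_per_day, mc$max_slope_pct_per_day)
})

test_that("the onset delay grows with cascade length", {
  lags <- vapply(c(2, 5), function(n) {
    traj <- simulate_treatment_response(ref_params(n_stages = n),
                                        pre_days = 200, post_days = 80,
                                        t_step = 0.1)
    recovery_metrics(traj)$onset_delay_days
  }, numeric(1))
  expect_gt(lags[2], lags[1])
})

test_that("degenerate recovery inputs are flagged undefined", {
  p <- ref_params()
  # no treatment window at all
  traj <- simulate_feedback_model(p, t_max = 100, t_step = 1)
  expect_false(recovery_metrics(traj)$defined)
  # trajectory at steady state with a treatment window of zero effect
  p0 <- ref_params(a1 = 0, a2 = 0)
  tr2 <- simulate_feedback_model(
    p0, protocol = treatment_protocol(c(1000, 1003)),
    t_max = 1100, t_step = 1
  )
  expect_false(recovery_metrics(tr2)$defined)
  # trajectory must span beyond the window
  expect_error(
    recovery_metrics(
      simulate_feedback_model(p, protocol = treatment_protocol(c(90, 120)),
                              t_max = 100, t_step = 1),
      protocol = treatment_protocol(c(90, 120))
    ),
    "span"
  )
})

test_that("trajectories plot and carry their metadata", {
  traj <- simulate_treatment_response(ref_params(), pre_days = 50,
                                      post_days = 20, t_step = 1)
  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(attr(traj, "params"), "ode_parameters")
})
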