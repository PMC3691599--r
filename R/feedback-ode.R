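#' Parameters of the feedback-regulated methylation model
#'
#' The model tracks the methylation level `x` of a locus of interest
#' (capacity `k1`), the methylation level `w` of hypothetical feedback
#' sensors (capacity `k2`), and a signalling cascade `y1..yn` whose last
#' element `yn` is the active de novo methyltransferase (MTase):
#'
#' \deqn{dx/dt = \lambda y_n (1 - x/k_1) - a_1 x}
#' \deqn{dw/dt = \gamma y_n (1 - w/k_2) - a_2 w}
#' \deqn{dy_1/dt = \eta_{prod} - q y_1}
#' \deqn{dy_i/dt = q (y_{i-1} - y_i), \quad 1 < i < n}
#' \deqn{dy_n/dt = q y_{n-1} - \delta y_n}
#'
#' In `non_cimp` mode the cascade input is produced at rate
#' `eta * (c - w)` while the sensor methylation `w` lies below the
#' threshold `c`, and production stops when `w` reaches `c` (negative
#' feedback). In `cimp` mode the feedback is corrupted and production is
#' the constant `eta`. The demethylation rates `a1`, `a2` act only
#' during treatment windows (see [treatment_protocol()]). The MTase
#' decay rate `delta` is taken large relative to the slow rates so that
#' methylation stops quickly once the activation signal is off.
#'
#' The defaults are the reference non-CIMP parameter set used throughout
#' the package; time is measured in days.
#'
#' @param lam Locus methylation rate (lambda).
#' @param k1 Locus methylation capacity.
#' @param a1 Treatment demethylation rate of the locus, per day.
#' @param gam Sensor methylation rate (gamma).
#' @param k2 Sensor methylation capacity.
#' @param a2 Treatment demethylation rate of the sensors, per day.
#' @param eta Production rate constant of the cascade input.
#' @param c Feedback threshold on sensor methylation (0 <= c <= k2).
#' @param q Cascade transfer rate, per day.
#' @param delta MTase decay rate, per day.
#' @param n_stages Cascade length `n` (>= 1).
#' @param mode `"non_cimp"` (negative feedback) or `"cimp"` (constant
#'   production).
#' @return An `ode_parameters` list.
#' @export
#' @examples
#' ode_parameters()
#' ode_parameters(mode = "cimp")
ode_parameters <- function(lam = 0.4, k1 = 0.04, a1 = 4,
                           gam = 80, k2 = 100, a2 = 0.4,
                           eta = 2, c = 10, q = 0.8, delta = 4000,
                           n_stages = 3,
                           mode = c("non_cimp", "cimp")) {
  mode <- match.arg(mode)
  rates <- c(lam = lam, a1 = a1, gam = gam, a2 = a2, eta = eta,
             q = q, delta = delta)
  if (any(rates < 0)) abort("all rates must be non-negative.")
  if (k1 <= 0 || k2 <= 0) abort("`k1` and `k2` must be positive.")
  if (c < 0 || c > k2) abort("`c` must lie in [0, k2].")
  if (n_stages < 1) abort("`n_stages` must be at least 1.")
  structure(
    list(lam = lam, k1 = k1, a1 = a1, gam = gam, k2 = k2, a2 = a2,
         eta = eta, c = c, q = q, delta = delta,
         n_stages = as.integer(n_stages), mode = mode),
    class = "ode_parameters"
  )
}

#' Treatment protocol
#'
#' Non-overlapping, ordered windows (in days) during which the
#' demethylation rates `a1` and `a2` are active; a 72-hour course is a
#' single 3-day window.
#'
#' @param windows Numeric vector `c(start, end)` or a list of such
#'   vectors.
#' @return A `treatment_protocol`: a two-column matrix of windows.
#' @export
#' @examples
#' treatment_protocol(c(400, 403))
treatment_protocol <- function(windows = list()) {
  if (is.numeric(windows)) windows <- list(windows)
  w <- do.call(rbind, lapply(windows, function(x) {
    if (length(x) != 2 || x[2] <= x[1]) {
      abort("each window must be c(start, end) with end > start.")
    }
    as.numeric(x)
  }))
  if (is.null(w)) w <- matrix(numeric(0), ncol = 2)
  colnames(w) <- c("start", "end")
  if (nrow(w) > 1) {
    w <- w[order(w[, 1]), , drop = FALSE]
    if (any(w[-1, 1] < w[-nrow(w), 2])) {
      abort("treatment windows must not overlap.")
    }
  }
  structure(w, class = c("treatment_protocol", "matrix"))
}

#' Cascade-input production rate
#'
#' `non_cimp` mode: `eta * (c - w)` while `w < c`, zero once the sensor
#' methylation reaches the feedback threshold. `cimp` mode: the constant
#' `eta`, regardless of `w`.
#'
#' @param w Sensor methylation level(s), >= 0.
#' @param params [ode_parameters()].
#' @return Production rate(s).
#' @export
#' @examples
#' production_rate(4, ode_parameters())   # 2 * (10 - 4) = 12
#' production_rate(4, ode_parameters(mode = "cimp"))
production_rate <- function(w, params) {
  if (params$mode == "cimp") {
    rep(params$eta, length(w))
  } else {
    params$eta * pmax(params$c - w, 0)
  }
}

feedback_derivs <- function(t, state, p, treat) {
  x <- state[1]
  w <- state[2]
  y <- state[-(1:2)]
  n <- p$n_stages
  yn <- y[n]
  prod <- if (p$mode == "cimp") p$eta else p$eta * max(p$c - w, 0)
  a1 <- if (treat) p$a1 else 0
  a2 <- if (treat) p$a2 else 0
  dx <- p$lam * yn * (1 - x / p$k1) - a1 * x
  dw <- p$gam * yn * (1 - w / p$k2) - a2 * w
  dy <- numeric(n)
  if (n == 1) {
    dy[1] <- prod - p$delta * y[1]
  } else {
    dy[1] <- prod - p$q * y[1]
    if (n > 2) {
      i <- 2:(n - 1)
      dy[i] <- p$q * (y[i - 1] - y[i])
    }
    dy[n] <- p$q * y[n - 1] - p$delta * y[n]
  }
  list(c(dx, dw, dy))
}

#' Simulate the feedback methylation model
#'
#' Integrates the stiff system with [deSolve::ode()] (`lsoda`, relative
#' tolerance `1e-8`), piecewise across treatment-window boundaries so
#' the discontinuous switching of the demethylation terms is handled
#' exactly at the window edges; the feedback production term itself is
#' continuous at the threshold crossing `w = c`.
#'
#' @param params [ode_parameters()].
#' @param protocol [treatment_protocol()] (or `NULL` for no treatment).
#' @param init Named initial state `c(x = , w = , y1 = , ...)`; the
#'   default is the fully unmethylated, inactive state (all zero).
#' @param t_max End of the integration, days.
#' @param t_step Output grid spacing, days.
#' @param times Explicit output grid (overrides `t_max`/`t_step`).
#' @param rtol,atol Solver tolerances.
#' @return A `meth_trajectory` tibble: `time`, `x`, `w`, `y1..yn`,
#'   `x_pct = 100 x / k1`, `w_pct = 100 w / k2`, with the parameters and
#'   protocol attached as attributes.
#' @export
#' @examples
#' traj <- simulate_feedback_model(ode_parameters(), t_max = 200, t_step = 1)
#' tail(traj$x_pct, 1)
simulate_feedback_model <- function(params,
                                    protocol = NULL,
                                    init = NULL,
                                    t_max = 500,
                                    t_step = 0.1,
                                    times = NULL,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ode_parameters"))
  n <- params$n_stages
  if (is.null(init)) {
    init <- c(x = 0, w = 0, setNames(rep(0, n), paste0("y", seq_len(n))))
  }
  state <- numeric(2 + n)
  names(state) <- c("x", "w", paste0("y", seq_len(n)))
  state[names(init)[names(init) %in% names(state)]] <-
    init[names(init) %in% names(state)]

  if (is.null(times)) times <- seq(0, t_max, by = t_step)
  times <- sort(unique(as.numeric(times)))
  t0 <- times[1]
  t_end <- times[length(times)]

  windows <- if (is.null(protocol)) {
    matrix(numeric(0), ncol = 2)
  } else {
    unclass(protocol)
  }
  # segment boundaries: start/end of span plus any window edge inside it
  edges <- sort(unique(c(t0, t_end,
                         windows[windows > t0 & windows < t_end])))
  out <- NULL
  for (s in seq_len(length(edges) - 1)) {
    a <- edges[s]; b <- edges[s + 1]
    mid <- (a + b) / 2
    treat <- nrow(windows) > 0 &&
      any(mid >= windows[, 1] & mid < windows[, 2])
    seg_times <- sort(unique(c(a, times[times >= a & times <= b], b)))
    sol <- deSolve::ode(
      y = state, times = seg_times, func = feedback_derivs,
      parms = params, treat = treat,
      method = "lsoda", rtol = rtol, atol = atol
    )
    state <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% times
    if (!is.null(out)) keep <- keep & !(sol[, 1] %in% out[, 1])
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1] <- "time"
  traj$x_pct <- 100 * traj$x / params$k1
  traj$w_pct <- 100 * traj$w / params$k2
  attr(traj, "params") <- params
  attr(traj, "protocol") <- protocol
  class(traj) <- c("meth_trajectory", class(traj))
  traj
}

#' Closed-form steady-state methylation fraction (non-CIMP, untreated)
#'
#' With no treatment, the locus and sensor equations are driven by the
#' same MTase activity, so time can be eliminated between them:
#' `d log(1 - x/k1) / d log(1 - w/k2) = (lam * k2) / (gam * k1)`.
#' Starting fully unmethylated, feedback halts methylation when `w`
#' reaches `c`, giving the final locus fraction
#' `1 - (1 - c/k2)^(lam * k2 / (gam * k1))` of `k1`, independent of the
#' cascade. (This relation is verified against direct numerical
#' integration in the package tests.)
#'
#' @param params [ode_parameters()] in `non_cimp` mode.
#' @return Fraction of `k1` (in \[0, 1\]).
#' @export
#' @examples
#' steady_state_fraction(ode_parameters())  # 1 - 0.9^12.5
steady_state_fraction <- function(params) {
  stopifnot(inherits(params, "ode_parameters"))
  if (params$mode != "non_cimp") {
    abort("the closed form applies to the non_cimp (feedback) mode only.")
  }
  if (params$c > params$k2) abort("`c` must not exceed `k2`.")
  expo <- params$lam * params$k2 / (params$gam * params$k1)
  1 - (1 - params$c / params$k2)^expo
}

#' Post-treatment recovery metrics
#'
#' Quantifies the re-methylation that follows the last treatment
#' window: the maximum recovery slope (finite differences of `x_pct`),
#' the final level, and the onset delay. The onset delay is the
#' growth-curve lag time: the tangent at the point of maximum slope is
#' extrapolated back to the post-treatment starting level, and the
#' intercept time (clamped at zero) is reported. A curve that climbs
#' immediately at its fastest rate therefore has onset ~0, while a
#' sigmoid whose slope peaks late has a positive onset, regardless of
#' how slow or fast the climb is.
#'
#' @param traj A `meth_trajectory` spanning beyond the last treatment
#'   window.
#' @param protocol The [treatment_protocol()] used (defaults to the one
#'   attached to `traj`).
#' @param min_gain Minimum post-treatment gain (percentage points of
#'   `x_pct`) below which the metrics are flagged undefined.
#' @return A one-row tibble: `onset_delay_days`,
#'   `max_slope_pct_per_day`, `final_level_pct`, `gain_pct`, `defined`.
#' @export
recovery_metrics <- function(traj, protocol = attr(traj, "protocol"),
                             min_gain = 1) {
  if (is.null(protocol) || nrow(unclass(protocol)) == 0) {
    return(tibble::tibble(
      onset_delay_days = NA_real_, max_slope_pct_per_day = NA_real_,
      final_level_pct = tail(traj$x_pct, 1), gain_pct = NA_real_,
      defined = FALSE
    ))
  }
  t_end <- max(unclass(protocol)[, 2])
  if (max(traj$time) <= t_end) {
    abort("trajectory must span beyond the last treatment window.")
  }
  post <- dplyr::filter(traj, .data$time >= t_end)
  tt <- post$time
  xp <- post$x_pct
  gain <- tail(xp, 1) - xp[1]
  if (!is.finite(gain) || gain < min_gain) {
    return(tibble::tibble(
      onset_delay_days = NA_real_, max_slope_pct_per_day = NA_real_,
      final_level_pct = tail(xp, 1), gain_pct = gain, defined = FALSE
    ))
  }
  sl <- diff(xp) / diff(tt)
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  xm <- (xp[-1] + xp[-length(xp)]) / 2
  i <- which.max(sl)
  lag <- tm[i] - (xm[i] - xp[1]) / sl[i] - t_end
  tibble::tibble(
    onset_delay_days = max(lag, 0),
    max_slope_pct_per_day = sl[i],
    final_level_pct = tail(xp, 1),
    gain_pct = gain,
    defined = TRUE
  )
}

#' Simulate a full equilibrate--treat--recover experiment
#'
#' Convenience wrapper reproducing the canonical in-silico experiment:
#' the cell equilibrates from the fully unmethylated state, a single
#' 72-hour treatment course is applied, and recovery is followed.
#'
#' @param params [ode_parameters()].
#' @param pre_days Equilibration time before treatment, days.
#' @param treat_days Treatment duration, days.
#' @param post_days Follow-up after treatment, days.
#' @param t_step Output grid spacing, days.
#' @return A `meth_trajectory` (time measured from the start of
#'   equilibration; the protocol is attached).
#' @export
#' @examples
#' traj <- simulate_treatment_response(ode_parameters(),
#'   pre_days = 100, post_days = 50, t_step = 0.5)
#' recovery_metrics(traj)
simulate_treatment_response <- function(params,
                                        pre_days = 400,
                                        treat_days = 3,
                                        post_days = 97,
                                        t_step = 0.1) {
  protocol <- treatment_protocol(c(pre_days, pre_days + treat_days))
  simulate_feedback_model(
    params, protocol = protocol,
    t_max = pre_days + treat_days + post_days, t_step = t_step
  )
}

#' @rdname simulate_feedback_model
#' @param object A `meth_trajectory`.
#' @param ... Unused.
#' @method autoplot meth_trajectory
#' @export
autoplot.meth_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  n <- p$n_stages
  yn <- object[[paste0("y", n)]]
  scale <- if (max(yn) > 0) max(object$x_pct) / max(yn) else 1
  df <- tibble::tibble(
    time = rep(object$time, 2),
    value = c(object$x_pct, yn * scale),
    series = rep(c("locus methylation (% of k1)", "MTase activity (scaled)"),
                 each = nrow(object))
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                         linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = "Level", linetype = NULL)
  protocol <- attr(object, "protocol")
  if (!is.null(protocol) && nrow(unclass(protocol)) > 0) {
    w <- as.data.frame(unclass(protocol))
    gg <- gg + ggplot2::annotate("rect",
      xmin = w$start, xmax = w$end, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "red"
    )
  }
  gg
}
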