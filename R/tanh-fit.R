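#' Delayed-tanh remethylation curve
#'
#' Evaluates `f(t) = y0 + y1 * tanh(m * t - b)`, the sigmoid used to
#' describe percent-methylation recovery after demethylating treatment.
#' `m` (per day) is the remethylation rate, the dimensionless `b` sets
#' the onset (the equivalent delay in days is `b' = b/m`),
#' `y0 - y1 * tanh(b)` is the initial level at `t = 0` and `y0 + y1`
#' the target level. For `m, y1 > 0` the curve is monotone increasing
#' and bounded in `(y0 - y1, y0 + y1)`.
#'
#' @param y0,y1 Offset and amplitude, percent.
#' @param m Rate, per day.
#' @param b Dimensionless onset.
#' @param t Day(s).
#' @return Percent methylation at `t`.
#' @export
#' @examples
#' eval_tanh(30, 20, 0.2, 2, c(0, 10, 100))
eval_tanh <- function(y0, y1, m, b, t) {
  y0 + y1 * tanh(m * t - b)
}

#' Fit the delayed-tanh curve to a remethylation time series
#'
#' Nonlinear least squares on the `b` parameterisation, with data-driven
#' initial values (`y0` = mean level, `y1` = half the observed range,
#' `m` from the steepest finite-difference slope scaled by `y1`, `b` =
#' `m` times the time of half-rise) and three deterministic restarts
#' that jitter `m` and `b` to escape the flat plateau of the tanh
#' likelihood. Parameters are bounded (`m > 0`, `y1 > 0`, levels within
#' the percent scale plus slack); the fit is marked non-converged when
#' the optimiser fails or ends on a bound. The returned residual sum of
#' squares never exceeds that of the initialisation.
#'
#' @param data A data frame for a single (cell line, locus) run.
#' @param day,level Column names (strings) of the sampling day and the
#'   percent methylation.
#' @return An object of class `tanh_fit`: fitted `y0`, `y1`, `m`, `b`,
#'   derived `b_prime = b/m`, `initial_level = y0 - y1*tanh(b)`,
#'   `target_level = y0 + y1`, `rss`, and `converged`. Use [tidy()] /
#'   [glance()] for tibble views and [autoplot()] to inspect the fit.
#' @export
#' @examples
#' d <- tibble::tibble(day = seq(0, 50, 5),
#'                     level = eval_tanh(30, 20, 0.2, 2, seq(0, 50, 5)))
#' fit <- fit_tanh(d, level = "level")
#' tidy(fit)
fit_tanh <- function(data, day = "day", level = "methylation_pct") {
  t <- as.numeric(data[[day]])
  y <- as.numeric(data[[level]])
  ok <- stats::complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 5) abort("at least 5 time points are required.")
  if (diff(range(t)) <= 0) abort("all sampling days are identical.")
  ord <- order(t)
  t <- t[ord]; y <- y[ord]

  start <- tanh_start(t, y)
  slack <- 10
  lower <- c(y0 = -slack, y1 = 1e-4, m = 1e-4, b = -20)
  upper <- c(y0 = 100 + slack, y1 = 100 + slack, m = 10, b = 60)
  starts <- list(
    start,
    replace(start, c("m", "b"), c(start[["m"]] * 0.3, start[["b"]] * 0.3)),
    replace(start, c("m", "b"), c(start[["m"]] * 3, start[["b"]] * 3)),
    replace(start, c("m", "b"), c(start[["m"]], 0))
  )
  rss_of <- function(p) sum((y - eval_tanh(p[1], p[2], p[3], p[4], t))^2)

  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + y1 * tanh(m * t - b),
        start = as.list(s), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    p <- coef(fit)
    cand <- list(par = p, rss = rss_of(p))
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }

  init_rss <- rss_of(start)
  if (is.null(best) || best$rss > init_rss) {
    best <- list(par = start, rss = init_rss, failed = is.null(best))
  }
  p <- best$par
  on_bound <- p[["m"]] <= lower[["m"]] * 1.01 || p[["y1"]] <= lower[["y1"]] * 1.01 ||
    p[["m"]] >= upper[["m"]] * 0.999 || p[["b"]] >= upper[["b"]] * 0.999
  converged <- !isTRUE(best$failed) && !on_bound &&
    p[["m"]] > 0 && p[["y1"]] > 0

  structure(
    list(
      y0 = unname(p[["y0"]]), y1 = unname(p[["y1"]]),
      m = unname(p[["m"]]), b = unname(p[["b"]]),
      b_prime = unname(p[["b"]] / p[["m"]]),
      initial_level = unname(p[["y0"]] - p[["y1"]] * tanh(p[["b"]])),
      target_level = unname(p[["y0"]] + p[["y1"]]),
      rss = best$rss, init_rss = init_rss,
      converged = converged,
      n = length(t),
      data = tibble::tibble(day = t, methylation_pct = y)
    ),
    class = "tanh_fit"
  )
}

# Data-driven starting values for the tanh fit.
tanh_start <- function(t, y) {
  y0 <- mean(y)
  y1 <- max(diff(range(y)) / 2, 0.5)
  slopes <- diff(y) / diff(t)
  m <- max(max(slopes, na.rm = TRUE), 1e-3) / y1
  m <- min(max(m, 1e-3), 5)
  half <- min(y) + diff(range(y)) / 2
  i <- which(y >= half)[1]
  t_half <- if (is.na(i)) stats::median(t) else t[i]
  c(y0 = y0, y1 = y1, m = m, b = m * t_half)
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat(sprintf(
    "<tanh_fit> %s | y0 = %.2f, y1 = %.2f, m = %.4f /d, b = %.3f (b' = %.2f d), rss = %.3g, n = %d\n",
    if (x$converged) "converged" else "NOT converged",
    x$y0, x$y1, x$m, x$b, x$b_prime, x$rss, x$n
  ))
  invisible(x)
}

#' @rdname fit_tanh
#' @param x A `tanh_fit` object.
#' @param ... Unused.
#' @method tidy tanh_fit
#' @export
tidy.tanh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "y1", "m", "b", "b_prime", "initial_level", "target_level"),
    estimate = c(x$y0, x$y1, x$m, x$b, x$b_prime,
                 x$initial_level, x$target_level)
  )
}

#' @rdname fit_tanh
#' @method glance tanh_fit
#' @export
glance.tanh_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged, n = x$n,
    m = x$m, b_prime = x$b_prime
  )
}

#' @rdname fit_tanh
#' @param object A `tanh_fit` object.
#' @method autoplot tanh_fit
#' @export
autoplot.tanh_fit <- function(object, ...) {
  grid <- tibble::tibble(
    day = seq(min(object$data$day), max(object$data$day), length.out = 200)
  )
  grid$fit <- eval_tanh(object$y0, object$y1, object$m, object$b, grid$day)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$day, .data$methylation_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "Days post-treatment", y = "Methylation (%)")
}
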