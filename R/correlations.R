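default_screen_quantities <- c(
  "m", "b", "b_prime", "y0", "y1", "target",
  "B", "A", "rel_drop", "L", "rel_final"
)

# Two-sided p-value from the t transform t = r * sqrt((n-2)/(1-r^2))
# on n-2 degrees of freedom; |r| = 1 gives p = 0 by convention.
cor_t_pvalue <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

# One pair: Pearson (t-based p), Spearman on average ranks (t-transform
# p by default, AS89 exact optionally for small n), OLS slope/intercept.
correlate_pair <- function(x, y, spearman_exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(
      n = n, pearson_r = NA_real_, p_pearson = NA_real_,
      spearman_rho = NA_real_, p_spearman = NA_real_,
      slope = NA_real_, intercept = NA_real_, sign = NA_character_,
      defined = FALSE
    ))
  }
  r <- cor(x, y)
  rho <- cor(rank(x), rank(y))
  p_sp <- if (spearman_exact && n <= 10) {
    stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    cor_t_pvalue(rho, n)
  }
  fit <- lm(y ~ x)
  tibble::tibble(
    n = n,
    pearson_r = r, p_pearson = cor_t_pvalue(r, n),
    spearman_rho = rho, p_spearman = p_sp,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    sign = if (r >= 0) "+" else "-",
    defined = TRUE
  )
}

#' Pairwise correlation screen over run quantities
#'
#' For every unordered pair of the requested quantities, computes the
#' Pearson correlation with a two-sided p-value from the t statistic
#' `r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, the
#' Spearman rank correlation on average ranks with a two-sided p-value
#' from the same t transform, and the ordinary least-squares slope and
#' intercept of the second quantity on the first. Diagonal pairs are
#' reported with `r = 1, p = 0`. Pairs with fewer than 4 complete
#' observations or a constant column are flagged `defined = FALSE`
#' rather than dropped. A Benjamini-Hochberg adjusted Pearson p-value
#' (`p_pearson_bh`, over the off-diagonal pairs) is appended as a
#' labelled extension; the screen itself reports raw p-values.
#'
#' @param runs Tibble of successful runs (see
#'   [fit_methylation_panel()]); rows with `status != "successful"` are
#'   removed if a `status` column is present.
#' @param quantities Character vector of column names to screen.
#' @param spearman_exact Use the exact small-sample Spearman p-value
#'   (only applied when `n <= 10`).
#' @return A tibble with one row per unordered pair (diagonal
#'   included): `var1`, `var2`, `n`, `pearson_r`, `p_pearson`,
#'   `spearman_rho`, `p_spearman`, `slope`, `intercept`, `sign`,
#'   `defined`, `p_pearson_bh`.
#' @export
#' @examples
#' panel <- simulate_methylation_panel(panel_config(seed = 7))
#' runs <- fit_methylation_panel(panel)
#' screen <- pairwise_correlations(runs)
#' dplyr::filter(screen, var1 == "m", var2 == "B")
pairwise_correlations <- function(runs,
                                  quantities = default_screen_quantities,
                                  spearman_exact = FALSE) {
  if ("status" %in% names(runs)) {
    runs <- dplyr::filter(runs, .data$status == "successful")
  }
  missing_q <- setdiff(quantities, names(runs))
  if (length(missing_q) > 0) {
    abort(paste0("quantities not present in `runs`: ",
                 paste(missing_q, collapse = ", ")))
  }
  pairs <- tidyr::expand_grid(
    i = seq_along(quantities), j = seq_along(quantities)
  ) |>
    dplyr::filter(.data$i <= .data$j)

  res <- purrr::pmap(pairs, function(i, j) {
    v1 <- quantities[i]; v2 <- quantities[j]
    if (i == j) {
      n_ok <- sum(stats::complete.cases(runs[[v1]]))
      out <- tibble::tibble(
        n = n_ok, pearson_r = 1, p_pearson = 0,
        spearman_rho = 1, p_spearman = 0,
        slope = 1, intercept = 0, sign = "+", defined = TRUE
      )
    } else {
      out <- correlate_pair(runs[[v1]], runs[[v2]],
                            spearman_exact = spearman_exact)
    }
    dplyr::bind_cols(tibble::tibble(var1 = v1, var2 = v2), out)
  }) |>
    purrr::list_rbind()

  off <- res$var1 != res$var2
  res$p_pearson_bh <- NA_real_
  res$p_pearson_bh[off] <- stats::p.adjust(res$p_pearson[off], method = "BH")
  res
}

#' Square p-value grid with sign annotations
#'
#' Arranges the pairwise Pearson p-values as a symmetric matrix with a
#' zero diagonal; cells below `alpha` carry the sign of their
#' correlation. Undefined pairs are `NA`.
#'
#' @param results Output of [pairwise_correlations()].
#' @param alpha Annotation threshold for significant cells.
#' @return An object of class `p_value_grid`: a list with the `p`
#'   matrix, the `sign` character matrix (`"+"`/`"-"` below `alpha`,
#'   `""` otherwise) and `alpha`. Supports `as.matrix()`,
#'   `as_tibble()`/`as.data.frame()` (long format), [autoplot()] and
#'   [write_p_value_grid()].
#' @export
p_value_grid <- function(results, alpha = 0.05) {
  vars <- unique(c(results$var1, results$var2))
  k <- length(vars)
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  s <- matrix("", k, k, dimnames = list(vars, vars))
  for (row in seq_len(nrow(results))) {
    i <- match(results$var1[row], vars)
    j <- match(results$var2[row], vars)
    p[i, j] <- p[j, i] <- results$p_pearson[row]
    sig <- !is.na(results$p_pearson[row]) && results$p_pearson[row] < alpha
    s[i, j] <- s[j, i] <- if (sig) results$sign[row] else ""
  }
  diag(p) <- 0
  diag(s) <- ""
  structure(list(p = p, sign = s, alpha = alpha), class = "p_value_grid")
}

#' @export
as.matrix.p_value_grid <- function(x, ...) x$p

#' @export
as.data.frame.p_value_grid <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' @importFrom tibble as_tibble
#' @method as_tibble p_value_grid
#' @export
as_tibble.p_value_grid <- function(x, ...) {
  vars <- rownames(x$p)
  tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::mutate(
      p = as.vector(t(x$p)),
      sign = as.vector(t(x$sign))
    )
}

#' @export
print.p_value_grid <- function(x, ...) {
  cat(sprintf("<p_value_grid> %d x %d, %d cells below alpha = %g\n",
              nrow(x$p), ncol(x$p),
              sum(x$sign != "") / 2, x$alpha))
  print(round(x$p, 4))
  invisible(x)
}

#' @rdname p_value_grid
#' @param object A `p_value_grid`.
#' @param ... Unused.
#' @method autoplot p_value_grid
#' @export
autoplot.p_value_grid <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      var1 = factor(.data$var1, levels = rownames(object$p)),
      var2 = factor(.data$var2, levels = rev(rownames(object$p))),
      label = ifelse(.data$sign != "",
                     paste0(.data$sign, "\n", signif(.data$p, 2)), "")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2,
                                   fill = -log10(.data$p + 1e-12))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname p_value_grid
#' @param grid A `p_value_grid`.
#' @param path Output CSV path (square layout, row names in the first
#'   column).
#' @export
write_p_value_grid <- function(grid, path) {
  df <- data.frame(quantity = rownames(grid$p), grid$p,
                   check.names = FALSE)
  readr::write_csv(df, path)
  invisible(grid)
}

#' Per-cell-line means of run quantities
#'
#' Arithmetic mean of each quantity per cell line over its successful
#' runs, with the run count.
#'
#' @param runs Run summaries; rows with `status != "successful"` are
#'   removed if a `status` column is present.
#' @param quantities Columns to average.
#' @return A tibble, one row per cell line.
#' @export
aggregate_by_cell_line <- function(runs,
                                   quantities = intersect(
                                     default_screen_quantities, names(runs)
                                   )) {
  if ("status" %in% names(runs)) {
    runs <- dplyr::filter(runs, .data$status == "successful")
  }
  runs |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      cimp = if ("cimp" %in% names(runs)) .data$cimp[1] else NA,
      dplyr::across(dplyr::all_of(quantities), mean),
      .groups = "drop"
    )
}

#' Headline correlation tests
#'
#' Extracts the four named results from the pairwise screen: rate vs
#' baseline (`m` vs `B`), onset vs baseline (`b` vs `B`), rate vs onset
#' (`m` vs `b`), and delay vs baseline (`b_prime` vs `B`).
#'
#' @inheritParams pairwise_correlations
#' @return A tibble of four `CorrelationResult` rows with a `label`
#'   column.
#' @export
headline_tests <- function(runs) {
  screen <- pairwise_correlations(
    runs, quantities = intersect(c("m", "b", "b_prime", "B"), names(runs))
  )
  wanted <- tibble::tribble(
    ~var1, ~var2, ~label,
    "m", "B", "rate vs baseline",
    "b", "B", "onset vs baseline",
    "m", "b", "rate vs onset",
    "b_prime", "B", "delay vs baseline"
  )
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  screen$.key <- key(screen$var1, screen$var2)
  wanted$.key <- key(wanted$var1, wanted$var2)
  dplyr::inner_join(wanted, dplyr::select(screen, -"var1", -"var2"),
                    by = ".key") |>
    dplyr::select(-".key")
}
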