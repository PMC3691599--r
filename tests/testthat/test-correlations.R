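screen_of <- function(df, ...) pairwise_correlations(df, ...)

test_that("perfect affine relations give r = rho = 1 with exact slope", {
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  res <- screen_of(df, quantities = c("x", "y"))
  row <- dplyr::filter(res, var1 == "x", var2 == "y")
  expect_equal(row$pearson_r, 1)
  expect_equal(row$spearman_rho, 1)
  expect_equal(row$p_pearson, 0)
  expect_equal(row$slope, 2)
  expect_equal(row$intercept, 1)
})

test_that("spearman matches the hand-evaluated rank-difference formula", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  row <- dplyr::filter(screen_of(df, quantities = c("x", "y")),
                       var1 == "x", var2 == "y")
  expect_equal(row$spearman_rho, 1 - 6 * 4 / (5 * 24))  # 0.8
})

test_that("monotone nonlinear relations: rho = 1 while pearson < 1", {
  df <- tibble::tibble(x = c(-2, -1, 0, 1, 2), y = c(-2, -1, 0, 1, 2)^3)
  row <- dplyr::filter(screen_of(df, quantities = c("x", "y")),
                       var1 == "x", var2 == "y")
  expect_equal(row$spearman_rho, 1)
  expect_lt(row$pearson_r, 1)
})

test_that("pearson p matches stats::cor.test and spearman uses the t transform", {
  set.seed(9)
  x <- rnorm(18); y <- -0.5 * x + rnorm(18)
  row <- dplyr::filter(
    screen_of(tibble::tibble(x = x, y = y), quantities = c("x", "y")),
    var1 == "x", var2 == "y"
  )
  ct <- cor.test(x, y)
  expect_equal(row$pearson_r, unname(ct$estimate))
  expect_equal(row$p_pearson, ct$p.value)
  rho <- cor(rank(x), rank(y))
  tt <- rho * sqrt(16 / (1 - rho^2))
  expect_equal(row$p_spearman, 2 * pt(-abs(tt), 16))
})

test_that("rank and affine invariances hold", {
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- dplyr::filter(
    screen_of(tibble::tibble(x = x, y = y), quantities = c("x", "y")),
    var1 == "x", var2 == "y"
  )
  # strictly monotone transform of y leaves spearman unchanged
  mono <- dplyr::filter(
    screen_of(tibble::tibble(x = x, y = exp(y)), quantities = c("x", "y")),
    var1 == "x", var2 == "y"
  )
  expect_equal(mono$spearman_rho, base$spearman_rho)
  # positive affine transform leaves pearson unchanged
  aff <- dplyr::filter(
    screen_of(tibble::tibble(x = 3 * x + 7, y = y), quantities = c("x", "y")),
    var1 == "x", var2 == "y"
  )
  expect_equal(aff$pearson_r, base$pearson_r, tolerance = 1e-12)
})

test_that("constant columns and short pairs are flagged, not zeroed", {
  df <- tibble::tibble(x = 1:6, y = rep(2, 6), z = c(1, 2, NA, NA, NA, NA))
  res <- screen_of(df, quantities = c("x", "y", "z"))
  xy <- dplyr::filter(res, var1 == "x", var2 == "y")
  expect_false(xy$defined)
  expect_true(is.na(xy$pearson_r))
  xz <- dplyr::filter(res, var1 == "x", var2 == "z")
  expect_false(xz$defined)
})

test_that("the p-value grid is symmetric with a zero diagonal and signed cells", {
  truth <- panel_truth(small_panel(seed = 5))
  runs <- dplyr::mutate(truth, B = baseline_pct)
  res <- pairwise_correlations(runs, quantities = c("m", "b", "b_prime", "B"))
  grid <- p_value_grid(res)
  M <- as.matrix(grid)
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_equal(grid$sign["m", "B"], "-")
  expect_s3_class(autoplot(grid), "ggplot")
  long <- tibble::as_tibble(grid)
  expect_equal(nrow(long), 16)
  f <- withr::local_tempfile(fileext = ".csv")
  write_p_value_grid(grid, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$m, unname(M[, "m"]))
})

test_that("planted panels light up the rate-baseline cell with a negative sign", {
  fits <- fit_methylation_panel(small_panel(seed = 7))
  res <- pairwise_correlations(fits)
  grid <- p_value_grid(res)
  expect_lt(as.matrix(grid)["m", "B"], 0.05)
  expect_equal(grid$sign["m", "B"], "-")
})

test_that("per-cell-line aggregation averages successful runs", {
  runs <- tibble::tibble(
    cell_line = c("a", "a", "b"),
    status = c("successful", "successful", "successful"),
    m = c(0.1, 0.3, 0.5),
    B = c(10, 20, 30)
  )
  agg <- aggregate_by_cell_line(runs, quantities = c("m", "B"))
  expect_equal(agg$m, c(0.2, 0.5))
  expect_equal(agg$n_runs, c(2L, 1L))
})

test_that("non-CIMP lines show higher mean rates than CIMP lines", {
  fits <- fit_methylation_panel(small_panel(seed = 7))
  agg <- aggregate_by_cell_line(fits)
  expect_gt(mean(agg$m[!agg$cimp]), mean(agg$m[agg$cimp]))
})

test_that("headline tests recover the planted directions", {
  fits <- fit_methylation_panel(small_panel(seed = 7))
  hl <- headline_tests(fits)
  expect_equal(nrow(hl), 4)
  expect_equal(hl$sign[hl$label == "rate vs baseline"], "-")
  expect_equal(hl$sign[hl$label == "rate vs onset"], "+")
  expect_true(all(hl$n == sum(fits$status == "successful")))
})

test_that("null panels give well-behaved p-values", {
  set.seed(31)
  ps <- replicate(200, {
    df <- tibble::tibble(x = rnorm(18), y = rnorm(18))
    dplyr::filter(screen_of(df, quantities = c("x", "y")),
                  var1 == "x", var2 == "y")$p_pearson
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
  expect_gt(mean(abs(ps - 0.5) < 0.45), 0.8)
})
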