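test_that("fit_standard_curve recovers an exact dilution line", {
  std <- tibble::tibble(quantity = 10^(0:4), ct = 40 - 3.32 * (0:4))
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, -3.32, tolerance = 1e-12)
  expect_equal(curve$intercept, 40, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(tidy(curve)$estimate, c(40, -3.32), tolerance = 1e-12)
  expect_error(fit_standard_curve(std[1:2, ]), "3 distinct")
  expect_error(
    fit_standard_curve(tibble::tibble(quantity = c(10, 10, 10),
                                      ct = c(30, 31, 32))),
    "3 distinct"
  )
  expect_error(
    fit_standard_curve(tibble::tibble(quantity = c(-1, 10, 100),
                                      ct = c(30, 25, 20))),
    "positive"
  )
})

test_that("fit_standard_curve matches the closed-form OLS solution on noisy points", {
  q <- c(1, 10, 100, 1000)
  ct <- c(39.8, 36.9, 33.2, 30.1)
  x <- log10(q)
  slope_hat <- sum((x - mean(x)) * (ct - mean(ct))) / sum((x - mean(x))^2)
  intercept_hat <- mean(ct) - slope_hat * mean(x)
  curve <- fit_standard_curve(tibble::tibble(quantity = q, ct = ct))
  expect_equal(curve$slope, slope_hat, tolerance = 1e-12)
  expect_equal(curve$intercept, intercept_hat, tolerance = 1e-12)
})

test_that("quantify inverts the curve and normalization is symmetric", {
  std <- simulate_standards()
  curve <- fit_standard_curve(std)
  expect_equal(quantify(curve$intercept, curve), 1)
  expect_equal(quantify(curve$intercept + curve$slope * 1, curve), 10)
  # Ct -> quantity -> Ct round trip
  qty <- c(0.5, 3, 250, 1e4)
  ct <- curve$intercept + curve$slope * log10(qty)
  expect_equal(quantify(ct, curve), qty, tolerance = 1e-9)
  # identical Ct on identical curves -> expression ratio 1
  coh <- tibble::tibble(goi_ct = 30, gapdh_ct = 30)
  expect_equal(add_expression(coh, curve, curve)$expression, 1)
})

test_that("dichotomize applies the median quartile rule with ties going low", {
  g <- dichotomize(1:8)
  expect_equal(as.character(g), rep(c("low", "high"), each = 4))
  g <- dichotomize(c(1, 1, 1, 9))
  expect_equal(sum(g == "high"), 1L)
  expect_equal(sum(g == "low"), 3L)
  withr::with_seed(1, {
    v <- rnorm(60)
    expect_equal(as.vector(table(dichotomize(v))), c(30L, 30L))
  })
  expect_error(dichotomize(rep(2, 10)), "identical")
  expect_error(dichotomize(c(1, 2)), "at least 4")
  # explicit cutoff reproduces unequal splits
  g <- dichotomize(1:20, cutoff = 15)
  expect_equal(sum(g == "high"), 5L)
})

test_that("chi-square association matches hand-worked contingency tables", {
  g <- rep(c("a", "b"), each = 10)
  balanced <- test_categorical(g, rep(c("x", "y"), 10))
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p_value, 1)

  perfect <- test_categorical(g, rep(c("x", "y"), each = 10))
  expect_equal(perfect$statistic, 20)
  expect_equal(perfect$p_value, 7.744216e-06, tolerance = 1e-6)
  expect_equal(perfect$summary[[1]]$percent, c(0, 100))

  # Pearson statistic doubles when every cell doubles
  gg <- rep(c("a", "b"), c(12, 8))
  ff <- c(rep(c("x", "y"), c(9, 3)), rep(c("x", "y"), c(2, 6)))
  one <- test_categorical(gg, ff)
  two <- test_categorical(rep(gg, 2), rep(ff, 2))
  expect_equal(two$statistic, 2 * one$statistic, tolerance = 1e-12)

  expect_error(test_categorical(rep("a", 10), rep(c("x", "y"), 5)),
               "two levels")
  expect_error(
    test_categorical(factor(g, levels = c("a", "b", "c")), rep("x", 20)),
    "two levels|zero margin"
  )
})

test_that("Mann-Whitney uses exact enumeration for tiny groups", {
  res <- test_continuous(rep(c("a", "b"), each = 3), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2/20 orderings are as extreme
  expect_equal(res$summary[[1]]$median, c(2, 5))

  sym <- test_continuous(rep(c("a", "b"), each = 4),
                         c(10, 20, 30, 40, 40, 30, 20, 10))
  expect_equal(sym$p_value, 1)
  expect_error(test_continuous(rep("a", 5), 1:5), "two levels")
})

test_that("exact and normal-approximation branches agree at the boundary", {
  withr::with_seed(42L, {
    v <- rnorm(16)
    g <- rep(c("a", "b"), each = 8)
    exact_p <- test_continuous(g, v)$p_value # 8 vs 8, no ties -> exact
    approx_p <- suppressWarnings(
      wilcox.test(v[1:8], v[9:16], exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(exact_p, approx_p, tolerance = 0.05)
  })
})

test_that("the simulated cohort pipeline is calibrated under the null and powered under shift", {
  std <- simulate_standards()
  goi_curve <- fit_standard_curve(std)
  gapdh_curve <- goi_curve

  run <- function(seed, effect) {
    cfg <- simulation_config(seed = seed, cohort_n = 60L, effect_size = effect)
    coh <- add_expression(simulate_cohort(cfg), goi_curve, gapdh_curve)
    test_continuous(coh$phenotype, coh$expression)$p_value
  }
  null_p <- vapply(1:200, run, numeric(1), effect = 0)
  expect_gt(mean(null_p < 0.05), 0.01)
  expect_lt(mean(null_p < 0.05), 0.10)

  shift_p <- vapply(1:100, run, numeric(1), effect = 1)
  expect_gt(mean(shift_p < 0.05), 0.85)
})

test_that("associate screens mixed covariates against the expression group", {
  cfg <- simulation_config(seed = 12L, cohort_n = 60L, effect_size = 1.5)
  std <- simulate_standards()
  curve <- fit_standard_curve(std)
  coh <- add_expression(simulate_cohort(cfg), curve, curve)
  coh$group <- dichotomize(coh$expression)
  res <- associate(coh, group, covariates = c("phenotype", "expression"))
  expect_equal(res$test, c("chi_square", "mann_whitney"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # a 1.5-SD planted shift should be detected by both routes
  expect_lt(res$p_value[2], 0.01)
})
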