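test_that("welch_t_test handles identical and degenerate groups", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  sep <- welch_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_lt(sep$p_value, 1e-6)

  eq <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(eq$p_value, 1)

  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  expect_error(welch_t_test(c(1, NA, 2), c(1, 2)), "non-finite")
})

test_that("welch_t_test matches the closed-form Welch/Satterthwaite formulas", {
  x <- c(1.1, 2.3, 1.9, 2.5); y <- c(3.2, 4.1, 3.8)
  # independent oracle: the textbook formulas evaluated directly
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_exp <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_exp <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  r <- welch_t_test(x, y)
  expect_equal(r$statistic, t_exp, tolerance = 1e-10)
  expect_equal(r$df, df_exp, tolerance = 1e-10)
  expect_equal(r$p_value, p_exp, tolerance = 1e-10)
})

test_that("row-wise Welch screen agrees with the scalar test", {
  set.seed(5)
  mat <- matrix(rnorm(200), 20, 10,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  res <- codsig:::row_welch_t(mat, rep(c(TRUE, FALSE), each = 5))
  for (i in c(1, 7, 20)) {
    ref <- welch_t_test(mat[i, 1:5], mat[i, 6:10])
    expect_equal(res$statistic[i], ref$statistic, tolerance = 1e-12)
    expect_equal(res$p_value[i], ref$p_value, tolerance = 1e-12)
  }
})

test_that("welch_t_test p-values are uniform under the null", {
  set.seed(77)
  mat <- matrix(rnorm(10000 * 20), 10000, 20,
                dimnames = list(sprintf("g%d", 1:10000), sprintf("s%d", 1:20)))
  p <- codsig:::row_welch_t(mat, rep(c(TRUE, FALSE), each = 10))$p_value
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("fisher_exact_two_sided matches hand-computable tables", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5)$p_value, 1)
  # fully separated 10/10 table: only the observed table and its mirror are
  # as extreme, each with probability 1/C(20,10)
  r <- fisher_exact_two_sided(10, 0, 0, 10)
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r$extra$continuity)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_two_sided(1.5, 0, 0, 1), "integers")
})

test_that("fisher_exact_two_sided equals exhaustive enumeration on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tot <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, tot, runif(4, 0.05, 1)))
    if (sum(cells) == 0) next
    got <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("chi_square_test matches the Pearson formula and is permutation-invariant", {
  ind <- outer(c(10, 20), c(3, 7)) / 10 # proportional to margins
  r0 <- chi_square_test(round(ind) * 10)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  r <- suppressWarnings(chi_square_test(tab))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12) # hand Pearson sum
  expect_equal(r$df, 1)

  tab3 <- matrix(c(8, 2, 5, 5, 1, 9), 3, byrow = TRUE)
  a <- suppressWarnings(chi_square_test(tab3))
  b <- suppressWarnings(chi_square_test(tab3[c(3, 1, 2), c(2, 1)]))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  expect_warning(chi_square_test(matrix(c(2, 3, 3, 2), 2)), "below 5")
  expect_error(chi_square_test(matrix(0, 2, 2)), "zero grand total")
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5, 3, 7), 3, byrow = TRUE)),
               "zero row")
})

test_that("point_biserial equals Pearson correlation with the 0/1 coding", {
  b <- c(0, 0, 0, 1, 1, 1, 1, 0)
  x <- c(1.2, 0.8, 1.1, 2.3, 2.9, 2.4, 2.2, 1.0)
  r <- point_biserial(b, x)
  expect_equal(r$effect, cor(x, b), tolerance = 1e-12)
  expect_equal(point_biserial(b, as.numeric(b))$effect, 1)
  expect_equal(point_biserial(b, rep(3, 8))$effect, 0)
  expect_error(point_biserial(rep(1, 5), rnorm(5)), "both classes")
  # latent-normal variant scales the point-biserial r upward
  expect_gt(abs(point_biserial(b, x, latent = TRUE)$effect), abs(r$effect))
  # r always in [-1, 1]
  set.seed(8)
  for (i in 1:50) {
    bb <- rbinom(12, 1, 0.5)
    if (length(unique(bb)) < 2) next
    expect_lte(abs(point_biserial(bb, rnorm(12))$effect), 1)
  }
})

test_that("log2_fold_difference converts log2 means to linear folds", {
  expr <- tiny_expr(rbind(c(5, 5, 6, 6), c(4, 4, 4, 4)), c("gA", "gB"),
                    c("s1", "s2", "s3", "s4"))
  expect_equal(log2_fold_difference(expr, "gB", c("s1", "s2"), c("s3", "s4")), 1)
  expect_equal(log2_fold_difference(expr, "gA", c("s3", "s4"), c("s1", "s2")), 2)
  expect_error(log2_fold_difference(expr, "gZ", "s1", "s2"), "unknown gene")
  expect_error(log2_fold_difference(expr, "gA", c("s1", "s2"), c("s2", "s3")),
               "disjoint")
})

test_that("a planted fold difference is recovered from the generator", {
  cfg <- simulation_config(n_genes = 300, n_int_module = 20, n_cod_module = 30,
                           n_normal = 4, n_intestinal = 4, n_diffuse = 600,
                           diffuse_subtype_props = c(0, 0.5, 0.5),
                           effect_size = log2(5.04), noise_sd = 0.5, seed = 17)
  co <- simulate_cohort(cfg)
  lat <- co$truth$latent
  folds <- vapply(co$truth$cod_module_genes, function(g) {
    log2_fold_difference(co$expression, g,
                         lat$sample_id[lat$latent_class == "cod_like"],
                         lat$sample_id[lat$latent_class == "int_like"])
  }, 0)
  expect_lt(abs(median(folds) - 5.04), 0.4)
})
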