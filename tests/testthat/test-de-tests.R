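test_that("gene-wise OLS matches the hand-worked two-group example", {
  # groups of two: values (1,3) vs (2,6)
  x <- matrix(c(1, 3, 2, 6), 1, 4,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  d <- design_table(colnames(x), c("A", "A", "B", "B"))
  fit <- fit_gaussian(x, model_spec(d))
  expect_equal(unname(fit$coefficients[1, ]), c(2, 2)) # mean A, B - A
  expect_equal(unname(fit$rss_full), 2 + 8)
  expect_equal(fit$df_res, 2)
  # reduced RSS about the grand mean 3: 4 + 0 + 1 + 9 = 14
  expect_equal(unname(fit$rss_reduced), 14)
  f1 <- f_statistics(fit, "F1")
  expect_equal(as.numeric(f1), ((14 - 10) / 1) / (10 / 2)) # 0.8
})

test_that("OLS residuals are orthogonal to the design and shifts hit only the intercept", {
  set.seed(21)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  d <- design_table(colnames(x), rep(c("A", "B"), each = 4))
  spec <- model_spec(d)
  fit <- fit_gaussian(x, spec)
  res <- t(x) - spec$X_full %*% t(fit$coefficients)
  expect_lt(max(abs(crossprod(spec$X_full, res))), 1e-10)

  fit2 <- fit_gaussian(x + 5, spec)
  expect_equal(fit2$coefficients[, 1], fit$coefficients[, 1] + 5)
  expect_equal(fit2$coefficients[, 2], fit$coefficients[, 2])
})

test_that("moderated F collapses to F1 at the shrinkage boundaries", {
  # G = 3 genes: the James-Stein numerator (G - 3) vanishes
  set.seed(22)
  x <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:6)))
  d <- design_table(colnames(x), rep(c("A", "B"), each = 3))
  fit <- fit_gaussian(x, model_spec(d))
  expect_equal(as.numeric(f_statistics(fit, "Fs")),
               as.numeric(f_statistics(fit, "F1")), tolerance = 1e-12)

  # identical residual variances: full shrinkage to the common point
  x2 <- rbind(g1 = c(1, 3, 2, 6), g2 = c(11, 13, 12, 16),
              g3 = c(1, 3, 6, 2), g4 = c(0, 2, 5, 1))
  colnames(x2) <- sprintf("s%d", 1:4)
  d2 <- design_table(colnames(x2), c("A", "A", "B", "B"))
  fit2 <- fit_gaussian(x2, model_spec(d2))
  expect_true(sd(fit2$sigma2) < 1e-12)
  expect_equal(as.numeric(f_statistics(fit2, "Fs")),
               as.numeric(f_statistics(fit2, "F1")), tolerance = 1e-12)
})

test_that("tabulated F p-values are exact: p(0) = 1 and null uniformity", {
  set.seed(23)
  n_genes <- 5000
  x <- matrix(rnorm(n_genes * 8), n_genes, 8,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              sprintf("s%d", 1:8)))
  d <- design_table(colnames(x), rep(c("A", "B"), each = 4))
  fit <- fit_gaussian(x, model_spec(d))
  rt <- tabulated_pvalues(f_statistics(fit, "F1"), rownames(x))
  ks <- ks.test(rt$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_equal(median(qf(1 - rt$p_value, 1, 6)),
               qf(0.5, 1, 6), tolerance = 0.1)

  zero <- tabulated_pvalues(structure(0, df_num = 1, df_res = 6), "g1")
  expect_equal(zero$p_value, 1)
})

test_that("permutation p-values match exhaustive enumeration on small designs", {
  set.seed(24)
  x <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:4)))
  d <- design_table(colnames(x), c("A", "A", "B", "B"))
  sfn <- gaussian_stat_fn("F1")
  expect_warning(
    rt <- permutation_pvalues(sfn, x, d, n_perm = 100,
                              pool_across_genes = FALSE),
    "exhaustive")
  obs <- sfn(x, d)
  alt1 <- sfn(x, design_table(colnames(x), c("A", "B", "A", "B")))
  alt2 <- sfn(x, design_table(colnames(x), c("A", "B", "B", "A")))
  oracle <- (1 + (alt1 >= obs) + (alt2 >= obs)) / 3
  expect_equal(rt$p_value, oracle)

  # pooled variant against the same enumeration
  expect_warning(
    rtp <- permutation_pvalues(sfn, x, d, n_perm = 100,
                               pool_across_genes = TRUE),
    "exhaustive")
  pool <- c(alt1, alt2)
  oracle_pool <- vapply(obs, function(o) (1 + sum(pool >= o)) / (1 + 12), 0)
  expect_equal(rtp$p_value, oracle_pool)
})

test_that("permutation p-values are positive with add-one granularity", {
  set.seed(25)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  d <- design_table(colnames(x), rep(c("A", "B"), each = 5))
  rt <- permutation_pvalues(gaussian_stat_fn("F1"), x, d, n_perm = 50,
                            seed = 99)
  pool_size <- 20 * 50
  expect_true(all(rt$p_value >= 1 / (1 + pool_size)))
  expect_true(all(abs(rt$p_value * (1 + pool_size) -
                        round(rt$p_value * (1 + pool_size))) < 1e-9))

  # a permutation-invariant statistic gives p = 1 everywhere
  const_fn <- function(x, design) rep(1, nrow(x))
  rt2 <- permutation_pvalues(const_fn, x, d, n_perm = 50, seed = 1)
  expect_true(all(rt2$p_value == 1))
})

test_that("within-block restriction permutes labels only inside blocks", {
  set.seed(26)
  x <- matrix(rnorm(4 * 8), 4, 8,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:8)))
  d <- design_table(colnames(x), rep(c("A", "B"), 4),
                    block = rep(c("b1", "b2"), each = 4))
  probe <- function(x, design) {
    for (b in unique(design$block)) {
      tab <- table(design$treatment[design$block == b])
      stopifnot(all(tab == 2)) # balance preserved within each block
    }
    rnorm(nrow(x))
  }
  expect_silent(suppressWarnings(
    permutation_pvalues(probe, x, d, n_perm = 30, seed = 5)))
})

test_that("run_de_methods validates tags and returns one row per gene per method", {
  sim <- nb_two_group(n_genes = 60, n_per_group = 3, n_de = 10, seed = 31)
  expect_error(run_de_methods(sim$counts, sim$design, methods = "edger"),
               "valid tags", class = "pb_value_error")
  rt <- run_de_methods(sim$counts, sim$design,
                       methods = c("nb-lrt-tagwise", "gauss-F1-tab"),
                       seed = 1)
  expect_equal(nrow(rt), 2 * 60)
  expect_setequal(unique(rt$method), c("nb-lrt-tagwise", "gauss-F1-tab"))
  expect_true(all(rt$p_value >= 0 & rt$p_value <= 1, na.rm = TRUE))
})
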