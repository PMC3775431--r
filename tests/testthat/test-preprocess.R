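test_that("technical replicates sum into biological samples, conserving reads", {
  cm <- count_matrix(matrix(c(3L, 1L, 4L, 0L, 5L, 2L), 2, 3),
                     c("g1", "g2"), c("s1a", "s1b", "s2"))
  d <- design_table(c("s1a", "s1b", "s2"), c("A", "A", "B"),
                    bio_rep = c("b1", "b1", "b1"),
                    tech_rep = c("1", "2", "1"))
  out <- collapse_technical(cm, d)
  expect_equal(ncol(out$counts), 2)
  expect_equal(unname(out$counts[, 1]), c(3L + 4L, 1L + 0L))
  expect_equal(sum(out$counts), sum(cm))
  expect_true(all(out$design$tech_rep == "1"))

  # r = 1 is the identity
  single <- collapse_technical(tiny_counts(), tiny_design())
  expect_identical(single$counts, tiny_counts())
})

test_that("CPM filter applies the >= 2 CPM in >= n_bio libraries rule", {
  base <- matrix(1L, 4, 6) # keeps library sizes near 1e6 scale irrelevant
  m <- rbind(kept = c(2L, 2L, 2L, 0L, 0L, 0L),
             dropped = c(2L, 2L, 1L, 0L, 0L, 0L),
             zero = rep(0L, 6))
  # library sizes exactly 1e6 so count == CPM
  filler <- matrix(0L, 1, 6)
  filler[1, ] <- 1000000L - colSums(m)
  cm <- count_matrix(rbind(m, filler),
                     c("kept", "dropped", "zero", "filler"),
                     sprintf("s%d", 1:6))
  out <- filter_cpm(cm, n_bio = 3)
  expect_true("kept" %in% out$kept)
  expect_false("dropped" %in% out$kept)
  expect_false("zero" %in% out$kept)
})

test_that("CPM filter is monotone: adding reads never drops a kept gene", {
  set.seed(7)
  m <- matrix(rpois(300, 20), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  kept1 <- filter_cpm(count_matrix(m), 3)$kept
  m2 <- m
  m2[kept1[1], ] <- m2[kept1[1], ] + 50L
  kept2 <- filter_cpm(count_matrix(m2), 3)$kept
  expect_true(kept1[1] %in% kept2)
})

test_that("TMM factors are 1 for proportional columns and match the reference implementation", {
  set.seed(3)
  a <- rpois(500, 50) + 1L
  m <- cbind(s1 = a, s2 = 2L * a)
  rownames(m) <- sprintf("g%03d", seq_len(500))
  f <- tmm_factors(count_matrix(m))
  expect_equal(f$scale_factor, c(1, 1), tolerance = 1e-12)

  # identical columns
  m2 <- cbind(s1 = a, s2 = a)
  rownames(m2) <- rownames(m)
  expect_equal(tmm_factors(count_matrix(m2))$scale_factor, c(1, 1))

  # asymmetric enrichment, cross-checked against edgeR
  set.seed(11)
  m3 <- matrix(rnbinom(3000, mu = exp(rnorm(1000, 4, 1.5)), size = 5),
               1000, 3)
  m3[1:500, 2] <- m3[1:500, 2] * 4L
  dimnames(m3) <- list(sprintf("g%04d", 1:1000), c("s1", "s2", "s3"))
  ours <- tmm_factors(count_matrix(m3))$scale_factor
  ref <- unname(edgeR::calcNormFactors(m3, method = "TMM"))
  expect_equal(ours, ref, tolerance = 1e-6)
  expect_equal(exp(mean(log(ours))), 1, tolerance = 1e-12)
})

test_that("TMM and size factors are invariant to gene order, equivariant to sample order", {
  set.seed(5)
  m <- matrix(rpois(600, 40) + 1L, 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  cm <- count_matrix(m)
  perm <- sample(nrow(m))
  expect_equal(tmm_factors(cm)$scale_factor,
               tmm_factors(cm[perm, ])$scale_factor)
  sperm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(tmm_factors(cm)$scale_factor[sperm],
               tmm_factors(cm[, sperm])$scale_factor)
  expect_equal(size_factors_median_ratio(cm)$size_factor[sperm],
               size_factors_median_ratio(cm[, sperm])$size_factor)
})

test_that("median-of-ratios size factors match hand computation and scale equivariantly", {
  cm <- count_matrix(matrix(c(2L, 6L, 4L, 12L), 2, 2),
                     c("g1", "g2"), c("s1", "s2"))
  sf <- size_factors_median_ratio(cm)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(9)
  m <- matrix(rpois(400, 30) + 1L, 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
  s1 <- size_factors_median_ratio(count_matrix(m))$size_factor
  m2 <- m; m2[, 2] <- m2[, 2] * 3L
  s2 <- size_factors_median_ratio(count_matrix(m2))$size_factor
  # ratio-based factors are scale-equivariant up to the overall gene-wise
  # geometric mean: scaling one column by c scales its factor relative to
  # any other column by exactly c
  expect_equal(s2[2] / s2[1], 3 * s1[2] / s1[1], tolerance = 1e-12)

  expect_error(size_factors_median_ratio(
    count_matrix(matrix(c(0L, 1L, 1L, 0L), 2, 2), c("g1", "g2"),
                 c("s1", "s2"))), class = "pb_value_error")
})

test_that("log2-CPM follows the prior/effective-size convention and stays finite", {
  cm <- count_matrix(matrix(c(0L, 10L), 1, 2), "g1", c("s1", "s2"))
  norm <- data.frame(sample_id = c("s1", "s2"),
                     library_size = c(999999, 999999),
                     scale_factor = 1,
                     effective_library_size = c(999999, 999999))
  x <- log2_cpm(cm, norm)
  expect_equal(x[1, 1], log2(0.5), tolerance = 1e-12)
  # monotone in counts, increment < 1 for a doubling, -> 1 as counts grow
  cm2 <- count_matrix(matrix(c(10L, 20L, 10000L, 20000L), 1, 4), "g1",
                      sprintf("s%d", 1:4))
  x2 <- log2_cpm(cm2, NULL)
  expect_true(all(is.finite(x2)))
  set.seed(2)
  big <- count_matrix(matrix(rpois(40, 1000), 10, 4,
                             dimnames = list(sprintf("g%02d", 1:10),
                                             sprintf("s%d", 1:4))))
  xb <- log2_cpm(big, tmm_factors(big))
  expect_true(all(is.finite(xb)))
})
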