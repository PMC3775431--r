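test_that("moment matching recovers known (mu, sigma2) at large n", {
  T <- 300; n <- 200
  params <- list(mu = matrix(rep(c(2, 2.7), each = T), T, 2),
                 sigma2 = rep(0.25, T),
                 truth = truth_table(sprintf("g%04d", 1:T), rep(TRUE, T),
                                     rep(0.7, T)))
  cfg <- sim_config(T = T, n = n, r = 1, p0 = 1, offset_scheme = "equal",
                    target_depth = 1) # offsets log(1) = 0
  ds <- simulate_dataset(cfg, params, seed = 42)
  pool <- estimate_parameters(ds$counts, ds$design, offsets = rep(0, 2 * n))
  expect_lt(abs(mean(pool$mu[, 1]) - 2), 0.05)
  expect_lt(abs(mean(pool$mu[, 2]) - 2.7), 0.05)
  expect_lt(abs(mean(pool$sigma2) - 0.25), 0.05)
})

test_that("pure Poisson data yield near-zero sigma2 and zero-mean genes are dropped", {
  set.seed(6)
  T <- 500; n <- 100
  y <- matrix(rpois(T * 2 * n, 20), T, 2 * n,
              dimnames = list(sprintf("g%04d", 1:T),
                              sprintf("s%03d", 1:(2 * n))))
  y[1, 1:n] <- 0L # one group all zero -> dropped from pool
  d <- design_table(colnames(y), rep(c("A", "B"), each = n))
  pool <- estimate_parameters(count_matrix(y), d, offsets = rep(0, 2 * n))
  expect_false("g0001" %in% pool$gene_id)
  expect_lt(mean(pool$sigma2), 0.01) # clipped-at-zero excess variance

  d1 <- design_table(colnames(y)[1:3], c("A", "A", "B"))
  expect_error(estimate_parameters(count_matrix(y[, 1:3]), d1,
                                   offsets = rep(0, 3)),
               class = "pb_value_error")
})

test_that("truth sampling fixes DE counts exactly and zeroes S0 differences", {
  pool <- make_parameter_pool(n_genes = 6000, seed = 1)
  st <- sample_truth(pool, 5000, 0.1, seed = 2)
  expect_equal(sum(st$truth$is_de), 500)
  expect_equal(sum(!st$truth$is_de), 4500)
  s0 <- !st$truth$is_de
  expect_true(all(st$mu[s0, 1] == st$mu[s0, 2]))
  s1 <- st$truth$is_de
  expect_equal(st$truth$true_log_effect[s1], st$mu[s1, 2] - st$mu[s1, 1])

  st0 <- sample_truth(pool, 100, 0, seed = 3)
  expect_true(all(!st0$truth$is_de))
  expect_true(all(st0$mu[, 1] == st0$mu[, 2]))

  # definitional check on a singleton pool
  p1 <- parameter_pool("x", matrix(c(1.0, 1.6), 1), 0.1)
  st1 <- sample_truth(p1, 1, 1, seed = 4)
  expect_equal(st1$truth$true_log_effect, 0.6)
})

test_that("simulated counts obey Poisson and lognormal-Poisson moments", {
  # sigma2 = 0, r = 1: variance/mean ratio near 1 across many draws
  draws <- 1e4
  params0 <- list(mu = matrix(3, draws, 2), sigma2 = rep(0, draws),
                  truth = truth_table(sprintf("g%05d", 1:draws),
                                      rep(FALSE, draws), rep(0, draws)))
  cfg <- sim_config(T = draws, n = 2, r = 1, p0 = 0, offset_scheme = "equal",
                    target_depth = 1)
  ds <- simulate_dataset(cfg, params0, seed = 5)
  y <- as.numeric(ds$counts) # 4e4 iid Poisson(e^3) draws
  expect_gt(var(y) / mean(y), 0.95)
  expect_lt(var(y) / mean(y), 1.05)

  # sigma2 = 0.25: mean N exp(mu + s2/2), var mean + (e^s2 - 1) mean^2
  s2 <- 0.25; mu <- 3
  params1 <- list(mu = matrix(mu, draws, 2), sigma2 = rep(s2, draws),
                  truth = params0$truth)
  ds1 <- simulate_dataset(cfg, params1, seed = 6)
  y1 <- as.numeric(ds1$counts)
  m_theory <- exp(mu + s2 / 2)
  v_theory <- m_theory + (exp(s2) - 1) * m_theory^2
  se_mean <- sqrt(v_theory / length(y1))
  expect_lt(abs(mean(y1) - m_theory), 3 * se_mean)
  # SE of the sample variance via fourth-moment bound from the sample
  se_var <- sd((y1 - mean(y1))^2) / sqrt(length(y1))
  expect_lt(abs(var(y1) - v_theory), 3 * se_var)
})

test_that("technical replicates share the sample residual and collapse to Poisson", {
  T <- 2000
  params <- list(mu = matrix(2.5, T, 2), sigma2 = rep(0.4, T),
                 truth = truth_table(sprintf("g%05d", 1:T), rep(FALSE, T),
                                     rep(0, T)))
  cfg <- sim_config(T = T, n = 3, r = 5, p0 = 0, offset_scheme = "equal",
                    target_depth = 1)
  ds <- simulate_dataset(cfg, params, seed = 7)
  expect_equal(ncol(ds$counts), 30)
  # technical replicates of one biological sample are positively correlated
  # through the shared residual; distinct biological samples are not
  same_bio <- cor(ds$counts[, 1], ds$counts[, 2])
  expect_gt(same_bio, 0.2)
  # summing the r technical columns of one biological sample: the
  # conditional law is Poisson(sum of rates), so var/mean of the sums,
  # rescaled by the mixing, matches the single-column lognormal-Poisson
  sums <- ds$counts[, 1:5] %*% rep(1, 5)
  m_theory <- 5 * exp(2.5 + 0.4 / 2)
  v_theory <- m_theory + (exp(0.4) - 1) * m_theory^2
  expect_lt(abs(mean(sums) - m_theory), 4 * sqrt(v_theory / T))
})

test_that("rate overflow is surfaced as an error naming the gene", {
  params <- list(mu = matrix(c(800, 800), 1, 2), sigma2 = 0,
                 truth = truth_table("gBIG", FALSE, 0))
  cfg <- sim_config(T = 1, n = 2, r = 1, p0 = 0, offset_scheme = "equal",
                    target_depth = 1)
  expect_error(simulate_dataset(cfg, params, seed = 1), "gBIG",
               class = "pb_value_error")
})

test_that("the scenario grid enumerates 9 labelled cells deterministically", {
  pool <- make_parameter_pool(n_genes = 300, seed = 9)
  cfg <- sim_config(T = 50, K = 2, p0 = 0.1, seed = 123)
  cells <- simulate_scenarios(pool, cfg)
  expect_equal(length(cells), 9)
  expect_setequal(names(cells),
                  as.vector(outer(c(3, 5, 10), c(1, 3, 5),
                                  function(n, r) sprintf("n%d_r%d", n, r))))
  expect_equal(sum(vapply(cells, function(cl) length(cl$datasets), 0L)), 18)
  for (cl in cells) {
    for (ds in cl$datasets) {
      expect_equal(ncol(ds$counts), 2 * cl$n * cl$r)
      expect_equal(sum(ds$truth$is_de), floor(0.1 * 50))
    }
  }
  cells2 <- simulate_scenarios(pool, cfg)
  expect_identical(cells, cells2) # same master seed, bitwise-identical
})

test_that("pooled null counts fit the lognormal-Poisson law (chi-square GOF)", {
  draws <- 20000; mu <- 2; s2 <- 0.3
  params <- list(mu = matrix(mu, draws, 2), sigma2 = rep(s2, draws),
                 truth = truth_table(sprintf("g%05d", 1:draws),
                                     rep(FALSE, draws), rep(0, draws)))
  cfg <- sim_config(T = draws, n = 2, r = 1, p0 = 0, offset_scheme = "equal",
                    target_depth = 1)
  y <- as.numeric(simulate_dataset(cfg, params, seed = 11)$counts[, 1])
  kmax <- max(y)
  pmf <- vapply(0:kmax, function(k) {
    integrate(function(e) dpois(k, exp(mu + e)) * dnorm(e, 0, sqrt(s2)),
              -6 * sqrt(s2), 6 * sqrt(s2), rel.tol = 1e-9)$value
  }, 0)
  # pool the sparse tail so expected cell counts stay above 5
  obs <- tabulate(y + 1, nbins = kmax + 1)
  cut <- max(which(pmf * length(y) >= 5))
  obs_b <- c(obs[1:cut], sum(obs[-(1:cut)]))
  p_b <- c(pmf[1:cut], 1 - sum(pmf[1:cut]))
  gof <- chisq.test(obs_b, p = p_b / sum(p_b))
  expect_gt(gof$p.value, 0.05)
})
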