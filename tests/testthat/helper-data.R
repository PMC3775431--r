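# Small programmatic fixtures shared across test files.

tiny_counts <- function() {
  count_matrix(matrix(c(3L, 1L, 0L, 7L), 2, 2),
               gene_ids = c("g1", "g2"), sample_ids = c("s1", "s2"))
}

tiny_design <- function() {
  design_table(c("s1", "s2"), treatment = c("A", "B"))
}

# NB two-group dataset with known per-gene means and a planted effect on
# the tail genes; returns counts, design and the truth of the planting
nb_two_group <- function(n_genes = 200, n_per_group = 10, n_de = 40,
                         effect = 1.5, size = 10, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  mu <- exp(rnorm(n_genes, 4, 1))
  eff <- rep(c(0, effect), c(n_genes - n_de, n_de))
  n <- 2 * n_per_group
  shift <- exp(outer(eff, rep(0:1, each = n_per_group)))
  Y <- matrix(rnbinom(n_genes * n, mu = rep(mu, n) * as.numeric(shift),
                      size = size),
              n_genes, n)
  rownames(Y) <- sprintf("g%04d", seq_len(n_genes))
  colnames(Y) <- sprintf("s%02d", seq_len(n))
  list(
    counts = count_matrix(Y),
    design = design_table(colnames(Y), rep(c("A", "B"), each = n_per_group)),
    truth = truth_table(rownames(Y), eff != 0, eff)
  )
}

# uniform-null result table for evaluation tests
uniform_null_results <- function(n_genes = 5000, seed = 1,
                                 method = "gauss-F1-tab") {
  set.seed(seed)
  list(
    results = result_table(sprintf("g%05d", seq_len(n_genes)),
                           statistic = 0, p_value = runif(n_genes),
                           method = method),
    truth = truth_table(sprintf("g%05d", seq_len(n_genes)),
                        rep(FALSE, n_genes), rep(0, n_genes))
  )
}
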