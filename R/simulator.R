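#' Estimate lognormal-Poisson parameters from a pilot dataset
#'
#' Closed-form moment matching for the over-dispersed Poisson model in
#' which a gene's log rate is `offset + mu_i + e`, with `e ~ N(0, sigma2)`
#' shared by all technical replicates of a biological sample. Working on
#' offset-corrected rates `z_j = y_j / exp(O_j)`, the group mean `m_i`
#' estimates `exp(mu_i + sigma2 / 2)` and the excess variance
#' `v_i = max(0, var(z) - m_i * mean(exp(-O)))` estimates
#' `m_i^2 (exp(sigma2) - 1)`, giving the pooled
#' `sigma2 = log(1 + sum(n_i v_i) / sum(n_i m_i^2))` and
#' `mu_i = log(m_i) - sigma2 / 2`. Genes with a zero mean rate in any
#' group are dropped from the pool.
#'
#' @param counts Count matrix (technical replicates collapsed).
#' @param design Design table with at least 2 biological replicates per
#'   treatment group.
#' @param offsets Per-sample natural-log library sizes (default:
#'   `log(colSums(counts))`).
#' @return A `parameter_pool`: list with `gene_id`, `mu` (genes x groups
#'   matrix, natural-log scale), `sigma2` (per-gene), `groups`.
#' @export
estimate_parameters <- function(counts, design,
                                offsets = log(colSums(counts))) {
  v <- validate_dataset(counts, design)
  counts <- v$counts; design <- v$design
  grp <- factor(design$treatment)
  n_i <- table(grp)
  if (any(n_i < 2L)) {
    pb_stop("need at least 2 biological replicates in every group",
            "pb_value_error")
  }
  z <- sweep(counts, 2L, exp(offsets), `/`)
  m <- matrix(0, nrow(counts), nlevels(grp))
  vhat <- matrix(0, nrow(counts), nlevels(grp))
  for (k in seq_len(nlevels(grp))) {
    cols <- which(grp == levels(grp)[k])
    zk <- z[, cols, drop = FALSE]
    m[, k] <- rowMeans(zk)
    poisson_part <- m[, k] * mean(exp(-offsets[cols]))
    vhat[, k] <- pmax(0, apply(zk, 1L, stats::var) - poisson_part)
  }
  keep <- rowSums(m == 0) == 0L
  m <- m[keep, , drop = FALSE]
  vhat <- vhat[keep, , drop = FALSE]
  w <- as.numeric(n_i)
  sigma2 <- log(1 + (vhat %*% w) / (m^2 %*% w))
  mu <- log(m) - drop(sigma2) / 2
  structure(list(gene_id = rownames(counts)[keep], mu = mu,
                 sigma2 = drop(sigma2), groups = levels(grp)),
            class = "parameter_pool")
}

#' Parameter pool constructor
#'
#' @param gene_id Character vector of source gene ids.
#' @param mu Matrix of group means (genes x groups), natural-log scale.
#' @param sigma2 Per-gene variance of the sample residual, `>= 0`.
#' @return A `parameter_pool` object.
#' @export
parameter_pool <- function(gene_id, mu, sigma2) {
  mu <- as.matrix(mu)
  stopifnot(length(gene_id) == nrow(mu), length(sigma2) == nrow(mu))
  if (nrow(mu) == 0L) pb_stop("parameter pool is empty", "pb_value_error")
  if (any(sigma2 < 0)) pb_stop("sigma2 must be >= 0", "pb_value_error")
  structure(list(gene_id = as.character(gene_id), mu = mu,
                 sigma2 = as.numeric(sigma2),
                 groups = paste0("t", seq_len(ncol(mu)))),
            class = "parameter_pool")
}

#' Simulation configuration
#'
#' @param T Transcripts per dataset.
#' @param K Number of datasets.
#' @param n Biological replicates per group (`>= 2`).
#' @param r Technical replicates per biological replicate (`>= 1`).
#' @param p0 Proportion of differentially expressed transcripts in \[0, 1\].
#' @param offset_scheme `"equal"` or `"lognormal"` library sizes.
#' @param target_depth Target library size in reads (default 2e7).
#' @param cv Coefficient of variation of lognormal library sizes
#'   (default 0.2).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(T = 5000L, K = 1L, n = 3L, r = 1L, p0 = 0.1,
                       offset_scheme = c("lognormal", "equal"),
                       target_depth = 2e7, cv = 0.2, seed = 1L) {
  offset_scheme <- match.arg(offset_scheme)
  stopifnot(T >= 1, K >= 1, n >= 2, r >= 1, p0 >= 0, p0 <= 1,
            target_depth > 0, cv >= 0)
  structure(list(T = as.integer(T), K = as.integer(K), n = as.integer(n),
                 r = as.integer(r), p0 = p0, offset_scheme = offset_scheme,
                 target_depth = target_depth, cv = cv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw transcript parameters and ground truth from a pool
#'
#' Samples `T` transcripts from the pool (without replacement when the pool
#' is large enough, else with replacement). Exactly `floor(p0 * T)` of them
#' are assigned to the alternative set S1 and keep their group means, with
#' `true_log_effect = mu_2 - mu_1`; the remaining S0 transcripts have both
#' group means replaced by their log-scale average so the treatment
#' difference is zeroed out while overall abundance is preserved.
#'
#' @param pool A `parameter_pool`.
#' @param T Number of transcripts to draw.
#' @param p0 Proportion differentially expressed.
#' @param seed Optional integer seed.
#' @return `list(mu, sigma2, truth)` where `truth` is a truth table with
#'   gene ids `g00001, ...`.
#' @export
sample_truth <- function(pool, T, p0, seed = NULL) {
  if (!inherits(pool, "parameter_pool") || nrow(pool$mu) == 0L) {
    pb_stop("parameter pool is empty", "pb_value_error")
  }
  with_seed(seed, {
    idx <- if (nrow(pool$mu) >= T) {
      sample.int(nrow(pool$mu), T)
    } else {
      sample.int(nrow(pool$mu), T, replace = TRUE)
    }
    mu <- pool$mu[idx, , drop = FALSE]
    sigma2 <- pool$sigma2[idx]
    n1 <- floor(p0 * T)
    s1 <- rep(FALSE, T)
    if (n1 > 0) s1[sample.int(T, n1)] <- TRUE
    effect <- ifelse(s1, mu[, 2] - mu[, 1], 0)
    mbar <- rowMeans(mu)
    mu[!s1, 1] <- mbar[!s1]
    mu[!s1, 2] <- mbar[!s1]
    gene_id <- sprintf("g%05d", seq_len(T))
    list(mu = mu, sigma2 = sigma2,
         truth = truth_table(gene_id, s1, effect),
         source_gene = pool$gene_id[idx])
  })
}

sim_offsets <- function(cfg, n_cols, seed = NULL) {
  with_seed(seed, {
    if (cfg$offset_scheme == "equal") {
      rep(log(cfg$target_depth), n_cols)
    } else {
      sdlog <- sqrt(log(1 + cfg$cv^2))
      log(cfg$target_depth) - sdlog^2 / 2 + stats::rnorm(n_cols, 0, sdlog)
    }
  })
}

#' Simulate one over-dispersed Poisson dataset
#'
#' For each gene, group and biological replicate a sample residual
#' `e ~ N(0, sigma2)` is drawn once; every technical replicate of that
#' biological sample shares the residual but receives an independent
#' Poisson draw with rate `exp(O + mu_i + e)`, where `O` is the log
#' library size from the offset scheme. The output has `2 n r` columns
#' ordered group-major.
#'
#' @param cfg A [sim_config()].
#' @param params `list(mu, sigma2, truth)` from [sample_truth()].
#' @param seed Optional integer seed.
#' @return A list with `counts`, `design`, `offsets`, `truth`.
#' @export
simulate_dataset <- function(cfg, params, seed = NULL) {
  mu <- params$mu
  sigma2 <- params$sigma2
  T <- nrow(mu)
  n <- cfg$n; r <- cfg$r
  n_groups <- ncol(mu)
  n_cols <- n_groups * n * r
  group_of <- rep(seq_len(n_groups), each = n * r)
  bio_of <- rep(rep(seq_len(n), each = r), times = n_groups)
  tech_of <- rep(seq_len(r), times = n_groups * n)
  bio_key <- (group_of - 1L) * n + bio_of

  with_seed(seed, {
    offsets <- sim_offsets(cfg, n_cols)
    e <- matrix(stats::rnorm(T * n_groups * n, 0, sqrt(sigma2)),
                T, n_groups * n) # recycles sigma2 by gene down columns
    log_rate <- mu[, group_of, drop = FALSE] +
      e[, bio_key, drop = FALSE] +
      matrix(offsets, T, n_cols, byrow = TRUE)
    too_big <- which(log_rate > 700, arr.ind = TRUE)
    if (nrow(too_big)) {
      pb_stop(sprintf("Poisson rate overflow (exp argument > 700) for gene %s",
                      params$truth$gene_id[too_big[1, 1]]),
              "pb_value_error")
    }
    y <- matrix(stats::rpois(T * n_cols, exp(log_rate)), T, n_cols)
    sample_id <- sprintf("t%d_b%d_r%d", group_of, bio_of, tech_of)
    counts <- count_matrix(y, params$truth$gene_id, sample_id)
    design <- design_table(sample_id,
                           treatment = paste0("t", group_of),
                           bio_rep = paste0("b", bio_of),
                           tech_rep = paste0("r", tech_of))
    list(counts = counts, design = design, offsets = offsets,
         truth = params$truth)
  })
}

#' Simulate the replication-scenario grid
#'
#' Crosses biological replication levels with technical replication levels
#' (default `{3, 5, 10} x {1, 3, 5}`, nine cells) and simulates `K`
#' datasets per cell, each with an independent truth draw and its own
#' recorded sub-seed derived from the master seed.
#'
#' @param pool A `parameter_pool`.
#' @param cfg A [sim_config()]; its `n` and `r` are overridden by the grid.
#' @param n_levels Biological replication levels.
#' @param r_levels Technical replication levels.
#' @return A named list of cells (`"n3_r1"`, ...), each a list with
#'   `n`, `r`, `sub_seed`, and `datasets` (length `K`).
#' @export
simulate_scenarios <- function(pool, cfg, n_levels = c(3L, 5L, 10L),
                               r_levels = c(1L, 3L, 5L)) {
  cells <- list()
  for (n in n_levels) {
    for (r in r_levels) {
      label <- sprintf("n%d_r%d", n, r)
      cell_cfg <- sim_config(T = cfg$T, K = cfg$K, n = n, r = r, p0 = cfg$p0,
                             offset_scheme = cfg$offset_scheme,
                             target_depth = cfg$target_depth, cv = cfg$cv,
                             seed = cfg$seed)
      sub_seed <- derive_seed(cfg$seed, paste0("simulate/", label))
      datasets <- lapply(seq_len(cfg$K), function(k) {
        sk <- derive_seed(sub_seed, sprintf("k%04d", k))
        params <- sample_truth(pool, cfg$T, cfg$p0,
                               seed = derive_seed(sk, "truth"))
        simulate_dataset(cell_cfg, params, seed = derive_seed(sk, "counts"))
      })
      cells[[label]] <- list(n = n, r = r, sub_seed = sub_seed,
                             datasets = datasets)
    }
  }
  cells
}
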