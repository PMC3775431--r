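#' Fixture specification for synthetic base datasets
#'
#' Declares the distributional shape of an offline stand-in for a real base
#' dataset: negative binomial counts with lognormally distributed gene
#' abundances, gamma-distributed dispersions, lognormal library sizes, and
#' optional planted treatment and block effects. The defaults are declared,
#' versioned choices typical of bulk RNA-seq depth and variability; they
#' are not fits to any particular published dataset.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param mean_log_cpm,sd_log_cpm Normal parameters of baseline log-CPM
#'   (natural log of counts-per-million abundance).
#' @param dispersion NB dispersion: a single value, or `NULL` to draw
#'   per-gene dispersions from `Gamma(shape = disp_shape,
#'   mean = disp_mean)`.
#' @param disp_shape,disp_mean Gamma parameters for per-gene dispersions.
#' @param de_fraction Fraction of genes with a planted treatment effect.
#' @param effect_min,effect_gamma_shape,effect_gamma_rate Planted absolute
#'   effects are `effect_min + Gamma(shape, rate)` with random sign.
#' @param n_blocks Number of blocks (1 = no block structure).
#' @param block_sd Standard deviation of per-(gene, block) log shifts.
#' @param depth,depth_cv Lognormal library-size distribution (reads).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 5000L, n_samples = 21L,
                         mean_log_cpm = log(50), sd_log_cpm = 1.5,
                         dispersion = NULL, disp_shape = 2,
                         disp_mean = 0.15,
                         de_fraction = 0, effect_min = 0.5,
                         effect_gamma_shape = 4, effect_gamma_rate = 4,
                         n_blocks = 1L, block_sd = 0,
                         depth = 1e7, depth_cv = 0.3, seed = 1L) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, depth > 0, depth_cv >= 0,
            disp_mean > 0, disp_shape > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

draw_fixture_params <- function(spec) {
  list(
    log_cpm = stats::rnorm(spec$n_genes, spec$mean_log_cpm, spec$sd_log_cpm),
    phi = if (is.null(spec$dispersion)) {
      stats::rgamma(spec$n_genes, shape = spec$disp_shape,
                    rate = spec$disp_shape / spec$disp_mean)
    } else {
      rep(spec$dispersion, spec$n_genes)
    },
    lib = spec$depth * exp(stats::rnorm(spec$n_samples,
                                        -log(1 + spec$depth_cv^2) / 2,
                                        sqrt(log(1 + spec$depth_cv^2))))
  )
}

rnbinom_mu <- function(n, mu, phi) {
  out <- integer(n)
  pois <- phi < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois],
                                 mu = mu[!pois])
  }
  out
}

#' Synthetic exchangeable base dataset ("cheung-like")
#'
#' NB counts whose gene-level expected abundances are shared by every
#' sample, so that samples are exchangeable by construction and any random
#' partition into pseudo-groups yields a valid null comparison. Default
#' preset: 5000 genes by 21 samples, emulating a structureless human
#' B-cell expression study used as a null plasmode base.
#'
#' @param spec A [fixture_spec()] without treatment or block effects.
#' @return `list(counts, design)`.
#' @export
make_exchangeable_base <- function(spec = fixture_spec()) {
  stopifnot(spec$de_fraction == 0, spec$n_blocks == 1L)
  with_seed(spec$seed, {
    pars <- draw_fixture_params(spec)
    mu <- outer(exp(pars$log_cpm), pars$lib / 1e6)
    y <- matrix(rnbinom_mu(length(mu), as.numeric(mu),
                           rep(pars$phi, times = spec$n_samples)),
                spec$n_genes, spec$n_samples)
    gene_id <- sprintf("g%05d", seq_len(spec$n_genes))
    sample_id <- sprintf("s%02d", seq_len(spec$n_samples))
    counts <- count_matrix(y, gene_id, sample_id)
    design <- design_table(sample_id, treatment = rep("all", spec$n_samples))
    list(counts = counts, design = design)
  })
}

#' Synthetic two-treatment blocked base dataset ("bottomly-like")
#'
#' NB counts with planted treatment effects on a stated fraction of genes
#' plus per-(gene, block) log shifts, emulating a two-strain mouse
#' comparison spread over three flowcells where the block explains a large
#' share of the variation. Default preset: 5000 genes, two treatment
#' groups of 10 and 11 samples arranged across 3 blocks.
#'
#' @param spec A [fixture_spec()]; its `de_fraction`, `n_blocks` and
#'   `block_sd` control the planted structure.
#' @param group_sizes Samples per treatment group (default `c(10, 11)`).
#' @return `list(counts, design, truth)` with the planted effects recorded
#'   in the truth table (natural-log scale, group 2 minus group 1).
#' @export
make_blocked_base <- function(spec = fixture_spec(de_fraction = 0.2,
                                                  n_blocks = 3L,
                                                  block_sd = 0.3),
                              group_sizes = c(10L, 11L)) {
  stopifnot(spec$n_blocks >= 2L, length(group_sizes) == 2L)
  n_samples <- sum(group_sizes)
  spec$n_samples <- n_samples
  with_seed(spec$seed, {
    pars <- draw_fixture_params(spec)
    treatment <- rep(c("A", "B"), group_sizes)
    # interleave blocks across both groups so block and treatment are not
    # confounded
    block <- rep_len(paste0("fc", seq_len(spec$n_blocks)), n_samples)
    n_de <- round(spec$de_fraction * spec$n_genes)
    is_de <- rep(FALSE, spec$n_genes)
    is_de[sample.int(spec$n_genes, n_de)] <- TRUE
    effect <- numeric(spec$n_genes)
    effect[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) *
      (spec$effect_min + stats::rgamma(n_de, spec$effect_gamma_shape,
                                       spec$effect_gamma_rate))
    block_shift <- matrix(stats::rnorm(spec$n_genes * spec$n_blocks, 0,
                                       spec$block_sd),
                          spec$n_genes, spec$n_blocks)
    block_idx <- as.integer(factor(block))
    log_mu <- outer(pars$log_cpm, log(pars$lib / 1e6), `+`) +
      outer(effect, as.numeric(treatment == "B")) +
      block_shift[, block_idx, drop = FALSE]
    mu <- exp(log_mu)
    y <- matrix(rnbinom_mu(length(mu), as.numeric(mu),
                           rep(pars$phi, times = n_samples)),
                spec$n_genes, n_samples)
    gene_id <- sprintf("g%05d", seq_len(spec$n_genes))
    sample_id <- sprintf("s%02d", seq_len(n_samples))
    counts <- count_matrix(y, gene_id, sample_id)
    design <- design_table(sample_id, treatment = treatment, block = block)
    truth <- truth_table(gene_id, is_de, effect)
    list(counts = counts, design = design, truth = truth)
  })
}

#' Synthetic parameter pool for the simulator
#'
#' Draws transcript-level parameters `(mu1, mu1 + delta, sigma2)` for the
#' lognormal-Poisson simulator: baseline `mu1 ~ N(mean_log_cpm -
#' log(1e6), sd_log_cpm^2)` on the natural-log relative-abundance scale,
#' treatment difference `delta` from an equal mixture of `N(0, 0.5^2)` and
#' `N(0, 1^2)` (many small effects, some large), and sample-effect
#' variance `sigma2 ~ Gamma(shape 2, mean 0.1)`.
#'
#' @param n_genes Pool size.
#' @param mean_log_cpm,sd_log_cpm Baseline abundance distribution (CPM
#'   scale, natural log).
#' @param delta_sd Two-component mixture standard deviations.
#' @param sigma2_shape,sigma2_mean Gamma parameters of `sigma2`.
#' @param seed Integer seed.
#' @return A `parameter_pool`.
#' @export
make_parameter_pool <- function(n_genes = 5000L, mean_log_cpm = log(50),
                                sd_log_cpm = 1.5, delta_sd = c(0.5, 1),
                                sigma2_shape = 2, sigma2_mean = 0.1,
                                seed = 1L) {
  with_seed(seed, {
    mu1 <- stats::rnorm(n_genes, mean_log_cpm - log(1e6), sd_log_cpm)
    comp <- sample.int(length(delta_sd), n_genes, replace = TRUE)
    delta <- stats::rnorm(n_genes, 0, delta_sd[comp])
    sigma2 <- stats::rgamma(n_genes, shape = sigma2_shape,
                            rate = sigma2_shape / sigma2_mean)
    parameter_pool(sprintf("pool%05d", seq_len(n_genes)),
                   cbind(mu1, mu1 + delta), sigma2)
  })
}
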