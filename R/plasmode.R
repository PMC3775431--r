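#' Null plasmodes from an exchangeable base dataset
#'
#' Model-free null datasets: each plasmode draws `t * r` distinct base
#' columns uniformly without replacement, copies them unchanged and assigns
#' arbitrary pseudo-group labels (the first `r` columns form group 1, the
#' next `r` group 2, ...). Because samples are assumed exchangeable, no
#' differential expression is expected beyond sample-to-sample variation,
#' and the truth marks every gene as null. The joint distribution and
#' gene-to-gene correlations of the base data are preserved exactly.
#'
#' @param base Base count matrix with exchangeable samples (the caller is
#'   responsible for verifying exchangeability, e.g. by multidimensional
#'   scaling inspection).
#' @param p Number of plasmodes.
#' @param t Number of pseudo-groups.
#' @param r Biological replicates per pseudo-group.
#' @param seed Optional integer seed.
#' @return A list of `p` plasmode datasets, each a list with `counts`,
#'   `design`, `truth`, `provenance` (plasmode column -> base sample id).
#' @export
make_null_plasmodes <- function(base, p = 10L, t = 2L, r = 10L, seed = NULL) {
  base <- count_matrix(base)
  if (t * r > ncol(base)) {
    pb_stop(sprintf("t * r = %d exceeds the %d base samples", t * r,
                    ncol(base)), "pb_config_error")
  }
  with_seed(seed, {
    lapply(seq_len(p), function(i) {
      cols <- sample.int(ncol(base), t * r)
      counts <- base[, cols, drop = FALSE]
      sample_id <- sprintf("grp%d_rep%d", rep(seq_len(t), each = r),
                           rep(seq_len(r), times = t))
      colnames(counts) <- sample_id
      design <- design_table(sample_id,
                             treatment = paste0("grp", rep(seq_len(t), each = r)))
      truth <- truth_table(rownames(base), rep(FALSE, nrow(base)),
                           rep(0, nrow(base)))
      provenance <- data.frame(column = sample_id,
                               base_sample = colnames(base)[cols],
                               stringsAsFactors = FALSE)
      list(counts = count_matrix(counts), design = design, truth = truth,
           provenance = provenance)
    })
  })
}

#' Select a high-confidence DE gene set from base data
#'
#' Fits the package's own NB GLM (treatment plus block, tagwise-shrunk
#' dispersions, TMM offsets) to every gene, computes likelihood-ratio
#' p-values, converts them to q-values by Benjamini-Hochberg, and returns
#' the genes with `q <= q_threshold` together with their estimated
#' natural-log treatment fold changes. These effects seed the DE-plasmode
#' spike-ins.
#'
#' @param base Base count matrix (filtering already applied).
#' @param design Design table with >= 2 treatment levels (block optional).
#' @param q_threshold BH q-value cutoff (default 0.01).
#' @return A `data.frame` with columns `gene_id`, `log_fold_change`,
#'   `q_value` (possibly empty, with a warning).
#' @export
select_effect_set <- function(base, design, q_threshold = 0.01) {
  v <- validate_dataset(base, design)
  base <- v$counts; design <- v$design
  if (length(unique(design$treatment)) < 2L) {
    pb_stop("base data must have at least 2 treatment levels",
            "pb_value_error")
  }
  spec <- model_spec(design)
  off <- normalization_offsets(base, "tmm")
  disp <- estimate_dispersion(base, spec, off, "tagwise_shrunk")
  rt <- nb_lrt(base, spec, off, disp)
  coefs <- attr(rt, "fit")
  trt_col <- grep("^treatment", colnames(coefs), value = TRUE)[1]
  q <- stats::p.adjust(rt$p_value, method = "BH")
  keep <- which(!is.na(q) & q <= q_threshold)
  if (!length(keep)) {
    warning("no gene passes the q-value threshold; effect set is empty")
  }
  data.frame(gene_id = rt$gene_id[keep],
             log_fold_change = coefs[keep, trt_col],
             q_value = q[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Impose a fold change on selected columns by binomial thinning
#'
#' Replaces each target count `y` by a `Binomial(y, exp(-|beta|))` draw,
#' reducing the target group's mean by the factor `exp(-|beta|)` while
#' keeping integer, count-like data (thinned values never exceed the
#' originals; zero rows stay zero). The caller chooses the target columns
#' as the group on the down side of the effect.
#'
#' @param row Integer count vector (one gene).
#' @param target_columns Indices of the columns to thin.
#' @param beta Finite natural-log effect size.
#' @return The thinned row.
#' @export
spike_counts <- function(row, target_columns, beta) {
  if (!is.finite(beta)) pb_stop("beta must be finite", "pb_value_error")
  q <- exp(-abs(beta))
  row[target_columns] <- stats::rbinom(length(target_columns),
                                       size = row[target_columns], prob = q)
  row
}

# balanced partition of one block's samples into two pseudo-groups;
# `larger_first` says which side takes the extra sample when odd
balanced_partition <- function(idx, larger_first) {
  m <- length(idx)
  n1 <- if (m %% 2L == 0L) m %/% 2L else m %/% 2L + as.integer(larger_first)
  g1 <- sample(idx, n1)
  list(g1 = sort(g1), g2 = sort(setdiff(idx, g1)))
}

#' DE plasmodes by within-block randomization and spiking
#'
#' Each plasmode (1) randomly partitions the base samples within each block
#' into two pseudo-treatment groups with sizes as equal as possible, odd
#' blocks alternating which side takes the extra sample; (2) selects
#' `round(pi_spike * T)` genes uniformly at random; and (3) imposes on each
#' selected gene an effect `beta` by binomial thinning of the pseudo-group
#' on the down side of the effect ([spike_counts()]). In
#' `effect_mode = "sampled_from_G"` the spiked genes are arbitrary and
#' their betas are drawn with replacement from the effect set's estimated
#' log fold changes; in `"own_effect_G_only"` the spiked genes are drawn
#' from the effect set itself and keep their own estimates. Non-spiked
#' rows are, within each block, untouched copies of the base rows.
#'
#' @param base Filtered base count matrix.
#' @param design Design table (its `block` drives the randomization).
#' @param G Effect set from [select_effect_set()].
#' @param p Number of plasmodes.
#' @param pi_spike Fraction of genes spiked (0 < pi < 1).
#' @param effect_mode `"sampled_from_G"` or `"own_effect_G_only"`.
#' @param seed Optional integer seed.
#' @return A list of `p` plasmode datasets (`counts`, `design`, `truth`,
#'   `provenance`).
#' @export
make_de_plasmodes <- function(base, design, G, p = 10L, pi_spike = 0.20,
                              effect_mode = c("sampled_from_G",
                                              "own_effect_G_only"),
                              seed = NULL) {
  effect_mode <- match.arg(effect_mode)
  v <- validate_dataset(base, design)
  base <- v$counts; design <- v$design
  stopifnot(pi_spike > 0, pi_spike < 1)
  T <- nrow(base)
  n_spike <- round(pi_spike * T)
  if (n_spike > T) pb_stop("round(pi * T) exceeds gene count", "pb_config_error")
  if (effect_mode == "own_effect_G_only" && nrow(G) < n_spike) {
    pb_stop(sprintf("effect set has %d genes but %d spikes requested",
                    nrow(G), n_spike), "pb_config_error")
  }
  if (nrow(G) == 0L) {
    pb_stop("effect set G is empty", "pb_value_error")
  }
  blocks <- split(seq_len(ncol(base)), design$block)

  with_seed(seed, {
    lapply(seq_len(p), function(i) {
      group <- integer(ncol(base))
      larger_first <- TRUE
      for (idx in blocks) {
        part <- balanced_partition(idx, larger_first)
        if (length(idx) %% 2L == 1L) larger_first <- !larger_first
        group[part$g1] <- 1L
        group[part$g2] <- 2L
      }
      if (effect_mode == "sampled_from_G") {
        spiked <- sample.int(T, n_spike)
        beta <- sample(G$log_fold_change, n_spike, replace = TRUE)
      } else {
        pick <- sample.int(nrow(G), n_spike)
        spiked <- match(G$gene_id[pick], rownames(base))
        beta <- G$log_fold_change[pick]
      }
      counts <- base
      for (j in seq_len(n_spike)) {
        down <- which(group == (if (beta[j] >= 0) 1L else 2L))
        counts[spiked[j], ] <- spike_counts(counts[spiked[j], ], down, beta[j])
      }
      pseudo <- design
      pseudo$treatment <- paste0("grp", group)
      is_de <- seq_len(T) %in% spiked
      effect <- numeric(T)
      effect[spiked] <- beta
      provenance <- data.frame(column = colnames(base),
                               base_sample = colnames(base),
                               pseudo_group = group,
                               stringsAsFactors = FALSE)
      list(counts = count_matrix(counts),
           design = pseudo,
           truth = truth_table(rownames(base), is_de, effect),
           provenance = provenance)
    })
  })
}
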