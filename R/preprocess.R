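#' Sum technical replicates into biological samples
#'
#' Technical replicates are repeated sequencing runs of the same RNA source:
#' they add depth, not independent biological variation, and are summed into
#' one column per biological sample before filtering and analysis.
#'
#' @param counts Count matrix.
#' @param design Design table identifying `tech_rep` within
#'   (`treatment`, `block`, `bio_rep`).
#' @return `list(counts, design)` with one column per biological sample and
#'   `tech_rep` collapsed to `"1"`.
#' @export
collapse_technical <- function(counts, design) {
  v <- validate_dataset(counts, design)
  counts <- v$counts; design <- v$design
  key <- paste(design$treatment, design$block, design$bio_rep, sep = "\r")
  first <- !duplicated(key)
  groups <- factor(key, levels = key[first])
  if (nlevels(groups) == ncol(counts)) {
    design$tech_rep <- rep("1", nrow(design))
    return(list(counts = counts, design = design))
  }
  summed <- counts %*% outer(key, key[first], `==`)
  storage.mode(summed) <- "integer"
  new_design <- design[first, , drop = FALSE]
  new_design$tech_rep <- "1"
  new_design$sample_id <- paste(new_design$treatment, new_design$block,
                                new_design$bio_rep, sep = "_")
  colnames(summed) <- new_design$sample_id
  rownames(new_design) <- NULL
  list(counts = count_matrix(summed), design = new_design)
}

#' Counts per million
#'
#' @param counts Count matrix.
#' @param lib_sizes Library sizes (default: column sums).
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  zero <- which(lib_sizes == 0)
  if (length(zero)) {
    pb_stop(sprintf("sample '%s' has zero library size",
                    colnames(counts)[zero[1]]), "pb_value_error")
  }
  sweep(counts, 2L, lib_sizes, `/`) * 1e6
}

#' Filter low-expression genes by raw CPM
#'
#' Keeps genes with 2 or more reads per million in at least as many
#' libraries as there are biological replicates per group. Filtering uses
#' raw (unnormalized) library sizes and is applied after technical
#' replicates have been summed.
#'
#' @param counts Count matrix of biological samples.
#' @param n_bio Biological replicates per group (the minimum number of
#'   libraries that must pass).
#' @param min_cpm CPM cutoff (default 2).
#' @return `list(counts, kept)` where `kept` is the character vector of
#'   retained gene ids.
#' @export
filter_cpm <- function(counts, n_bio, min_cpm = 2) {
  x <- cpm(counts)
  keep <- rowSums(x >= min_cpm) >= n_bio
  list(counts = counts[keep, , drop = FALSE], kept = rownames(counts)[keep])
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' Between-sample composition normalization: for each sample against a
#' reference column, gene-wise log ratios (M) are doubly trimmed (30% from
#' each tail by M, 5% from each tail by average abundance A) and averaged
#' with inverse approximate-variance precision weights; the scale factor is
#' 2 to that weighted mean. The reference is the column whose 75th
#' percentile of CPM is closest to the mean of those percentiles. Factors
#' are rescaled to geometric mean 1; the effective library size of a sample
#' is its library size times its scale factor.
#'
#' @param counts Count matrix (technical replicates collapsed, filtered).
#' @param logratio_trim Fraction trimmed from each tail of M (default 0.3).
#' @param abundance_trim Fraction trimmed from each tail of A (default 0.05).
#' @return A `data.frame` with columns `sample_id`, `library_size`,
#'   `scale_factor`, `effective_library_size`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  if (ncol(counts) < 2L) pb_stop("TMM needs at least 2 samples", "pb_value_error")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    pb_stop(sprintf("sample '%s' has zero library size",
                    colnames(counts)[zero[1]]), "pb_value_error")
  }
  f75 <- apply(cpm(counts, lib), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref],
             logratio_trim, abundance_trim)
  }, 0)
  fac <- fac / geometric_mean(fac)
  data.frame(sample_id = colnames(counts), library_size = lib,
             scale_factor = fac, effective_library_size = lib * fac,
             row.names = NULL, stringsAsFactors = FALSE)
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("all genes excluded in TMM comparison; factor set to 1")
    return(1)
  }
  po <- obs[keep] / n_obs
  pr <- ref[keep] / n_ref
  M <- log2(po / pr)
  A <- (log2(po) + log2(pr)) / 2 # this form keeps exact ties tied
  # delta-method variance of M for precision weighting
  w <- 1 / ((n_obs - obs[keep]) / (n_obs * obs[keep]) +
            (n_ref - ref[keep]) / (n_ref * ref[keep]))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1
  hiA <- n + 1 - loA
  inM <- rank(M) >= loM & rank(M) <= hiM
  inA <- rank(A) >= loA & rank(A) <= hiA
  sel <- inM & inA
  if (!any(sel)) {
    warning("all genes trimmed in TMM comparison; factor set to 1")
    return(1)
  }
  f <- 2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  if (!is.finite(f)) 1 else f
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes positive in
#' every sample) of the ratio of its count to the gene's geometric mean
#' across samples.
#'
#' @param counts Count matrix.
#' @return A `data.frame` with columns `sample_id`, `size_factor`.
#' @export
size_factors_median_ratio <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    pb_stop("no gene has positive counts in every sample; size factors undefined",
            "pb_value_error")
  }
  x <- counts[pos, , drop = FALSE]
  log_geo <- rowMeans(log(x))
  sf <- apply(exp(sweep(log(x), 1L, log_geo, `-`)), 2L, stats::median)
  data.frame(sample_id = colnames(counts), size_factor = sf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' log2 counts-per-million transform
#'
#' `x = log2((count + prior) / (effective_library_size + 1) * 1e6)`, the
#' transformation feeding the Gaussian testing engines. Finite for all
#' non-negative integer input.
#'
#' @param counts Count matrix.
#' @param norm `NormFactors` data frame from [tmm_factors()], or `NULL` for
#'   raw library sizes with unit scale factors.
#' @param prior Prior count added to every cell (default 0.5).
#' @return Numeric matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, norm = NULL, prior = 0.5) {
  if (is.null(norm)) {
    eff <- colSums(counts)
  } else {
    eff <- norm$effective_library_size[match(colnames(counts), norm$sample_id)]
  }
  log2(sweep(counts + prior, 2L, eff + 1, `/`) * 1e6)
}

#' Natural-log effective-library-size offsets
#'
#' Convenience accessor producing the per-sample offsets used by the NB GLM
#' engines: `log(effective library size)` for TMM normalization or
#' `log(size factor)` for median-of-ratios.
#'
#' @param counts Count matrix.
#' @param method `"tmm"` or `"median_ratio"`.
#' @return Named numeric vector of offsets, one per sample.
#' @export
normalization_offsets <- function(counts, method = c("tmm", "median_ratio")) {
  method <- match.arg(method)
  if (method == "tmm") {
    nf <- tmm_factors(counts)
    out <- log(nf$effective_library_size)
    names(out) <- nf$sample_id
  } else {
    sf <- size_factors_median_ratio(counts)
    out <- log(sf$size_factor) + log(mean(colSums(counts)))
    names(out) <- sf$sample_id
  }
  out[colnames(counts)]
}
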