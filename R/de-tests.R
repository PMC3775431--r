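#' Negative binomial likelihood-ratio test per gene
#'
#' Fits the full and reduced NB GLMs at the supplied per-gene dispersions
#' and refers the deviance difference to a chi-square distribution with
#' degrees of freedom equal to the rank difference of the two design
#' matrices. Genes whose fits failed to converge receive a missing p-value
#' and are excluded downstream.
#'
#' @param counts Filtered count matrix.
#' @param spec A [model_spec()].
#' @param offsets Per-sample natural-log offsets.
#' @param disp Dispersion table from [estimate_dispersion()].
#' @param method Method tag recorded in the result (default from the
#'   dispersion policy).
#' @return A result table; attribute `"fit"` carries the full-model
#'   coefficients (natural-log scale).
#' @export
nb_lrt <- function(counts, spec, offsets, disp, method = NULL) {
  Y <- as.matrix(counts)
  phi <- disp$phi[match(rownames(counts), disp$gene_id)]
  if (anyNA(phi)) pb_stop("dispersion table does not cover all genes",
                          "pb_structure_error")
  full <- nb_fit_matrix(Y, spec$X_full, offsets, phi)
  red <- nb_fit_matrix(Y, spec$X_reduced, offsets, phi)
  stat <- pmax(red$deviance - full$deviance, 0)
  df <- qr(spec$X_full)$rank - qr(spec$X_reduced)$rank
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  bad <- !(full$converged & red$converged)
  if (any(bad)) {
    warning(sprintf("%d gene(s) failed to converge; p-values set to NA",
                    sum(bad)))
    p[bad] <- NA_real_
  }
  if (is.null(method)) {
    method <- paste0("nb-lrt-", sub("_.*", "", disp$policy[1]))
  }
  rt <- result_table(rownames(counts), stat, p, method)
  colnames(full$coefficients) <- colnames(spec$X_full)
  attr(rt, "fit") <- full$coefficients
  rt
}

#' Gene-wise ordinary least squares on transformed counts
#'
#' Fits the full and reduced Gaussian linear models to every row of a
#' log2-CPM matrix by a single QR decomposition each, recording residual
#' sums of squares, residual degrees of freedom and coefficients.
#'
#' @param x Numeric matrix (genes x samples), typically from [log2_cpm()].
#' @param spec A [model_spec()].
#' @return A list of class `"gaussian_fit"` with `gene_id`, `coefficients`,
#'   `rss_full`, `rss_reduced`, `df_res`, `df_num`, `sigma2` (residual
#'   variance).
#' @export
fit_gaussian <- function(x, spec) {
  x <- as.matrix(x)
  qr_full <- qr(spec$X_full)
  qr_red <- qr(spec$X_reduced)
  if (qr_full$rank < ncol(spec$X_full)) {
    pb_stop(sprintf("rank-deficient full model: aliased column '%s'",
                    colnames(spec$X_full)[qr_full$pivot[qr_full$rank + 1L]]),
            "pb_value_error")
  }
  df_res <- ncol(x) - qr_full$rank
  if (df_res < 1L) pb_stop("no residual degrees of freedom", "pb_value_error")
  res_full <- qr.resid(qr_full, t(x))
  res_red <- qr.resid(qr_red, t(x))
  coefs <- t(qr.coef(qr_full, t(x)))
  colnames(coefs) <- colnames(spec$X_full)
  structure(list(
    gene_id = rownames(x),
    coefficients = coefs,
    rss_full = colSums(res_full^2),
    rss_reduced = colSums(res_red^2),
    df_res = df_res,
    df_num = qr_full$rank - qr_red$rank,
    sigma2 = colSums(res_full^2) / df_res
  ), class = "gaussian_fit")
}

#' Gene-wise and moderated F statistics
#'
#' `F1` is the ordinary per-gene ANOVA F statistic. `Fs` replaces the
#' per-gene residual variance by a variance shrunk across genes: log
#' variances are pulled toward their mean by the positive-part James-Stein
#' factor `(1 - (G - 3) V / sum((X_g - Xbar)^2))+`, where
#' `V = trigamma(df_res / 2)` is the sampling variance of the log of a
#' scaled chi-square. Genes with zero residual variance cannot form an F
#' and are flagged `NA`.
#'
#' @param fits A [fit_gaussian()] object.
#' @param mode `"F1"` or `"Fs"`.
#' @return Numeric vector of statistics with attributes `df_num`, `df_res`.
#' @export
f_statistics <- function(fits, mode = c("F1", "Fs")) {
  mode <- match.arg(mode)
  ms_num <- (fits$rss_reduced - fits$rss_full) / fits$df_num
  s2 <- fits$sigma2
  denom <- if (mode == "F1") {
    ifelse(s2 > 0, s2, NA_real_)
  } else {
    ok <- s2 > 0
    G <- sum(ok)
    lx <- log(s2[ok])
    ss <- sum((lx - mean(lx))^2)
    V <- trigamma(fits$df_res / 2)
    c_shrink <- if (ss > 0) max(0, 1 - (G - 3) * V / ss) else 0
    shrunk <- rep(NA_real_, length(s2))
    shrunk[ok] <- exp(mean(lx) + c_shrink * (lx - mean(lx)))
    shrunk
  }
  out <- ms_num / denom
  attr(out, "df_num") <- fits$df_num
  attr(out, "df_res") <- fits$df_res
  out
}

#' Tabulated F p-values
#'
#' Upper-tail probabilities from the F distribution with the fit's
#' numerator and residual degrees of freedom. The moderated statistic uses
#' the same reference distribution: moderation changes the statistic, not
#' the reference.
#'
#' @param stat Statistics from [f_statistics()].
#' @param gene_id Gene identifiers.
#' @param df_num,df_res Degrees of freedom (default: taken from `stat`
#'   attributes).
#' @param method Method tag for the result table.
#' @return A result table.
#' @export
tabulated_pvalues <- function(stat, gene_id,
                              df_num = attr(stat, "df_num"),
                              df_res = attr(stat, "df_res"),
                              method = "gauss-F-tab") {
  p <- stats::pf(as.numeric(stat), df_num, df_res, lower.tail = FALSE)
  result_table(gene_id, as.numeric(stat), p, method)
}

# Enumerate every distinct treatment-label assignment (within blocks when
# restricted). Returns a list of character vectors of treatment labels.
enumerate_assignments <- function(treatment, strata) {
  blocks <- split(seq_along(treatment), strata)
  block_opts <- lapply(blocks, function(idx) {
    unique_label_orders(treatment[idx])
  })
  combos <- list(list())
  for (b in seq_along(blocks)) { # cartesian product across blocks
    combos <- unlist(lapply(combos, function(a) {
      lapply(block_opts[[b]], function(o) c(a, list(o)))
    }), recursive = FALSE)
  }
  lapply(combos, function(parts) {
    out <- treatment
    for (b in seq_along(blocks)) out[blocks[[b]]] <- parts[[b]]
    out
  })
}

# all distinct orderings of a label multiset (distinct multiset
# permutations, not factorial duplicates)
unique_label_orders <- function(labs) {
  labs <- as.character(labs)
  if (length(labs) == 1L) return(list(labs))
  out <- list()
  for (u in unique(labs)) {
    rest <- labs[-match(u, labs)]
    out <- c(out, lapply(unique_label_orders(rest), function(r) c(u, r)))
  }
  out
}

#' Permutation p-values for gene-wise statistics
#'
#' Shuffles treatment labels across whole samples (within blocks when
#' `restrict_within_block` and the design has more than one block),
#' recomputes the statistic for every gene under each permutation, and
#' forms p-values against a null pool that spans all genes and all
#' permutations when `pool_across_genes`. The add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + pool size)` guarantees strictly
#' positive p-values with granularity `1 / (1 + pool size)`. When fewer
#' distinct permutations exist than requested, all of them are enumerated
#' exhaustively (with a warning) and the observed assignment is excluded
#' from the pool, which reproduces the classical exact permutation p-value.
#'
#' @param statistic_fn `function(x, design)` returning one statistic per
#'   gene (larger = more extreme); see [gaussian_stat_fn()].
#' @param x Data matrix (genes x samples).
#' @param design Design table.
#' @param n_perm Number of permutations (default 100).
#' @param pool_across_genes Pool the null across genes (default `TRUE`).
#' @param restrict_within_block Permute only within blocks (default `TRUE`).
#' @param seed Optional integer seed.
#' @param method Method tag for the result table.
#' @return A result table.
#' @export
permutation_pvalues <- function(statistic_fn, x, design, n_perm = 100L,
                                pool_across_genes = TRUE,
                                restrict_within_block = TRUE,
                                seed = NULL, method = "gauss-F-perm") {
  x <- as.matrix(x)
  treatment <- as.character(design$treatment)
  strata <- if (restrict_within_block) as.character(design$block)
            else rep("1", nrow(design))
  if (any(table(strata) < 2L)) {
    pb_stop("every permutable stratum needs at least 2 samples",
            "pb_value_error")
  }
  observed <- statistic_fn(x, design)

  n_distinct <- prod(vapply(split(treatment, strata), function(labs) {
    tab <- table(labs)
    exp(lgamma(length(labs) + 1) - sum(lgamma(tab + 1)))
  }, 0))
  # the test statistic is label-symmetric: a global label swap that
  # preserves per-block group sizes maps a split onto itself
  sizes <- table(treatment, strata)
  swap_symmetric <- nrow(sizes) == 2L && all(sizes[1, ] == sizes[2, ])
  n_splits <- if (swap_symmetric) round(n_distinct) / 2 else round(n_distinct)

  perm_design <- function(labs) {
    d <- design
    d$treatment <- labs
    d
  }

  if (n_splits - 1 <= n_perm) {
    warning(sprintf(
      "only %d distinct label splits available; using exhaustive enumeration",
      n_splits))
    assigns <- enumerate_assignments(treatment, strata)
    canon <- function(a) {
      # a split and its global label swap give identical statistics
      k <- paste(a, collapse = "\r")
      if (!swap_symmetric) return(k)
      lv <- sort(unique(treatment))
      ks <- paste(ifelse(a == lv[1], lv[2], lv[1]), collapse = "\r")
      if (ks < k) ks else k
    }
    key <- vapply(assigns, canon, "")
    dedup <- !duplicated(key)
    assigns <- assigns[dedup]
    key <- key[dedup]
    assigns <- assigns[key != canon(treatment)]
    null_stats <- vapply(assigns, function(a) statistic_fn(x, perm_design(a)),
                         numeric(nrow(x)))
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        labs <- treatment
        for (idx in split(seq_along(treatment), strata)) {
          labs[idx] <- sample(treatment[idx])
        }
        statistic_fn(x, perm_design(labs))
      }, numeric(nrow(x)))
    })
  }
  null_stats <- matrix(null_stats, nrow = nrow(x))

  p <- if (pool_across_genes) {
    pool <- sort(-as.numeric(null_stats))
    (1 + findInterval(-observed, pool)) / (1 + length(pool))
  } else {
    (1 + rowSums(null_stats >= observed)) / (1 + ncol(null_stats))
  }
  result_table(rownames(x), observed, p, method)
}

#' Built-in Gaussian F statistic function for permutation testing
#'
#' @param mode `"F1"` or `"Fs"`.
#' @param include_block Passed to [model_spec()].
#' @return A `function(x, design)` usable with [permutation_pvalues()].
#' @export
gaussian_stat_fn <- function(mode = c("F1", "Fs"),
                             include_block = "auto") {
  mode <- match.arg(mode)
  function(x, design) {
    spec <- model_spec(design, include_block = include_block)
    as.numeric(f_statistics(fit_gaussian(x, spec), mode = mode))
  }
}

de_method_tags <- c("nb-lrt-tagwise", "nb-lrt-trend",
                    "gauss-F1-tab", "gauss-Fs-tab",
                    "gauss-F1-perm", "gauss-Fs-perm")

#' Run a panel of differential-expression tests
#'
#' Orchestrates the compared engines on one dataset: NB GLM LRT with
#' tagwise-shrunk dispersions and TMM effective-library-size offsets
#' (edgeR-like), NB GLM LRT with trend-maximum dispersions and
#' median-of-ratios size-factor offsets (DESeq-like), and Gaussian F1/Fs
#' tests on TMM-normalized log2-CPM with tabulated or pooled-permutation
#' p-values (MAANOVA-like). Input counts are expected to have technical
#' replicates collapsed and low-expression genes filtered.
#'
#' @param counts Filtered count matrix of biological samples.
#' @param design Design table.
#' @param methods Character vector of method tags (subset of
#'   `"nb-lrt-tagwise"`, `"nb-lrt-trend"`, `"gauss-F1-tab"`,
#'   `"gauss-Fs-tab"`, `"gauss-F1-perm"`, `"gauss-Fs-perm"`).
#' @param n_perm Permutations for the `-perm` methods (default 100).
#' @param seed Optional integer seed for permutation draws.
#' @return A result table with one row per gene per method.
#' @export
run_de_methods <- function(counts, design, methods = de_method_tags,
                           n_perm = 100L, seed = NULL) {
  bad <- setdiff(methods, de_method_tags)
  if (length(bad)) {
    pb_stop(sprintf("unknown method tag '%s'; valid tags: %s", bad[1],
                    paste(de_method_tags, collapse = ", ")),
            "pb_value_error")
  }
  v <- validate_dataset(counts, design)
  counts <- v$counts; design <- v$design
  spec <- model_spec(design)
  out <- list()
  if (any(grepl("^nb-lrt", methods))) {
    if ("nb-lrt-tagwise" %in% methods) {
      off <- normalization_offsets(counts, "tmm")
      disp <- estimate_dispersion(counts, spec, off, "tagwise_shrunk")
      out$tagwise <- nb_lrt(counts, spec, off, disp, method = "nb-lrt-tagwise")
    }
    if ("nb-lrt-trend" %in% methods) {
      off <- normalization_offsets(counts, "median_ratio")
      disp <- estimate_dispersion(counts, spec, off, "trend_max")
      out$trend <- nb_lrt(counts, spec, off, disp, method = "nb-lrt-trend")
    }
  }
  if (any(grepl("^gauss", methods))) {
    x <- log2_cpm(counts, tmm_factors(counts))
    fits <- fit_gaussian(x, spec)
    for (mode in c("F1", "Fs")) {
      tab_tag <- paste0("gauss-", mode, "-tab")
      perm_tag <- paste0("gauss-", mode, "-perm")
      if (tab_tag %in% methods) {
        out[[tab_tag]] <- tabulated_pvalues(f_statistics(fits, mode),
                                            rownames(counts), method = tab_tag)
      }
      if (perm_tag %in% methods) {
        out[[perm_tag]] <- suppressWarnings(permutation_pvalues(
          gaussian_stat_fn(mode), x, design, n_perm = n_perm,
          seed = if (is.null(seed)) NULL else derive_seed(seed, perm_tag),
          method = perm_tag))
      }
    }
  }
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}
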