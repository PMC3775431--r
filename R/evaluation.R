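#' Confusion counts at a significance threshold
#'
#' Declares genes with `p <= alpha` significant (inclusive, so permutation
#' granularity points sit on the curve) and cross-tabulates the declaration
#' against the known null/alternative status. Genes with missing p-values
#' are dropped from both sides. The marginal identities
#' `TP + FN = #S1`, `FP + TN = #S0`, `R0 + R1 = G` are asserted on every
#' call. No multiple-testing correction is applied anywhere in evaluation.
#'
#' @param results Result table for one method.
#' @param truth Truth table covering the same genes.
#' @param alpha Significance threshold.
#' @return A list with `TP`, `FP`, `TN`, `FN`, `R0`, `R1`, `S0_count`,
#'   `S1_count`, `G_total`, `TPR`, `FPR` (rates are `NA` when their
#'   denominator set is empty).
#' @export
confusion_at <- function(results, truth, alpha) {
  m <- merge(results[, c("gene_id", "p_value")],
             truth[, c("gene_id", "is_de")], by = "gene_id")
  m <- m[!is.na(m$p_value), , drop = FALSE]
  declared <- m$p_value <= alpha
  TP <- sum(declared & m$is_de)
  FP <- sum(declared & !m$is_de)
  FN <- sum(!declared & m$is_de)
  TN <- sum(!declared & !m$is_de)
  S1 <- TP + FN; S0 <- FP + TN
  stopifnot(TP + FN == S1, FP + TN == S0,
            (TN + FN) + (FP + TP) == S0 + S1)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       R0 = TN + FN, R1 = FP + TP,
       S0_count = S0, S1_count = S1, G_total = S0 + S1,
       TPR = if (S1 > 0) TP / S1 else NA_real_,
       FPR = if (S0 > 0) FP / S0 else NA_real_)
}

#' ROC curve over p-value thresholds
#'
#' Sweeps [confusion_at()] over thresholds (default: every distinct
#' p-value plus 0 and 1), producing a step curve from (0, 0) to (1, 1).
#'
#' @param results Result table.
#' @param truth Truth table.
#' @param thresholds Numeric thresholds, or `NULL` for all distinct
#'   p-values plus the endpoints.
#' @return A `data.frame` with columns `threshold`, `TPR`, `FPR`.
#' @export
roc_curve <- function(results, truth, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, results$p_value[!is.na(results$p_value)], 1)))
  } else {
    thresholds <- sort(unique(thresholds))
  }
  rows <- lapply(thresholds, function(a) {
    cc <- confusion_at(results, truth, a)
    data.frame(threshold = a, TPR = cc$TPR, FPR = cc$FPR)
  })
  do.call(rbind, rows)
}

#' Empirical type-I error over a nominal grid
#'
#' Empirical type-I error at nominal level `alpha` is the rejection rate
#' among true-null (S0) genes, i.e. the FPR restricted to S0; for a fully
#' null dataset that is every gene. The default grid covers 1e-4 to 1e-1
#' with 30 log-spaced points, the region where miscalibration of the NB
#' engines concentrates.
#'
#' @param results Result table.
#' @param truth Truth table.
#' @param nominal Nominal significance grid.
#' @return A `data.frame` with columns `nominal`, `empirical`.
#' @export
type1_curve <- function(results, truth,
                        nominal = 10^seq(-4, -1, length.out = 30)) {
  m <- merge(results[, c("gene_id", "p_value")],
             truth[, c("gene_id", "is_de")], by = "gene_id")
  p0 <- m$p_value[!m$is_de & !is.na(m$p_value)]
  if (!length(p0)) pb_stop("no null genes with observed p-values",
                           "pb_value_error")
  data.frame(nominal = nominal,
             empirical = vapply(nominal, function(a) mean(p0 <= a), 0))
}

#' Uniform Q-Q data for null p-values
#'
#' Pairs the sorted p-values of the true-null genes with uniform expected
#' quantiles `i / (m + 1)`, both on the -log10 scale. Zero p-values (which
#' can arise from engines without the add-one rule) are replaced by the
#' minimum positive observed p-value before taking logs.
#'
#' @param results Result table.
#' @param truth Truth table.
#' @return A `data.frame` with columns `expected`, `observed` (-log10
#'   scale, aligned smallest-p last); attribute `"zero_replacement"` holds
#'   the value substituted for zeros (`NA` if none were present).
#' @export
qq_uniform <- function(results, truth) {
  m <- merge(results[, c("gene_id", "p_value")],
             truth[, c("gene_id", "is_de")], by = "gene_id")
  p <- m$p_value[!m$is_de & !is.na(m$p_value)]
  if (!length(p)) pb_stop("no null genes with observed p-values",
                          "pb_value_error")
  zero_rep <- NA_real_
  if (any(p == 0)) {
    pos <- p[p > 0]
    if (!length(pos)) pb_stop("all null p-values are zero", "pb_value_error")
    zero_rep <- min(pos)
    p[p == 0] <- zero_rep
  }
  mlen <- length(p)
  out <- data.frame(expected = -log10(seq_len(mlen) / (mlen + 1)),
                    observed = -log10(sort(p)))
  attr(out, "zero_replacement") <- zero_rep
  out
}

#' Histogram of null p-values
#'
#' @param results Result table.
#' @param truth Truth table.
#' @param bins Number of equal-width bins on \[0, 1\] (default 20).
#' @return A `data.frame` with columns `lower`, `upper`, `count`; counts
#'   sum to the number of null genes with observed p-values.
#' @export
pvalue_histogram <- function(results, truth, bins = 20L) {
  m <- merge(results[, c("gene_id", "p_value")],
             truth[, c("gene_id", "is_de")], by = "gene_id")
  p <- m$p_value[!m$is_de & !is.na(m$p_value)]
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- hist(p, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = TRUE)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = h$counts)
}

#' Aggregate evaluation curves across datasets
#'
#' Keeps every individual curve (the spread across plasmodes or simulated
#' datasets is itself informative) and adds a pointwise mean curve on the
#' union of all thresholds, with each curve carried to the common grid by
#' right-continuous step interpolation.
#'
#' @param curves Non-empty list of curve data frames whose first column is
#'   the threshold and remaining columns are rates.
#' @return `list(curves, mean)` where `mean` is a data frame on the common
#'   grid.
#' @export
aggregate_curves <- function(curves) {
  if (!length(curves)) pb_stop("no curves to aggregate", "pb_value_error")
  xcol <- names(curves[[1]])[1]
  ycols <- names(curves[[1]])[-1]
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv[[xcol]]))))
  acc <- matrix(0, length(grid), length(ycols),
                dimnames = list(NULL, ycols))
  for (cv in curves) {
    for (y in ycols) {
      f <- stats::approxfun(cv[[xcol]], cv[[y]], method = "constant",
                            rule = 2, f = 0, ties = "ordered")
      acc[, y] <- acc[, y] + f(grid)
    }
  }
  mean_curve <- data.frame(grid, acc / length(curves))
  names(mean_curve)[1] <- xcol
  list(curves = curves, mean = mean_curve)
}
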