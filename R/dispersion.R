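#' Build a model specification from a design table
#'
#' Encodes the full and reduced models as design matrices with
#' treatment-contrast (first-level baseline) coding. The tested term is
#' always `treatment`; with more than one block level the block enters both
#' models as a fixed effect (`full = ~ block + treatment`,
#' `reduced = ~ block`), mirroring a blocked two-group comparison.
#'
#' @param design Design table (one row per biological sample).
#' @param include_block `"auto"` (block included when > 1 level), `"yes"`,
#'   or `"no"`.
#' @return A list of class `"model_spec"` with `X_full`, `X_reduced`,
#'   `df_test`, `treatment`, `block`, `design`.
#' @export
model_spec <- function(design, include_block = c("auto", "yes", "no")) {
  include_block <- match.arg(include_block)
  treatment <- factor(design$treatment)
  block <- factor(design$block)
  if (nlevels(treatment) < 2L) {
    pb_stop("model_spec needs at least 2 treatment levels", "pb_value_error")
  }
  use_block <- switch(include_block,
                      auto = nlevels(block) > 1L,
                      yes = TRUE, no = FALSE)
  df <- data.frame(treatment = treatment, block = block)
  if (use_block) {
    X_full <- stats::model.matrix(~ block + treatment, df)
    X_reduced <- stats::model.matrix(~ block, df)
  } else {
    X_full <- stats::model.matrix(~ treatment, df)
    X_reduced <- stats::model.matrix(~ 1, df)
  }
  r_full <- qr(X_full)$rank
  if (r_full < ncol(X_full)) {
    pb_stop(sprintf(
      "design matrix is rank deficient: aliased column '%s'",
      colnames(X_full)[qr(X_full)$pivot[(r_full + 1):ncol(X_full)]][1]),
      "pb_value_error")
  }
  structure(list(X_full = X_full, X_reduced = X_reduced,
                 df_test = ncol(X_full) - qr(X_reduced)$rank,
                 treatment = treatment, block = block, design = design),
            class = "model_spec")
}

default_phi_grid <- function(length_out = 15L, range = c(1e-6, 10)) {
  exp(seq(log(range[1]), log(range[2]), length.out = length_out))
}

# quadratic interpolation of the per-gene maximizer on a log-phi grid
interpolate_max <- function(logphi, score) {
  i <- max.col(score, ties.method = "first")
  G <- length(logphi)
  out <- logphi[i]
  interior <- i > 1L & i < G
  if (any(interior)) {
    idx <- which(interior)
    x0 <- logphi[i[idx] - 1L]; x1 <- logphi[i[idx]]; x2 <- logphi[i[idx] + 1L]
    y0 <- score[cbind(idx, i[idx] - 1L)]
    y1 <- score[cbind(idx, i[idx])]
    y2 <- score[cbind(idx, i[idx] + 1L)]
    denom <- (y0 - y1) * (x1 - x2) - (y1 - y2) * (x0 - x1)
    vertex <- ifelse(abs(denom) > 0,
                     ((y0 - y1) * (x1^2 - x2^2) - (y1 - y2) * (x0^2 - x1^2)) /
                       (2 * denom),
                     x1)
    out[idx] <- pmin(pmax(vertex, x0), x2)
  }
  out
}

#' Estimate NB dispersions under one of three sharing policies
#'
#' * `common`: one dispersion maximizing the summed Cox-Reid adjusted
#'   profile log-likelihood (APL) across genes, searched on
#'   `[1e-6, 10]`.
#' * `tagwise_shrunk`: per-gene dispersion maximizing
#'   `APL_g(phi) + w0 * mean_g APL(phi)`, i.e. the gene's own APL shrunk
#'   toward the all-gene average with a prior weight of `w0` gene
#'   equivalents (default 10).
#' * `trend_max`: per-gene method-of-moments estimate
#'   `max(0, (s2 - ybar) / ybar^2)` on size-factor-scaled counts pooled
#'   within conditions, a hyperbolic trend `phi(mu) = a0 + a1 / mu` fitted
#'   by least squares over genes with positive estimates, and the final
#'   dispersion the maximum of the gene estimate and the trend value.
#'
#' @param counts Filtered count matrix (technical replicates collapsed).
#' @param spec A [model_spec()].
#' @param offsets Per-sample natural-log offsets.
#' @param policy `"common"`, `"tagwise_shrunk"`, or `"trend_max"`.
#' @param w0 Prior weight (gene equivalents) for tagwise shrinkage.
#' @param grid Dispersion grid for the APL policies.
#' @return A `data.frame` with columns `gene_id`, `phi`, `policy`.
#' @export
estimate_dispersion <- function(counts, spec, offsets,
                                policy = c("tagwise_shrunk", "common",
                                           "trend_max"),
                                w0 = 10, grid = default_phi_grid()) {
  policy <- match.arg(policy)
  Y <- as.matrix(counts)
  n <- ncol(Y)
  p <- ncol(spec$X_full)
  if (n - p < 2L) {
    pb_stop("fewer than 2 residual degrees of freedom: dispersion unidentifiable",
            "pb_value_error")
  }
  phi <- switch(policy,
    common = {
      f <- function(lp) sum(nb_apl(Y, spec$X_full, offsets, exp(lp)))
      opt <- stats::optimize(f, interval = log(range(grid)), maximum = TRUE,
                             tol = 1e-3)
      rep(exp(opt$maximum), nrow(Y))
    },
    tagwise_shrunk = {
      apl <- vapply(grid, function(ph) nb_apl(Y, spec$X_full, offsets, ph),
                    numeric(nrow(Y)))
      apl <- matrix(apl, nrow = nrow(Y))
      score <- apl + w0 * matrix(colMeans(apl), nrow(Y), length(grid),
                                 byrow = TRUE)
      exp(interpolate_max(log(grid), score))
    },
    trend_max = dispersion_trend_max(Y, spec$treatment, offsets)
  )
  data.frame(gene_id = rownames(counts), phi = phi, policy = policy,
             row.names = NULL, stringsAsFactors = FALSE)
}

dispersion_trend_max <- function(Y, condition, offsets) {
  s <- exp(offsets)
  s <- s / geometric_mean(s)
  q <- sweep(Y, 2L, s, `/`)
  ybar <- rowMeans(q)
  cond <- factor(condition)
  num <- 0; den <- 0
  for (lev in levels(cond)) {
    cols <- which(cond == lev)
    if (length(cols) >= 2L) {
      v <- apply(q[, cols, drop = FALSE], 1L, stats::var)
      num <- num + (length(cols) - 1L) * v
      den <- den + (length(cols) - 1L)
    }
  }
  if (den == 0) {
    pb_stop("no condition has 2 or more replicates: dispersion unidentifiable",
            "pb_value_error")
  }
  s2 <- num / den
  raw <- pmax(0, (s2 - ybar) / ybar^2)
  pos <- raw > 0 & ybar > 0
  trend <- rep(0, length(raw))
  if (sum(pos) >= 2L) {
    fit <- stats::lm.fit(cbind(1, 1 / ybar[pos]), raw[pos])
    a <- fit$coefficients
    trend <- pmax(0, a[1] + a[2] / ybar)
  }
  pmax(raw, trend)
}
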