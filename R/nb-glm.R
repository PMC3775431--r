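#' Negative binomial GLM with fixed dispersion, fitted by IRLS
#'
#' Maximizes the negative binomial log-likelihood with log link at a fixed
#' dispersion `phi` (variance function `mu + phi * mu^2`); `phi = 0`
#' degenerates to the Poisson GLM. Convergence is declared when the
#' relative deviance change drops below `tol`; a gene that fails to converge
#' within `maxit` iterations is flagged, not raised.
#'
#' @param y Integer count vector for one gene.
#' @param X Design matrix (samples x coefficients), full column rank.
#' @param offset Per-sample offset on the natural-log scale (e.g. log
#'   effective library size).
#' @param phi NB dispersion, a single value >= 0.
#' @param tol Relative deviance convergence tolerance (default 1e-8).
#' @param maxit Maximum IRLS iterations (default 50).
#' @return A list with `coefficients`, `fitted` (mean vector), `deviance`,
#'   `converged`.
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), phi = 0,
                       tol = 1e-8, maxit = 50L) {
  fit <- nb_fit_matrix(matrix(y, nrow = 1L), X, offset, phi,
                       tol = tol, maxit = maxit)
  list(coefficients = stats::setNames(drop(fit$coefficients), colnames(X)),
       fitted = drop(fit$fitted),
       deviance = fit$deviance[1],
       converged = fit$converged[1])
}

# Vectorized IRLS across genes sharing one design matrix.
# Y: genes x samples; phi scalar or per-gene vector. The per-iteration
# normal equations are assembled with matrix products over all genes at
# once; only the small p x p solves loop over genes.
nb_fit_matrix <- function(Y, X, offset, phi, tol = 1e-8, maxit = 50L,
                          compute_cr = FALSE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  Tg <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(offset) == n)
  phi <- rep_len(phi, Tg)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XC <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]

  off <- matrix(offset, Tg, n, byrow = TRUE)
  mu <- Y + 0.125
  eta_x <- log(mu) - off # linear predictor net of offset; projected next step
  dev <- rep(Inf, Tg)
  converged <- rep(FALSE, Tg)
  beta <- matrix(0, Tg, p)

  for (it in seq_len(maxit)) {
    W <- mu / (1 + phi * mu)
    Z <- eta_x + (Y - mu) / mu
    A <- W %*% XC            # packed upper triangles of X' W X, per gene
    B <- (W * Z) %*% X       # X' W z, per gene
    M <- matrix(0, p, p)
    for (g in seq_len(Tg)) {
      M[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
      M[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
      bg <- tryCatch(solve(M, B[g, ]), error = function(e) beta[g, ])
      beta[g, ] <- bg
    }
    eta_x <- tcrossprod(beta, X)
    expo <- pmin(pmax(eta_x + off, -700), 700)
    mu <- pmax(exp(expo), 1e-8)
    dev_new <- nb_deviance(Y, mu, phi)
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    converged <- converged | done
    dev <- dev_new
    if (all(done)) break
  }

  out <- list(coefficients = beta, fitted = mu, deviance = dev,
              converged = converged)
  if (compute_cr) {
    W <- mu / (1 + phi * mu)
    A <- W %*% XC
    M <- matrix(0, p, p)
    half_logdet <- numeric(Tg)
    for (g in seq_len(Tg)) {
      M[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
      M[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
      ch <- tryCatch(chol(M), error = function(e) NULL)
      half_logdet[g] <- if (is.null(ch)) NA_real_ else sum(log(diag(ch)))
    }
    out$cr_adjustment <- half_logdet
  }
  out
}

#' Negative binomial deviance and log-likelihood
#'
#' Row-wise (per-gene) deviance of counts `Y` around fitted means `mu` at
#' dispersion `phi`; `phi = 0` gives the Poisson deviance.
#'
#' @param Y Count matrix (genes x samples) or vector.
#' @param mu Fitted means, same shape.
#' @param phi Dispersion, scalar or per-gene.
#' @return Numeric vector of per-gene deviances.
#' @export
nb_deviance <- function(Y, mu, phi) {
  Y <- rbind(Y)[, , drop = FALSE]
  mu <- rbind(mu)[, , drop = FALSE]
  phi <- rep_len(phi, nrow(Y))
  ylogy <- Y * log(ifelse(Y > 0, Y / mu, 1))
  pois <- phi < 1e-12
  out <- numeric(nrow(Y))
  if (any(pois)) {
    out[pois] <- 2 * rowSums((ylogy - (Y - mu))[pois, , drop = FALSE])
  }
  if (any(!pois)) {
    i <- !pois
    ph <- phi[i]
    Yi <- Y[i, , drop = FALSE]; mi <- mu[i, , drop = FALSE]
    out[i] <- 2 * rowSums(ylogy[i, , drop = FALSE] -
      (Yi + 1 / ph) * log((1 + ph * Yi) / (1 + ph * mi)))
  }
  out
}

#' @rdname nb_deviance
#' @return `nb_loglik`: per-gene log-likelihood at (`mu`, `phi`).
#' @export
nb_loglik <- function(Y, mu, phi) {
  Y <- rbind(Y)[, , drop = FALSE]
  mu <- rbind(mu)[, , drop = FALSE]
  phi <- rep_len(phi, nrow(Y))
  out <- numeric(nrow(Y))
  pois <- phi < 1e-12
  if (any(pois)) {
    out[pois] <- rowSums(matrix(
      stats::dpois(Y[pois, , drop = FALSE], mu[pois, , drop = FALSE],
                   log = TRUE),
      nrow = sum(pois)))
  }
  if (any(!pois)) {
    i <- which(!pois)
    out[i] <- rowSums(matrix(
      stats::dnbinom(Y[i, , drop = FALSE], size = 1 / phi[i],
                     mu = mu[i, , drop = FALSE], log = TRUE),
      nrow = length(i)))
  }
  out
}

# Cox-Reid adjusted profile log-likelihood per gene at a common phi:
# profile log-likelihood at the constrained MLE of the mean parameters,
# minus half the log-determinant of the observed information of those
# parameters (invariant in phi up to parameterization).
nb_apl <- function(Y, X, offset, phi, tol = 1e-6, maxit = 30L) {
  fit <- nb_fit_matrix(Y, X, offset, phi, tol = tol, maxit = maxit,
                       compute_cr = TRUE)
  nb_loglik(Y, fit$fitted, phi) - fit$cr_adjustment
}
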