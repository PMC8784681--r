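# Penalized Gaussian graphical model estimation: graphical lasso solved by
# block coordinate descent (outer loop over columns of the covariance
# estimate W, inner lasso coordinate descent), followed by model selection
# on a log-spaced penalty path via the extended BIC.

# One graphical lasso fit at penalty rho for correlation matrix Sig.
# Returns the precision matrix K (exact zeros off the selected support)
# or NULL if the fit failed to produce a usable model.
glasso_fit <- function(Sig, rho, maxit = 100, tol = 1e-5) {
  p <- ncol(Sig)
  W <- Sig
  diag(W) <- diag(Sig) + rho
  Beta <- matrix(0, p - 1, p)
  off_scale <- mean(abs(Sig[upper.tri(Sig)]))
  if (off_scale == 0) off_scale <- 1
  for (it in seq_len(maxit)) {
    W_prev <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- Sig[idx, j]
      b <- Beta[, j]
      for (sweep in 1:200) {
        delta <- 0
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * b) + W11[k, k] * b[k]
          bk <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
          delta <- max(delta, abs(bk - b[k]))
          b[k] <- bk
        }
        if (delta < tol) break
      }
      Beta[, j] <- b
      w12 <- as.vector(W11 %*% b)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_prev)) < tol * off_scale) break
  }
  # Back out the precision matrix from the regression coefficients.
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    b <- Beta[, j]
    k22 <- 1 / (W[j, j] - sum(W[idx, j] * b))
    if (!is.finite(k22) || k22 <= 0) return(NULL)
    K[j, j] <- k22
    K[idx, j] <- -b * k22
  }
  # Support by the OR rule over the two regressions of each pair, then
  # symmetrize the surviving entries.
  supp <- (K != 0) | t(K != 0)
  K <- (K + t(K)) / 2
  K[!supp] <- 0
  K
}

# Gaussian log-likelihood (up to constants) of precision K for correlation R.
gauss_loglik <- function(K, R, n) {
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) return(NA_real_)
  (n / 2) * (as.numeric(ld$modulus) - sum(R * K))
}

# Repair a non-PSD correlation matrix by clipping negative eigenvalues at
# zero (plus a tiny jitter) and renormalizing to unit diagonal.
psd_repair <- function(R, tol = 1e-8, context = "correlation matrix") {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= -tol) return(R)
  warn(paste0("Repairing non-positive-semi-definite ", context,
              " by eigenvalue clipping (min eigenvalue ",
              format(min(ev$values), digits = 3), ")."))
  vals <- pmax(ev$values, tol)
  R2 <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Estimate a partial-correlation network by EBIC-selected graphical lasso
#'
#' Fits penalized Gaussian graphical models along a log-spaced path of
#' `n_lambda` lasso penalties, starting from the smallest penalty that gives
#' an empty graph, and selects the model minimizing the extended Bayesian
#' information criterion `-2 loglik + E log(S) + 4 E gamma log(N)`, where
#' `E` is the number of selected edges.  The input is the Spearman
#' correlation matrix of the data (repaired to positive semi-definiteness
#' by eigenvalue clipping if needed); edge weights are the partial
#' correlations `-K_ij / sqrt(K_ii K_jj)` of the selected precision matrix.
#'
#' @inheritParams estimate_network
#' @return A [new_network()] object with the selected penalty recorded in
#'   `params`.
#' @export
ebicglasso_network <- function(data, vars = NULL, gamma = 0.5,
                               n_lambda = 100, lambda_min_ratio = 0.01) {
  parsed <- sm_parse(data, vars)
  X <- parsed$values
  check_nonconstant(X)
  fit <- ebicglasso_core(X, gamma, n_lambda, lambda_min_ratio)
  new_network(fit$P, var_labels = parsed$var_labels, method = "ebicglasso",
              params = list(gamma = gamma, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio,
                            lambda = fit$lambda, ebic = fit$ebic),
              assoc = fit$R, n_samples = nrow(X))
}

# Matrix-level core shared with the permutation engine.
ebicglasso_core <- function(X, gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01) {
  if (gamma < 0) abort("`gamma` must be non-negative.")
  if (n_lambda < 2) abort("`n_lambda` must be at least 2.")
  S <- nrow(X)
  N <- ncol(X)
  R <- cor(apply(X, 2, rank))
  R <- psd_repair(R, context = "Spearman correlation matrix")
  lambda_max <- max(abs(R[upper.tri(R)]))
  if (lambda_max == 0) lambda_max <- 1e-3
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  best <- NULL
  best_ebic <- Inf
  best_lambda <- NA_real_
  n_failed <- 0L
  for (lam in lambdas) {
    K <- glasso_fit(R, lam)
    ll <- if (is.null(K)) NA_real_ else gauss_loglik(K, R, S)
    if (is.null(K) || is.na(ll)) {
      n_failed <- n_failed + 1L
      next
    }
    E <- sum(K[upper.tri(K)] != 0)
    ebic <- -2 * ll + E * log(S) + 4 * E * gamma * log(N)
    if (ebic < best_ebic) {
      best_ebic <- ebic
      best <- K
      best_lambda <- lam
    }
  }
  if (n_failed > 0) {
    warn(paste0("Skipped ", n_failed, " penalty value(s) where the ",
                "penalized estimation did not converge."))
  }
  if (is.null(best)) abort("Penalized estimation failed at every penalty value.")
  d <- sqrt(diag(best))
  P <- -best / outer(d, d)
  diag(P) <- 0
  dimnames(P) <- list(colnames(X), colnames(X))
  list(P = P, lambda = best_lambda, ebic = best_ebic, R = R)
}
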