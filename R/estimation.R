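#' Pairwise Spearman associations with p-values
#'
#' Computes the matrix of Spearman rank correlations between all variable
#' pairs (average ranks under ties) and two-sided p-values from the
#' large-sample t approximation `t = r * sqrt((S - 2) / (1 - r^2))` on
#' `S - 2` degrees of freedom.
#'
#' @param data Samples-by-variables data frame (see [read_sample_matrix()]).
#' @param vars Optional character vector selecting the variable columns.
#' @return A list with symmetric matrices `assoc` (unit diagonal) and
#'   `pvals` (diagonal `NA`).
#' @export
spearman_assoc <- function(data, vars = NULL) {
  X <- sm_parse(data, vars)$values
  check_nonconstant(X)
  spearman_assoc_mat(X)
}

# Matrix-level fast path shared with the permutation engine.
spearman_assoc_mat <- function(X) {
  S <- nrow(X)
  R <- apply(X, 2, rank)
  assoc <- cor(R)
  r <- pmin(pmax(assoc, -1), 1)
  tt <- r * sqrt((S - 2) / pmax(1 - r^2, .Machine$double.eps))
  pvals <- 2 * pt(-abs(tt), df = S - 2)
  pvals[abs(r) >= 1 - 1e-12] <- 0
  diag(assoc) <- 1
  diag(pvals) <- NA_real_
  dimnames(pvals) <- dimnames(assoc)
  list(assoc = assoc, pvals = pvals)
}

#' Adjust a vector of p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the three policies
#' used when drawing network edges: no adjustment, Bonferroni
#' (`min(1, m * p)`), and Benjamini-Hochberg step-up.  Adjustment is meant
#' to be applied once per network, over the `N(N-1)/2` unique variable pairs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"none"`, `"bonferroni"`, `"bh"`.
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "bh")) {
  method <- match.arg(tolower(method[1]), c("none", "bonferroni", "bh"))
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  switch(method,
         none = p,
         bonferroni = p.adjust(p, "bonferroni"),
         bh = p.adjust(p, "BH"))
}

#' Threshold an association matrix into a weighted network
#'
#' Keeps the association value as edge weight where the (adjusted) p-value
#' is at most `alpha`, and sets the weight to zero otherwise.  Adjustment is
#' applied over the unique upper-triangle pairs only.
#'
#' @param assoc Symmetric association matrix.
#' @param pvals Symmetric p-value matrix (diagonal ignored).
#' @param alpha Significance threshold for drawing an edge (default 0.05).
#' @param adjust Multiple-testing policy, see [adjust_pvalues()].
#' @param method Estimator tag stored in the result.
#' @param params Extra estimator settings stored in the result.
#' @param n_samples Optional sample count stored in the result.
#' @return A [new_network()] object.
#' @export
threshold_network <- function(assoc, pvals, alpha = 0.05,
                              adjust = c("bh", "bonferroni", "none"),
                              method = "spearman", params = list(),
                              n_samples = NULL) {
  adjust <- match.arg(tolower(adjust[1]), c("bh", "bonferroni", "none"))
  assoc <- as.matrix(assoc)
  pvals <- as.matrix(pvals)
  if (!identical(dim(assoc), dim(pvals))) {
    abort("`assoc` and `pvals` must have the same dimensions.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  n <- ncol(assoc)
  ut <- upper.tri(assoc)
  padj_vec <- adjust_pvalues(pvals[ut], adjust)
  W <- matrix(0, n, n)
  keep <- !is.na(padj_vec) & padj_vec <= alpha
  W[ut] <- ifelse(keep, assoc[ut], 0)
  W <- W + t(W)
  padj <- matrix(NA_real_, n, n)
  padj[ut] <- padj_vec
  padj <- pmin(padj, t(padj), na.rm = TRUE)
  diag(padj) <- NA_real_
  dimnames(W) <- dimnames(assoc)
  dimnames(padj) <- dimnames(assoc)
  new_network(W, var_labels = colnames(assoc), method = method,
              params = c(list(alpha = alpha, adjust = adjust), params),
              assoc = assoc, pvals = pvals, pvals_adj = padj,
              n_samples = n_samples)
}

# ---- distance correlation ----------------------------------------------

# Double-centered distance matrix of a numeric vector.
dcor_center <- function(x) {
  D <- abs(outer(x, x, "-"))
  rm <- rowMeans(D)
  D - rm - rep(rm, each = length(x)) + mean(D)
}

# Sample distance covariance/correlation from centered matrices.
dcov2 <- function(A, B) mean(A * B)

#' Sample distance correlation of two vectors
#'
#' The classical (biased) sample distance correlation, in `[0, 1]`, zero in
#' the population if and only if the two variables are independent, and
#' sensitive to nonlinear dependence.
#'
#' @param x,y Numeric vectors of equal length (at least 4 values).
#' @return A scalar in `[0, 1]`.
#' @export
dcor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    abort("`x` and `y` must have equal length >= 4.")
  }
  A <- dcor_center(x)
  B <- dcor_center(y)
  vx <- dcov2(A, A)
  vy <- dcov2(B, B)
  if (vx <= 0 || vy <= 0) abort("Distance variance is zero (constant input).")
  sqrt(max(dcov2(A, B), 0) / sqrt(vx * vy))
}

#' Pairwise distance correlations with permutation p-values
#'
#' Distance correlation for every variable pair, with p-values from a
#' permutation test of independence: one variable of the pair is permuted
#' `n_perm` times and the p-value is `(1 + #{dCov_perm >= dCov_obs}) /
#' (1 + n_perm)` (the add-one convention standard for permutation
#' independence tests, which keeps p strictly positive).
#'
#' @inheritParams spearman_assoc
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Optional integer seed making the permutations reproducible.
#' @return A list with matrices `assoc` (unit diagonal) and `pvals`.
#' @export
dcor_assoc <- function(data, vars = NULL, n_perm = 1000, seed = NULL) {
  X <- sm_parse(data, vars, min_samples = 4L)$values
  check_nonconstant(X)
  with_seed_opt(seed, dcor_assoc_mat(X, n_perm))
}

dcor_assoc_mat <- function(X, n_perm) {
  S <- nrow(X)
  N <- ncol(X)
  cent <- lapply(seq_len(N), function(j) dcor_center(X[, j]))
  dvar <- vapply(cent, function(A) dcov2(A, A), numeric(1))
  assoc <- diag(1, N)
  pvals <- matrix(NA_real_, N, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      A <- cent[[i]]
      B <- cent[[j]]
      obs <- dcov2(A, B)
      assoc[i, j] <- assoc[j, i] <- sqrt(max(obs, 0) / sqrt(dvar[i] * dvar[j]))
      ge <- 0L
      for (m in seq_len(n_perm)) {
        p <- sample.int(S)
        if (dcov2(A, B[p, p]) >= obs) ge <- ge + 1L
      }
      pvals[i, j] <- pvals[j, i] <- (1 + ge) / (1 + n_perm)
    }
  }
  dimnames(assoc) <- list(colnames(X), colnames(X))
  dimnames(pvals) <- dimnames(assoc)
  list(assoc = assoc, pvals = pvals)
}

# ---- dispatcher ---------------------------------------------------------

#' Estimate a weighted network from a sample table
#'
#' Dispatches to one of three estimators: pairwise Spearman correlation
#' (`"spearman"`), pairwise distance correlation (`"dcor"`) -- both pruned
#' by thresholding (adjusted) p-values at `alpha` -- or the EBIC-selected
#' graphical lasso (`"ebicglasso"`), whose weights are the partial
#' correlations of the selected penalized precision matrix.
#'
#' @inheritParams spearman_assoc
#' @param method Estimator: `"spearman"`, `"dcor"` or `"ebicglasso"`.
#' @param alpha Edge-inclusion threshold on (adjusted) p-values.
#' @param adjust Multiple-testing policy (`"bh"`, `"bonferroni"`, `"none"`).
#' @param gamma EBIC hyperparameter in `[0, 0.5]`; larger values prefer
#'   sparser models.
#' @param n_lambda,lambda_min_ratio Size and range of the lasso penalty path.
#' @param dcor_n_perm Permutation replicates for the dCor independence test.
#' @param seed Optional seed (used by the dCor permutation test).
#' @return A [new_network()] object.
#' @export
estimate_network <- function(data, vars = NULL,
                             method = c("spearman", "dcor", "ebicglasso"),
                             alpha = 0.05,
                             adjust = c("bh", "bonferroni", "none"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01,
                             dcor_n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(tolower(adjust[1]), c("bh", "bonferroni", "none"))
  switch(
    method,
    spearman = {
      a <- spearman_assoc(data, vars)
      threshold_network(a$assoc, a$pvals, alpha = alpha, adjust = adjust,
                        method = "spearman",
                        n_samples = nrow(sm_parse(data, vars)$values))
    },
    dcor = {
      a <- dcor_assoc(data, vars, n_perm = dcor_n_perm, seed = seed)
      threshold_network(a$assoc, a$pvals, alpha = alpha, adjust = adjust,
                        method = "dcor",
                        params = list(n_perm = dcor_n_perm, seed = seed),
                        n_samples = nrow(sm_parse(data, vars)$values))
    },
    ebicglasso = ebicglasso_network(data, vars, gamma = gamma,
                                    n_lambda = n_lambda,
                                    lambda_min_ratio = lambda_min_ratio)
  )
}
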