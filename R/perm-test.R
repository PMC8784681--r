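# Permutation test of network invariance.  Both networks are re-estimated
# from every permuted group assignment and the characteristic is recomputed,
# so the null distribution reflects the whole estimation pipeline.  The
# p-value is the printed estimator P = (1/M) * #{x_m >= x0}; the common
# (1 + #)/(1 + M) variant is deliberately not used here.

#' Randomly permute unpaired group labels
#'
#' Uniformly reassigns samples to groups while preserving both group sizes,
#' the unpaired permutation scheme of the network invariance test.
#'
#' @param group_labels Vector of group labels (two groups).
#' @param seed Optional integer seed.
#' @return A permuted label vector of the same length.
#' @export
permute_unpaired <- function(group_labels, seed = NULL) {
  if (length(unique(group_labels)) != 2) {
    abort("`group_labels` must contain exactly two groups.")
  }
  with_seed_opt(seed, sample(group_labels))
}

#' Randomly swap paired condition assignments
#'
#' Independently for each pair, swaps the two condition labels with
#' probability 1/2 -- the paired permutation scheme used for longitudinal
#' comparisons where both conditions are measured on the same subjects.
#'
#' @param pair_keys Vector of pair identifiers; each key must occur exactly
#'   twice.
#' @param group_labels Condition labels aligned with `pair_keys`; each pair
#'   must hold one sample per condition.
#' @param seed Optional integer seed.
#' @return A permuted label vector of the same length.
#' @export
permute_paired <- function(pair_keys, group_labels, seed = NULL) {
  tab <- table(pair_keys)
  if (any(tab != 2)) {
    abort("Every `pair_keys` value must occur exactly twice.")
  }
  if (any(table(pair_keys, group_labels) != 1)) {
    abort("Each pair must contain one sample per condition.")
  }
  with_seed_opt(seed, {
    keys <- unique(pair_keys)
    swap <- stats::runif(length(keys)) < 0.5
    names(swap) <- keys
    out <- as.character(group_labels)
    flip <- swap[as.character(pair_keys)]
    lev <- sort(unique(out))
    out[flip] <- ifelse(out[flip] == lev[1], lev[2], lev[1])
    out
  })
}

# ---- shared preparation -------------------------------------------------

# Split a two-group sample table into aligned matrices.  For paired data
# rows are ordered by pair key so row k of ZA and ZB belong to one subject.
prepare_two_groups <- function(data, group, vars, pair_key, paired) {
  data <- as_tibble(data)
  if (!group %in% names(data)) {
    abort(paste0("Grouping column `", group, "` not found."))
  }
  glab <- as.character(data[[group]])
  levels <- sort(unique(glab))
  if (length(levels) != 2) {
    abort("The grouping column must contain exactly two groups.")
  }
  parsed <- sm_parse(dplyr::select(data, !dplyr::all_of(group)), vars)
  X <- parsed$values
  iA <- which(glab == levels[1])
  iB <- which(glab == levels[2])
  pairs <- NULL
  if (paired) {
    if (is.null(pair_key) || !pair_key %in% names(data)) {
      abort("Paired permutation requires a `pair_key` column.")
    }
    pk <- as.character(data[[pair_key]])
    ka <- pk[iA]
    kb <- pk[iB]
    if (length(ka) != length(kb) || anyDuplicated(ka) || anyDuplicated(kb) ||
        !setequal(ka, kb)) {
      abort("Pair keys must match samples one-to-one across the two groups.")
    }
    iA <- iA[order(ka)]
    iB <- iB[order(kb)]
    pairs <- sort(ka)
  }
  list(ZA = X[iA, , drop = FALSE], ZB = X[iB, , drop = FALSE],
       levels = levels, var_labels = parsed$var_labels, pairs = pairs)
}

# Estimator closures used inside the permutation loop.
est_fun_factory <- function(method, opts) {
  if (method == "spearman") {
    function(X) {
      S <- nrow(X)
      n <- ncol(X)
      C <- cor(apply(X, 2, rank))
      ut <- upper.tri(C)
      r <- C[ut]
      tt <- r * sqrt((S - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tt), df = S - 2)
      p[abs(r) >= 1 - 1e-12] <- 0
      padj <- adjust_pvalues(p, opts$adjust)
      W <- matrix(0, n, n)
      W[ut] <- ifelse(padj <= opts$alpha, r, 0)
      W <- W + t(W)
      dimnames(W) <- dimnames(C)
      W
    }
  } else if (method == "dcor") {
    function(X) {
      a <- dcor_assoc_mat(X, opts$dcor_n_perm)
      ut <- upper.tri(a$assoc)
      padj <- adjust_pvalues(a$pvals[ut], opts$adjust)
      W <- matrix(0, ncol(X), ncol(X))
      W[ut] <- ifelse(padj <= opts$alpha, a$assoc[ut], 0)
      W <- W + t(W)
      dimnames(W) <- dimnames(a$assoc)
      W
    }
  } else if (method == "ebicglasso") {
    function(X) {
      ebicglasso_core(X, opts$gamma, opts$n_lambda, opts$lambda_min_ratio)$P
    }
  } else {
    abort(paste0("Unknown estimation method: ", method))
  }
}

# Core loop: pre-generates the permutation stream (so it depends only on
# the seed, not on which characteristics are evaluated), re-estimates both
# networks for every assignment and evaluates the statistic vector.
perm_engine <- function(ZA, ZB, est_fun, stat_fun, paired, M, seed,
                        enumerate = FALSE) {
  with_seed_opt(seed, {
    if (paired) {
      P <- nrow(ZA)
      if (enumerate) {
        if (2^P > 1e4) abort("Full enumeration limited to 2^pairs <= 10^4.")
        M <- as.integer(2^P)
        asn <- vapply(seq_len(M) - 1L,
                      function(m) as.logical(bitwAnd(m, bitwShiftL(1L, seq_len(P) - 1L))),
                      logical(P))
        asn <- matrix(asn, nrow = P)
      } else {
        asn <- matrix(stats::runif(P * M) < 0.5, P, M)
      }
    } else {
      SA <- nrow(ZA)
      Z <- rbind(ZA, ZB)
      Stot <- nrow(Z)
      if (enumerate) {
        n_all <- choose(Stot, SA)
        if (n_all > 1e4) abort("Full enumeration limited to C(S, S_A) <= 10^4.")
        asn <- combn(Stot, SA)
        M <- ncol(asn)
      } else {
        asn <- vapply(seq_len(M), function(m) sample.int(Stot, SA),
                      integer(SA))
        asn <- matrix(asn, nrow = SA)
      }
    }
    x0 <- stat_fun(est_fun(ZA), est_fun(ZB))
    stats <- matrix(NA_real_, length(x0), M)
    for (m in seq_len(M)) {
      if (paired) {
        sw <- asn[, m]
        XA <- ZA; XA[sw, ] <- ZB[sw, , drop = FALSE]
        XB <- ZB; XB[sw, ] <- ZA[sw, , drop = FALSE]
      } else {
        XA <- Z[asn[, m], , drop = FALSE]
        XB <- Z[-asn[, m], , drop = FALSE]
      }
      stats[, m] <- stat_fun(est_fun(XA), est_fun(XB))
    }
    list(x0 = x0, stats = stats, p = rowMeans(stats >= x0), M = M)
  })
}

collect_opts <- function(alpha, adjust, gamma, n_lambda, lambda_min_ratio,
                         dcor_n_perm) {
  adjust <- match.arg(tolower(adjust[1]), c("bh", "bonferroni", "none"))
  list(alpha = alpha, adjust = adjust, gamma = gamma, n_lambda = n_lambda,
       lambda_min_ratio = lambda_min_ratio, dcor_n_perm = dcor_n_perm)
}

# ---- single-characteristic test ----------------------------------------

#' Permutation test of network invariance for one characteristic
#'
#' Estimates the two group networks, computes the observed characteristic
#' `x0`, then re-estimates both networks under `M` random group
#' reassignments (label shuffles preserving group sizes when unpaired;
#' within-pair condition swaps when paired) and reports the approximate
#' p-value `P = (1/M) * #{x_m >= x0}`.  Ties count towards the p-value.
#'
#' @param data Data frame with variable columns, a two-level grouping
#'   column, and (for paired tests) a pair-key column.
#' @param characteristic One of `"global_strength"`, `"frobenius"`,
#'   `"max_metric"`, `"spectral"`, `"jaccard"`, `"n_edges"`, `"n_clusters"`,
#'   `"n_isolated"`, `"degree"`, `"edge_strength"`.
#' @param node_i,node_j Node labels, required for `"degree"` (`node_i`) and
#'   `"edge_strength"` (both).
#' @param group Name of the grouping column (default `"group"`).
#' @param vars Optional character vector selecting the variable columns.
#' @param pair_key Name of the pair-key column (paired tests only).
#' @param paired Use the within-pair swap scheme?
#' @param method,alpha,adjust,gamma,n_lambda,lambda_min_ratio,dcor_n_perm
#'   Estimator settings, see [estimate_network()].
#' @param M Number of permutation replicates (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @param enumerate Evaluate all distinct assignments instead of sampling
#'   (small instances only).
#' @return A `dnet_test` object; see [tidy.dnet_test()].
#' @export
permutation_test <- function(data, characteristic, node_i = NULL,
                             node_j = NULL, group = "group", vars = NULL,
                             pair_key = "pair_key", paired = FALSE,
                             method = c("spearman", "dcor", "ebicglasso"),
                             alpha = 0.05,
                             adjust = c("bh", "bonferroni", "none"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, dcor_n_perm = 200,
                             M = 10000, seed = NULL, enumerate = FALSE) {
  method <- match.arg(method)
  opts <- collect_opts(alpha, adjust, gamma, n_lambda, lambda_min_ratio,
                       dcor_n_perm)
  if (M < 1) abort("`M` must be at least 1.")
  prep <- prepare_two_groups(data, group, vars, pair_key, paired)
  plan <- characteristic_row(characteristic, node_i, node_j,
                             prep$var_labels)
  stat_fun <- make_stat_fun(plan, prep$var_labels)
  est_fun <- est_fun_factory(method, opts)
  res <- perm_engine(prep$ZA, prep$ZB, est_fun, stat_fun, paired, M, seed,
                     enumerate)
  structure(
    list(characteristic = characteristic, node_i = node_i, node_j = node_j,
         x0 = unname(res$x0), perm_values = as.numeric(res$stats),
         p_value = unname(res$p), M = res$M, paired = paired, seed = seed,
         method = method, params = opts, groups = prep$levels),
    class = "dnet_test"
  )
}

# Validate a single-characteristic request.
characteristic_row <- function(characteristic, node_i, node_j, var_labels) {
  valid <- c(overall_characteristics, "degree", "edge_strength")
  if (!characteristic %in% valid) {
    abort(paste0("Unknown characteristic: ", characteristic))
  }
  if (characteristic == "degree") {
    if (is.null(node_i)) abort("`degree` requires `node_i`.")
    if (!node_i %in% var_labels) abort(paste0("Unknown node: ", node_i))
  } else if (characteristic == "edge_strength") {
    if (is.null(node_i) || is.null(node_j)) {
      abort("`edge_strength` requires `node_i` and `node_j`.")
    }
    if (!all(c(node_i, node_j) %in% var_labels)) {
      abort("Unknown node label(s) for `edge_strength`.")
    }
  } else if (!is.null(node_i) || !is.null(node_j)) {
    abort("Node arguments are only used for `degree` and `edge_strength`.")
  }
  tibble(characteristic = characteristic,
         node_i = node_i %||% NA_character_,
         node_j = node_j %||% NA_character_)
}

#' @export
print.dnet_test <- function(x, ...) {
  cat("<dnet_test> ", x$characteristic,
      if (!is.null(x$node_i) && !is.na(x$node_i)) paste0(" [", x$node_i,
        if (!is.null(x$node_j) && !is.na(x$node_j)) paste0("-", x$node_j), "]"),
      ": x0 = ", signif(x$x0, 4), ", p = ", signif(x$p_value, 4),
      " (M = ", x$M, ", ", if (x$paired) "paired" else "unpaired", ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a single-characteristic permutation test
#'
#' @param x A `dnet_test`.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value and test
#'   settings.
#' @export
tidy.dnet_test <- function(x, ...) {
  tibble(characteristic = x$characteristic,
         node_i = x$node_i %||% NA_character_,
         node_j = x$node_j %||% NA_character_,
         x0 = x$x0, p_value = x$p_value, M = x$M, paired = x$paired,
         method = x$method)
}

#' @rdname tidy.dnet_test
#' @export
glance.dnet_test <- function(x, ...) tidy(x, ...)

#' Plot the permutation null distribution of a test
#'
#' Histogram of the permuted statistic values with the observed value
#' marked; the p-value is the fraction of the null mass at or beyond the
#' line.
#'
#' @param object A `dnet_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnet_test <- function(object, ...) {
  df <- tibble(x = object$perm_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$x0, colour = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(x = object$characteristic, y = "count",
                  title = paste0("Permutation null (p = ",
                                 signif(object$p_value, 3), ", M = ",
                                 object$M, ")")) +
    ggplot2::theme_minimal()
}

# ---- exhaustive oracle --------------------------------------------------

#' Exact permutation test by full enumeration
#'
#' Evaluates the characteristic under every distinct group assignment
#' (all `C(S_A + S_B, S_A)` label assignments when unpaired, all
#' `2^pairs` swap patterns when paired) and returns the exact p-value under
#' the same `>=` convention as [permutation_test()].  Intended as an oracle
#' for small instances; it deliberately goes through the public
#' estimation/characteristic functions rather than the sampling engine.
#'
#' @inheritParams permutation_test
#' @return A list with `p_value`, `x0`, `values` (one statistic per
#'   assignment) and `M_all`.
#' @export
exhaustive_test <- function(data, characteristic, node_i = NULL,
                            node_j = NULL, group = "group", vars = NULL,
                            pair_key = "pair_key", paired = FALSE,
                            method = c("spearman", "dcor", "ebicglasso"),
                            alpha = 0.05,
                            adjust = c("bh", "bonferroni", "none"),
                            gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01, dcor_n_perm = 200,
                            seed = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(tolower(adjust[1]), c("bh", "bonferroni", "none"))
  prep <- prepare_two_groups(data, group, vars, pair_key, paired)
  characteristic_row(characteristic, node_i, node_j, prep$var_labels)
  est <- function(X) {
    estimate_network(as_tibble(as.data.frame(X)), method = method,
                     alpha = alpha, adjust = adjust, gamma = gamma,
                     n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                     dcor_n_perm = dcor_n_perm, seed = seed)
  }
  stat <- function(A, B) {
    switch(characteristic,
           global_strength = global_strength_diff(A, B),
           frobenius = frobenius_distance(A, B),
           max_metric = max_metric_distance(A, B),
           spectral = spectral_distance(A, B),
           jaccard = jaccard_distance(A, B),
           n_edges = edge_count_diff(A, B),
           n_clusters = cluster_count_diff(A, B),
           n_isolated = isolated_count_diff(A, B),
           degree = degree_diff(A, B, node_i),
           edge_strength = edge_strength_diff(A, B, node_i, node_j))
  }
  ZA <- prep$ZA
  ZB <- prep$ZB
  x0 <- stat(est(ZA), est(ZB))
  vals <- if (paired) {
    P <- nrow(ZA)
    if (2^P > 1e4) abort("Full enumeration limited to 2^pairs <= 10^4.")
    vapply(seq_len(2^P) - 1L, function(m) {
      sw <- as.logical(bitwAnd(m, bitwShiftL(1L, seq_len(P) - 1L)))
      XA <- ZA; XA[sw, ] <- ZB[sw, , drop = FALSE]
      XB <- ZB; XB[sw, ] <- ZA[sw, , drop = FALSE]
      stat(est(XA), est(XB))
    }, numeric(1))
  } else {
    Z <- rbind(ZA, ZB)
    if (choose(nrow(Z), nrow(ZA)) > 1e4) {
      abort("Full enumeration limited to C(S, S_A) <= 10^4.")
    }
    apply(combn(nrow(Z), nrow(ZA)), 2, function(iA) {
      stat(est(Z[iA, , drop = FALSE]), est(Z[-iA, , drop = FALSE]))
    })
  }
  list(p_value = mean(vals >= x0), x0 = x0, values = vals,
       M_all = length(vals))
}

# ---- multi-characteristic comparison ------------------------------------

#' Compare two networks across many characteristics at once
#'
#' Runs the permutation test for a whole set of characteristics over one
#' shared permutation stream: each permuted assignment triggers a single
#' re-estimation of the two networks, from which every requested statistic
#' is computed.  With `characteristics = "all"` the result has one row per
#' overall characteristic, per node (degree) and per node pair (edge
#' strength): `8 + N + N(N-1)/2` rows.
#'
#' @inheritParams permutation_test
#' @param characteristics `"all"` or a subset of the characteristic ids.
#' @param comparison_id Optional label stored in the first column.
#' @param sig_level Significance threshold for the `significant` flag.
#' @return A `dnet_comparison` tibble with columns `comparison_id`,
#'   `characteristic`, `node_i`, `node_j`, `x0`, `p_value`, `M`, `paired`,
#'   `seed`, `significant`.
#' @export
compare_networks <- function(data, group = "group", vars = NULL,
                             characteristics = "all",
                             pair_key = "pair_key", paired = FALSE,
                             method = c("spearman", "dcor", "ebicglasso"),
                             alpha = 0.05,
                             adjust = c("bh", "bonferroni", "none"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, dcor_n_perm = 200,
                             M = 10000, seed = NULL, enumerate = FALSE,
                             comparison_id = NULL, sig_level = 0.05) {
  method <- match.arg(method)
  opts <- collect_opts(alpha, adjust, gamma, n_lambda, lambda_min_ratio,
                       dcor_n_perm)
  if (M < 1) abort("`M` must be at least 1.")
  prep <- prepare_two_groups(data, group, vars, pair_key, paired)
  plan <- characteristic_plan(characteristics, prep$var_labels)
  stat_fun <- make_stat_fun(plan, prep$var_labels)
  est_fun <- est_fun_factory(method, opts)
  res <- perm_engine(prep$ZA, prep$ZB, est_fun, stat_fun, paired, M, seed,
                     enumerate)
  out <- tibble(
    comparison_id = comparison_id %||% NA_character_,
    characteristic = plan$characteristic,
    node_i = plan$node_i,
    node_j = plan$node_j,
    x0 = unname(res$x0),
    p_value = unname(res$p),
    M = res$M,
    paired = paired,
    seed = seed %||% NA_integer_,
    significant = unname(res$p) <= sig_level
  )
  attr(out, "method") <- method
  attr(out, "params") <- opts
  attr(out, "groups") <- prep$levels
  class(out) <- c("dnet_comparison", class(out))
  out
}

#' Tidy a network comparison table
#'
#' @param x A `dnet_comparison`.
#' @param ... Unused.
#' @return The underlying tibble, without the extra class.
#' @export
tidy.dnet_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dnet_comparison")
  as_tibble(out)
}

#' One-row summary of a network comparison
#'
#' @param x A `dnet_comparison`.
#' @param ... Unused.
#' @return A tibble with the number of characteristics tested and flagged
#'   significant, and the test settings.
#' @export
glance.dnet_comparison <- function(x, ...) {
  tibble(n_characteristics = nrow(x),
         n_significant = sum(x$significant),
         min_p = min(x$p_value),
         M = x$M[1], paired = x$paired[1],
         method = attr(x, "method") %||% NA_character_)
}

#' Plot the p-values of a network comparison
#'
#' Dot plot of p-values by characteristic, with the significance threshold
#' marked; node- and edge-level rows are labelled by their nodes.
#'
#' @param object A `dnet_comparison`.
#' @param sig_level Threshold line to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnet_comparison <- function(object, sig_level = 0.05, ...) {
  df <- tidy(object)
  df$label <- ifelse(is.na(df$node_i), df$characteristic,
                     ifelse(is.na(df$node_j),
                            paste0("degree:", df$node_i),
                            paste0(df$node_i, "-", df$node_j)))
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(.data$p_value, .data$label)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = sig_level, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "permutation p-value", y = NULL) +
    ggplot2::theme_minimal()
}
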