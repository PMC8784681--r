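# Matched case-control study pipeline: window extraction, risk-set
# sampling, propensity + Mahalanobis matching with common-support and
# duplicate-control pruning, and the four cross-sectional/longitudinal
# network comparisons.
#
# Conventions: measurement times are hours since the encounter's admission;
# the admission window is [0, 24) anchored at 0, and the event window for a
# treatment duration L is [L - 48, L - 24) anchored at L (the 48-24 h span
# before death for cases, or before the length-of-stay-matched index time
# for controls).  Windows are half-open and the "closest to anchor" rule
# picks the recorded value nearest the anchor inside the window.

#' Extract one value from a time window of an encounter
#'
#' Restricts the measurements of one variable to a half-open time window
#' `[window[1], window[2])` (hours since admission) and summarizes them:
#' the value recorded closest to `anchor` (ties broken towards the earlier
#' timestamp), or the window mean or median.  Returns `NA` when no
#' measurement falls inside the window -- the documented "missing" signal
#' that marks the encounter ineligible for that window.
#'
#' @param measurements Tibble with columns `time`, `variable`, `value`
#'   (and optionally `encounter_id`, filtered via `encounter`).
#' @param variable Variable name to extract.
#' @param window Numeric length-2 vector, half-open interval in hours since
#'   admission.
#' @param anchor Time point the `"closest"` rule targets (defaults to the
#'   window start).
#' @param encounter Optional encounter id to filter on.
#' @param select Aggregation rule: `"closest"`, `"mean"` or `"median"`.
#' @return A single numeric value, `NA` if the window is empty.
#' @export
extract_window_value <- function(measurements, variable, window,
                                 anchor = window[1], encounter = NULL,
                                 select = c("closest", "mean", "median")) {
  select <- match.arg(select)
  m <- measurements
  if (!is.null(encounter)) m <- m[m$encounter_id == encounter, , drop = FALSE]
  m <- m[m$variable == variable & m$time >= window[1] & m$time < window[2], ,
         drop = FALSE]
  if (nrow(m) == 0) return(NA_real_)
  switch(select,
         closest = {
           ord <- order(abs(m$time - anchor), m$time)
           m$value[ord[1]]
         },
         mean = mean(m$value),
         median = median(m$value))
}

# Vectorized window extraction for many encounters at once.
# durations: tibble(encounter_id, duration); for the admission window pass
# duration = NA and window_type = "admission".
window_table <- function(measurements, encounter_ids, vars,
                         window_type = c("admission", "event"),
                         durations = NULL,
                         select = c("closest", "mean", "median")) {
  window_type <- match.arg(window_type)
  select <- match.arg(select)
  m <- measurements[measurements$encounter_id %in% encounter_ids &
                      measurements$variable %in% vars, , drop = FALSE]
  if (window_type == "admission") {
    m$lo <- 0
    m$hi <- 24
    m$anchor <- 0
  } else {
    d <- durations$duration[match(m$encounter_id, durations$encounter_id)]
    m$lo <- d - 48
    m$hi <- d - 24
    m$anchor <- d
  }
  m <- m[!is.na(m$lo) & m$time >= m$lo & m$time < m$hi, , drop = FALSE]
  out <- tibble(encounter_id = encounter_ids)
  if (nrow(m) == 0) {
    for (v in vars) out[[v]] <- NA_real_
    return(out)
  }
  agg <- switch(
    select,
    closest = {
      m <- m[order(m$encounter_id, m$variable, abs(m$time - m$anchor),
                   m$time), ]
      m[!duplicated(m[c("encounter_id", "variable")]),
        c("encounter_id", "variable", "value")]
    },
    mean = dplyr::summarise(dplyr::group_by(m, .data$encounter_id,
                                            .data$variable),
                            value = mean(.data$value), .groups = "drop"),
    median = dplyr::summarise(dplyr::group_by(m, .data$encounter_id,
                                              .data$variable),
                              value = median(.data$value), .groups = "drop")
  )
  wide <- tidyr::pivot_wider(agg, names_from = "variable",
                             values_from = "value")
  for (v in setdiff(vars, names(wide))) wide[[v]] <- NA_real_
  out <- dplyr::left_join(out, wide[c("encounter_id", vars)],
                          by = "encounter_id")
  out
}

#' Fit a propensity score for case status
#'
#' Logistic regression of the outcome on the configured covariates, the
#' standard reading of a Rosenbaum-Rubin propensity score.  Scores are the
#' fitted probabilities, strictly inside (0, 1); separation or
#' non-convergence is an error with diagnostics rather than a silent
#' degenerate score.
#'
#' @param data One row per encounter with the outcome and covariates.
#' @param outcome Name of the binary outcome column (default `"died"`).
#' @param covariates Character vector of covariate column names.
#' @return The input tibble with a `.ps` column appended.
#' @export
fit_propensity <- function(data, outcome = "died", covariates) {
  data <- as_tibble(data)
  missing_cov <- setdiff(c(outcome, covariates), names(data))
  if (length(missing_cov)) {
    abort(paste0("Missing column(s): ", paste(missing_cov, collapse = ", ")))
  }
  if (anyNA(data[c(outcome, covariates)])) {
    abort("Missing covariate or outcome values; propensity requires complete data.")
  }
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                  paste0("`", covariates, "`",
                                         collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = data)
  ps <- as.numeric(fitted(fit))
  if (!fit$converged || any(ps < 1e-10) || any(ps > 1 - 1e-10)) {
    abort(paste0("Propensity model did not yield usable scores ",
                 "(converged = ", fit$converged, ", score range [",
                 format(min(ps), digits = 3), ", ",
                 format(max(ps), digits = 3), "]). ",
                 "Check for separation or collinear covariates."))
  }
  data$.ps <- ps
  data
}

#' Risk set of potential controls for one case
#'
#' All encounters of the cohort (any survival status, the case excluded)
#' treated at least as long as the case, with complete admission-window
#' values and at least one recorded value of each network parameter in the
#' event window anchored at the control's index time (its admission plus
#' the case's treatment duration).
#'
#' @param case_id Encounter id of the case.
#' @param encounters Encounter table (`encounter_id`, `los_hours`, ...).
#' @param measurements Long measurement table (times in hours since
#'   admission).
#' @param vars Network parameter names.
#' @param select Window aggregation rule, see [extract_window_value()].
#' @return Tibble with `control_id` and `index_duration` (hours).
#' @export
build_risk_set <- function(case_id, encounters, measurements,
                           vars = organ_vars, select = "closest") {
  case <- encounters[encounters$encounter_id == case_id, , drop = FALSE]
  if (nrow(case) != 1) abort(paste0("Unknown case: ", case_id))
  dur <- case$los_hours
  cand <- encounters$encounter_id[encounters$los_hours >= dur &
                                    encounters$encounter_id != case_id]
  if (!length(cand)) {
    return(tibble(control_id = character(), index_duration = numeric()))
  }
  adm <- window_table(measurements, cand, vars, "admission", select = select)
  ok_adm <- stats::complete.cases(adm[vars])
  cand <- cand[ok_adm[match(cand, adm$encounter_id)]]
  if (!length(cand)) {
    return(tibble(control_id = character(), index_duration = numeric()))
  }
  evt <- window_table(measurements, cand, vars, "event",
                      durations = tibble(encounter_id = cand,
                                         duration = dur),
                      select = select)
  ok_evt <- stats::complete.cases(evt[vars])
  cand <- cand[ok_evt[match(cand, evt$encounter_id)]]
  tibble(control_id = sort(cand),
         index_duration = rep(dur, length(cand)))
}

#' Match the nearest control to each case
#'
#' For every case, selects from its risk set the control with the smallest
#' Mahalanobis distance computed from the log propensity score and the
#' admission values of the network parameters; the covariance is estimated
#' over all eligible encounters (ridge-inflated diagonal if near-singular).
#' Pairs whose case or control score falls outside the common support (the
#' largest interval containing scores of both survival groups) are dropped.
#'
#' @param risk_sets Named list: for each case id, a character vector of
#'   control ids.
#' @param ps Named numeric vector of propensity scores for all eligible
#'   encounters.
#' @param adm Numeric matrix of admission values (rows named by encounter
#'   id) for all eligible encounters.
#' @param case_flag Named logical vector: `TRUE` for cases (non-survivors),
#'   used for the common-support interval.
#' @param ridge Relative ridge added to the covariance diagonal when it is
#'   numerically singular.
#' @return Tibble of matched pairs (`case_id`, `control_id`, `ps_case`,
#'   `ps_control`, `delta`, `distance`) with attribute `support`.
#' @export
match_controls <- function(risk_sets, ps, adm, case_flag, ridge = 1e-6) {
  feat <- cbind(log_ps = log(ps[rownames(adm)]), adm)
  Sigma <- cov(feat)
  if (!is.finite(determinant(Sigma)$modulus) ||
      rcond_psd(Sigma) < 1e-12) {
    warn("Near-singular Mahalanobis covariance; inflating the diagonal.")
    Sigma <- Sigma + diag(ridge * mean(diag(Sigma)), ncol(Sigma))
  }
  Sigma_inv <- solve(Sigma)
  pairs <- purrr::map_dfr(sort(names(risk_sets)), function(cid) {
    ctr <- risk_sets[[cid]]
    if (!length(ctr)) return(NULL)
    ctr <- sort(ctr) # deterministic tie-break by control id
    d2 <- mahalanobis(feat[ctr, , drop = FALSE], feat[cid, ], Sigma_inv,
                      inverted = TRUE)
    best <- ctr[which.min(d2)]
    tibble(case_id = cid, control_id = best,
           ps_case = unname(ps[cid]), ps_control = unname(ps[best]),
           delta = unname(abs(ps[cid] - ps[best])),
           distance = unname(sqrt(min(d2))))
  })
  support <- common_support(ps, case_flag)
  if (nrow(pairs)) {
    inside <- pairs$ps_case >= support[1] & pairs$ps_case <= support[2] &
      pairs$ps_control >= support[1] & pairs$ps_control <= support[2]
    pairs <- pairs[inside, , drop = FALSE]
  }
  attr(pairs, "support") <- support
  pairs
}

# Vectorized risk-set construction over all cases at once; equivalent to
# calling build_risk_set() per case (asserted in the test suite) but works
# on precomputed atomic vectors.  Candidates here are the admission-eligible
# encounters (`enc_el`), as in the pipeline.
risk_sets_fast <- function(case_ids, enc_el, measurements, vars) {
  ids <- enc_el$encounter_id
  nv <- length(vars)
  m <- measurements[measurements$encounter_id %in% ids &
                      measurements$variable %in% vars, , drop = FALSE]
  enc_i <- match(m$encounter_id, ids)
  var_i <- match(m$variable, vars)
  tt <- m$time
  los <- enc_el$los_hours
  out <- lapply(setNames(case_ids, case_ids), function(cid) {
    dur <- los[match(cid, ids)]
    sel <- tt >= dur - 48 & tt < dur - 24
    code <- unique((enc_i[sel] - 1L) * nv + var_i[sel])
    cnt <- tabulate((code - 1L) %/% nv + 1L, nbins = length(ids))
    sort(ids[los >= dur & ids != cid & cnt == nv])
  })
  out
}

# Reciprocal condition number for a symmetric PSD matrix.
rcond_psd <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# Largest interval containing propensity scores of both groups.
common_support <- function(ps, case_flag) {
  cs <- ps[names(case_flag)[case_flag]]
  ct <- ps[names(case_flag)[!case_flag]]
  c(max(min(cs), min(ct)), min(max(cs), max(ct)))
}

#' Keep only the best pair per duplicated control
#'
#' A control selected for several cases would enter the control network
#' multiple times; among pairs sharing a control only the one with the
#' smallest propensity-score difference `delta` is retained (ties broken by
#' case id order).
#'
#' @param pairs Tibble of matched pairs with columns `case_id`,
#'   `control_id`, `delta`.
#' @return The pruned pairs tibble, ordered by case id.
#' @export
prune_duplicate_controls <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  ord <- order(pairs$control_id, pairs$delta, pairs$case_id)
  kept <- pairs[ord, , drop = FALSE]
  kept <- kept[!duplicated(kept$control_id), , drop = FALSE]
  kept[order(kept$case_id), , drop = FALSE]
}

#' Full matching pipeline on an encounter cohort
#'
#' Runs the whole control-selection procedure: admission-window completeness
#' filter, propensity model fit, risk-set construction per case (length of
#' stay at least the case's, event-window completeness at the index time),
#' Mahalanobis nearest-control matching, common-support filter, and
#' duplicate-control pruning.  Deterministic given the cohort: a permuted
#' row order yields identical pairs.
#'
#' @param encounters Encounter table, see [simulate_icu_cohort()].
#' @param measurements Long measurement table.
#' @param vars Network parameter names.
#' @param ps_covariates Non-network covariates entering the propensity
#'   model (the network parameters' admission values are always included).
#' @param select Window aggregation rule.
#' @param ridge Covariance ridge, see [match_controls()].
#' @return A `dnet_matching` object; `tidy()` gives the pairs table.
#' @export
match_cohort <- function(encounters, measurements, vars = organ_vars,
                         ps_covariates = c("age", "sex", "saps2m", "tiss10",
                                           "charlson", "catecholamines"),
                         select = "closest", ridge = 1e-6) {
  encounters <- dplyr::arrange(as_tibble(encounters), .data$encounter_id)
  if (any(encounters$los_hours < 72)) {
    abort("Cohort eligibility requires a length of stay of at least 72 h.")
  }
  if (any(encounters$died & !is.na(encounters$death_time) &
            encounters$death_time <= encounters$admission_time)) {
    abort("Death times must lie after admission.")
  }
  adm <- window_table(measurements, encounters$encounter_id, vars,
                      "admission", select = select)
  eligible <- encounters$encounter_id[stats::complete.cases(adm[vars])]
  enc_el <- encounters[encounters$encounter_id %in% eligible, , drop = FALSE]
  adm_el <- adm[match(eligible, adm$encounter_id), , drop = FALSE]
  ps_data <- dplyr::left_join(enc_el, adm_el, by = "encounter_id")
  ps_data <- fit_propensity(ps_data, outcome = "died",
                            covariates = c(ps_covariates, vars))
  ps <- setNames(ps_data$.ps, ps_data$encounter_id)
  case_flag <- setNames(enc_el$died, enc_el$encounter_id)
  # Cases additionally need complete event-window values before death.
  case_ids <- enc_el$encounter_id[enc_el$died]
  if (length(case_ids)) {
    evt_case <- window_table(measurements, case_ids, vars, "event",
                             durations = tibble(
                               encounter_id = case_ids,
                               duration = enc_el$los_hours[match(case_ids, enc_el$encounter_id)]),
                             select = select)
    case_ids <- case_ids[stats::complete.cases(evt_case[vars])]
  }
  risk_sets <- risk_sets_fast(case_ids, enc_el, measurements, vars)
  adm_mat <- as.matrix(adm_el[vars])
  rownames(adm_mat) <- adm_el$encounter_id
  pairs <- match_controls(risk_sets, ps, adm_mat, case_flag, ridge = ridge)
  n_matched <- nrow(pairs)
  pairs_pruned <- prune_duplicate_controls(pairs)
  structure(
    list(pairs = pairs_pruned, support = attr(pairs, "support"),
         ps = ps, eligible = eligible, case_ids = case_ids,
         n_before_pruning = n_matched,
         params = list(vars = vars, ps_covariates = ps_covariates,
                       select = select, ridge = ridge)),
    class = "dnet_matching"
  )
}

#' @export
print.dnet_matching <- function(x, ...) {
  cat("<dnet_matching> ", length(x$case_ids), " eligible cases, ",
      nrow(x$pairs), " matched pairs (",
      x$n_before_pruning - nrow(x$pairs),
      " dropped as duplicate controls)\n", sep = "")
  cat("  common support: [", format(x$support[1], digits = 3), ", ",
      format(x$support[2], digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a matching result into the pairs table
#' @param x A `dnet_matching`.
#' @param ... Unused.
#' @return Tibble with one row per retained case-control pair.
#' @export
tidy.dnet_matching <- function(x, ...) as_tibble(x$pairs)

#' One-row summary of a matching result
#' @param x A `dnet_matching`.
#' @param ... Unused.
#' @return Tibble with eligibility/matching counts and the common-support
#'   interval.
#' @export
glance.dnet_matching <- function(x, ...) {
  tibble(n_eligible = length(x$eligible),
         n_cases = length(x$case_ids),
         n_matched = x$n_before_pruning,
         n_pairs = nrow(x$pairs),
         support_lo = x$support[1],
         support_hi = x$support[2])
}

# ---- the four comparisons ----------------------------------------------

# Build the four samples-by-variables tables from the matched pairs.
build_study_samples <- function(encounters, measurements, pairs,
                                vars = organ_vars, select = "closest") {
  dur <- encounters$los_hours[match(pairs$case_id, encounters$encounter_id)]
  adm_case <- window_table(measurements, pairs$case_id, vars, "admission",
                           select = select)
  adm_ctrl <- window_table(measurements, pairs$control_id, vars, "admission",
                           select = select)
  evt_case <- window_table(measurements, pairs$case_id, vars, "event",
                           durations = tibble(encounter_id = pairs$case_id,
                                              duration = dur),
                           select = select)
  evt_ctrl <- window_table(measurements, pairs$control_id, vars, "event",
                           durations = tibble(encounter_id = pairs$control_id,
                                              duration = dur),
                           select = select)
  tabs <- list(case_admission = adm_case, control_admission = adm_ctrl,
               case_event = evt_case, control_event = evt_ctrl)
  for (nm in names(tabs)) {
    if (anyNA(tabs[[nm]][vars])) {
      abort(paste0("Incomplete ", gsub("_", " ", nm), " values for matched ",
                   "pairs; matching eligibility should have excluded these."))
    }
  }
  tabs
}

#' Run the four study comparisons on matched pairs
#'
#' Builds the four samples-by-variables tables (non-survivors and survivors
#' at admission and at the event stage) from the matched pairs and runs the
#' shared-permutation network comparison for each of:
#' C1 non-survivors vs survivors at admission (unpaired),
#' C2 non-survivors vs survivors at event (unpaired),
#' C3 survivors admission vs event (paired),
#' C4 non-survivors admission vs event (paired).
#'
#' @param encounters,measurements Cohort tables.
#' @param matching A `dnet_matching` from [match_cohort()], or a pairs
#'   tibble with `case_id` and `control_id` columns.
#' @param vars Network parameter names.
#' @param drop_dual_role Drop pairs whose case also serves as a control in
#'   another pair (sensitivity re-analysis of the admission comparison).
#' @param select Window aggregation rule.
#' @inheritParams compare_networks
#' @return A `dnet_study` object: comparisons `C1`-`C4` plus the samples
#'   used; `tidy()` binds the four result tables.
#' @export
run_study <- function(encounters, measurements, matching,
                      vars = organ_vars, characteristics = "all",
                      method = c("spearman", "dcor", "ebicglasso"),
                      alpha = 0.05, adjust = c("bh", "bonferroni", "none"),
                      gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                      dcor_n_perm = 200, M = 10000, seed = NULL,
                      drop_dual_role = FALSE, select = "closest",
                      sig_level = 0.05) {
  method <- match.arg(method)
  pairs <- if (inherits(matching, "dnet_matching")) matching$pairs else
    as_tibble(matching)
  if (!all(c("case_id", "control_id") %in% names(pairs))) {
    abort("`matching` must provide `case_id` and `control_id`.")
  }
  if (drop_dual_role) {
    pairs <- pairs[!pairs$case_id %in% pairs$control_id, , drop = FALSE]
  }
  if (nrow(pairs) < 3) abort("At least 3 matched pairs are required.")
  smp <- build_study_samples(encounters, measurements, pairs, vars, select)
  two_group <- function(a, a_lab, b, b_lab, keys) {
    dplyr::bind_rows(
      dplyr::bind_cols(tibble(group = a_lab, pair_key = keys), a[vars]),
      dplyr::bind_cols(tibble(group = b_lab, pair_key = keys), b[vars])
    )
  }
  key <- pairs$case_id # one key per matched pair
  datasets <- list(
    C1 = list(data = two_group(smp$case_admission, "non-survivor",
                               smp$control_admission, "survivor", key),
              paired = FALSE),
    C2 = list(data = two_group(smp$case_event, "non-survivor",
                               smp$control_event, "survivor", key),
              paired = FALSE),
    C3 = list(data = two_group(smp$control_admission, "admission",
                               smp$control_event, "event", key),
              paired = TRUE),
    C4 = list(data = two_group(smp$case_admission, "admission",
                               smp$case_event, "event", key),
              paired = TRUE)
  )
  comparisons <- purrr::imap(datasets, function(d, id) {
    cmp_seed <- if (is.null(seed)) NULL else
      as.integer(seed) + match(id, names(datasets))
    compare_networks(d$data, group = "group", vars = vars,
                     characteristics = characteristics,
                     pair_key = "pair_key", paired = d$paired,
                     method = method, alpha = alpha, adjust = adjust,
                     gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio,
                     dcor_n_perm = dcor_n_perm, M = M, seed = cmp_seed,
                     comparison_id = id, sig_level = sig_level)
  })
  structure(
    list(comparisons = comparisons, samples = smp, pairs = pairs,
         params = list(vars = vars, method = method, alpha = alpha,
                       adjust = match.arg(tolower(adjust[1]),
                                          c("bh", "bonferroni", "none")),
                       M = M, seed = seed, select = select,
                       drop_dual_role = drop_dual_role)),
    class = "dnet_study"
  )
}

#' @export
print.dnet_study <- function(x, ...) {
  cat("<dnet_study> ", nrow(x$pairs), " matched pairs, M = ",
      x$params$M, " permutations (", x$params$method, "/",
      x$params$adjust, ")\n", sep = "")
  for (id in names(x$comparisons)) {
    g <- glance(x$comparisons[[id]])
    cat("  ", id, ": ", g$n_significant, "/", g$n_characteristics,
        " characteristics significant (min p = ",
        signif(g$min_p, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy the four study comparisons into one table
#' @param x A `dnet_study`.
#' @param ... Unused.
#' @return Tibble binding the four comparison tables; `comparison_id` keys
#'   C1-C4.
#' @export
tidy.dnet_study <- function(x, ...) {
  dplyr::bind_rows(lapply(x$comparisons, tidy))
}

#' One-row-per-comparison summary of a study
#' @param x A `dnet_study`.
#' @param ... Unused.
#' @return Tibble with one row per comparison C1-C4.
#' @export
glance.dnet_study <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x$comparisons, glance))
  out$comparison_id <- names(x$comparisons)
  dplyr::relocate(out, "comparison_id")
}

#' Plot study p-values across the four comparisons
#' @param object A `dnet_study`.
#' @param sig_level Threshold line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object, faceted by comparison.
#' @export
autoplot.dnet_study <- function(object, sig_level = 0.05, ...) {
  df <- tidy(object)
  df$label <- ifelse(is.na(df$node_i), df$characteristic,
                     ifelse(is.na(df$node_j),
                            paste0("degree:", df$node_i),
                            paste0(df$node_i, "-", df$node_j)))
  ggplot2::ggplot(df, ggplot2::aes(.data$p_value, .data$label)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::geom_vline(xintercept = sig_level, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40")) +
    ggplot2::facet_wrap(~comparison_id, nrow = 1) +
    ggplot2::labs(x = "permutation p-value", y = NULL) +
    ggplot2::theme_minimal()
}
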