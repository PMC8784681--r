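# Seeded generators for synthetic data with prescribed Spearman structure.
# Latent Gaussian copula: to hit a Spearman target rho_S, the latent normal
# correlation is set to 2*sin(pi*rho_S/6) (the classical arcsine identity),
# so estimator tests compare like with like.  Monotone marginal transforms
# leave the Spearman structure untouched.

#' Default organ-system variable labels
#' @format Character vector of the nine network parameter symbols:
#'   bilirubin, sodium, creatinine, C-reactive protein, blood glucose,
#'   Horovitz quotient, hemoglobin, mean arterial pressure, platelet count.
#' @export
organ_vars <- c("Bil", "Na", "Cre", "CRP", "Glu", "PF", "Hb", "MAP", "Plt")

# Convert a Spearman correlation target to the latent normal correlation.
spearman_to_latent <- function(R) {
  L <- 2 * sin(pi * R / 6)
  diag(L) <- 1
  L
}

check_spearman_target <- function(R, vars = NULL) {
  R <- as.matrix(R)
  n <- ncol(R)
  if (nrow(R) != n || max(abs(R - t(R))) > 1e-10 || any(diag(R) != 1)) {
    abort("`R` must be a symmetric correlation matrix with unit diagonal.")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("`R` must be positive semi-definite.")
  }
  vars <- vars %||% colnames(R) %||% paste0("V", seq_len(n))
  dimnames(R) <- list(vars, vars)
  R
}

# Symmetric matrix square root.
mat_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Sample a table with a prescribed Spearman correlation structure
#'
#' Draws latent multivariate normal samples whose correlation is chosen so
#' the population Spearman correlation of the output equals `R`, then
#' applies optional monotone marginal transforms (which preserve Spearman
#' correlations).
#'
#' @param R Target Spearman correlation matrix (unit diagonal, PSD).
#' @param n Number of samples.
#' @param marginals Optional named list of monotone functions applied
#'   per column, e.g. `list(Bil = marginal_lognormal())`.
#' @param vars Variable labels (defaults to the dimnames of `R`).
#' @param seed Optional integer seed.
#' @return A tibble with a `sample_id` column and one column per variable.
#' @export
simulate_correlated <- function(R, n, marginals = NULL, vars = NULL,
                                seed = NULL) {
  R <- check_spearman_target(R, vars)
  with_seed_opt(seed, {
    X <- latent_draw(R, n)
    X <- apply_marginals(X, marginals)
    dplyr::bind_cols(tibble(sample_id = as.character(seq_len(n))),
                     as_tibble(as.data.frame(X)))
  })
}

latent_draw <- function(R, n) {
  L <- spearman_to_latent(R)
  ev <- min(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    L <- psd_repair(L, context = "latent correlation matrix")
  }
  Z <- matrix(rnorm(n * ncol(L)), n) %*% mat_sqrt(L)
  colnames(Z) <- colnames(R)
  Z
}

apply_marginals <- function(X, marginals) {
  if (is.null(marginals)) return(X)
  for (v in names(marginals)) {
    if (!v %in% colnames(X)) abort(paste0("Unknown marginal variable: ", v))
    X[, v] <- marginals[[v]](X[, v])
  }
  X
}

#' Monotone marginal transforms for skewed laboratory values
#'
#' Map a standard-normal latent value to a log-normal or shifted-gamma
#' scale.  Both are strictly increasing, so they change marginal shapes
#' without touching Spearman correlations.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @return A function of one numeric vector.
#' @export
marginal_lognormal <- function(meanlog = 0, sdlog = 1) {
  function(z) qlnorm(pnorm(z), meanlog = meanlog, sdlog = sdlog)
}

#' @rdname marginal_lognormal
#' @param shape,scale,shift Gamma parameters and offset.
#' @export
marginal_gamma <- function(shape = 2, scale = 1, shift = 0) {
  function(z) shift + qgamma(pnorm(z), shape = shape, scale = scale)
}

#' Sample paired admission/event measurements for one group
#'
#' Draws `n` subjects measured at two stages.  Each stage has its own
#' Spearman correlation structure, and the same variable is coupled across
#' stages within a subject with Spearman correlation about
#' `cross_stage_rho`.
#'
#' @param R_admission,R_event Stage-specific Spearman targets.
#' @param n Number of subjects (pairs).
#' @param cross_stage_rho Within-subject cross-stage Spearman coupling, in
#'   `[0, 1)`.
#' @param marginals,vars,seed See [simulate_correlated()].
#' @return A tibble with columns `pair_key`, `stage`
#'   (`"admission"`/`"event"`) and the variables; each pair key occurs once
#'   per stage.
#' @export
simulate_paired_stages <- function(R_admission, R_event, n,
                                   cross_stage_rho = 0.3, marginals = NULL,
                                   vars = NULL, seed = NULL) {
  Ra <- check_spearman_target(R_admission, vars)
  Re <- check_spearman_target(R_event, vars %||% colnames(R_admission))
  if (!identical(colnames(Ra), colnames(Re))) {
    abort("Stage targets must share the same variables.")
  }
  if (cross_stage_rho < 0 || cross_stage_rho >= 1) {
    abort("`cross_stage_rho` must lie in [0, 1).")
  }
  with_seed_opt(seed, {
    draws <- paired_latent_draw(Ra, Re, n, cross_stage_rho)
    Xa <- apply_marginals(draws$adm, marginals)
    Xe <- apply_marginals(draws$evt, marginals)
    key <- as.character(seq_len(n))
    dplyr::bind_rows(
      dplyr::bind_cols(tibble(pair_key = key, stage = "admission"),
                       as_tibble(as.data.frame(Xa))),
      dplyr::bind_cols(tibble(pair_key = key, stage = "event"),
                       as_tibble(as.data.frame(Xe)))
    )
  })
}

# Joint latent draw: [A, rho*A^1/2 B^1/2; rho*B^1/2 A^1/2, B] is PSD by
# construction, realized through its Cholesky-like factor.
paired_latent_draw <- function(Ra, Re, n, cross_stage_rho) {
  La <- spearman_to_latent(Ra)
  Le <- spearman_to_latent(Re)
  rho <- 2 * sin(pi * cross_stage_rho / 6)
  sa <- mat_sqrt(La)
  se <- mat_sqrt(Le)
  U1 <- matrix(rnorm(n * ncol(La)), n)
  U2 <- matrix(rnorm(n * ncol(La)), n)
  adm <- U1 %*% sa
  evt <- (rho * U1 + sqrt(1 - rho^2) * U2) %*% se
  colnames(adm) <- colnames(Ra)
  colnames(evt) <- colnames(Ra)
  list(adm = adm, evt = evt)
}

# ---- scenarios ----------------------------------------------------------

# Weak default Spearman structure on the nine organ-system parameters:
# a persistent negative bilirubin-platelet edge plus a few stage/group
# specific edges, all |rho| <= 0.5.
default_structures <- function(vars = organ_vars) {
  edge_matrix <- function(edges) {
    R <- diag(1, length(vars))
    dimnames(R) <- list(vars, vars)
    for (e in edges) {
      R[e[[1]], e[[2]]] <- R[e[[2]], e[[1]]] <- e[[3]]
    }
    R
  }
  adm <- edge_matrix(list(list("Bil", "Plt", -0.35),
                          list("Hb", "Plt", 0.20),
                          list("Na", "Cre", 0.15)))
  list(
    case_admission = adm,
    control_admission = adm,
    case_event = edge_matrix(list(list("Bil", "Plt", -0.50),
                                  list("Bil", "Na", -0.30),
                                  list("Na", "Plt", 0.30))),
    control_event = edge_matrix(list(list("Bil", "Plt", -0.45),
                                     list("Bil", "CRP", 0.45),
                                     list("CRP", "Plt", -0.35),
                                     list("Na", "Cre", 0.30),
                                     list("MAP", "CRP", -0.25)))
  )
}

#' Synthetic cohort specification
#'
#' Bundles the parameters driving the synthetic generators: the variable
#' set, the number of pairs per group, the group- and stage-specific
#' Spearman targets, and the within-subject cross-stage coupling.
#'
#' @param vars Variable labels (default the nine organ-system parameters).
#' @param n_pairs Subjects per group (default 123).
#' @param structures Named list of Spearman targets `case_admission`,
#'   `control_admission`, `case_event`, `control_event`.
#' @param cross_stage_rho Within-subject cross-stage coupling.
#' @param marginals Optional monotone marginal transforms.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(vars = organ_vars, n_pairs = 123,
                        structures = default_structures(vars),
                        cross_stage_rho = 0.3, marginals = NULL) {
  stopifnot(all(c("case_admission", "control_admission", "case_event",
                  "control_event") %in% names(structures)))
  structures <- lapply(structures, check_spearman_target, vars = vars)
  structure(list(vars = vars, n_pairs = n_pairs, structures = structures,
                 cross_stage_rho = cross_stage_rho, marginals = marginals),
            class = "cohort_spec")
}

#' Two-group scenarios for calibration and power studies
#'
#' `simulate_null()` draws both groups from a single Spearman structure, so
#' any rejection is a false positive.  `simulate_planted()` modifies the
#' listed variable pairs by `delta` in group B only (repairing the target
#' to the nearest PSD matrix if needed), planting a known edge difference.
#'
#' @param R Shared Spearman target; defaults to the admission structure of
#'   [cohort_spec()] on the nine organ-system parameters.
#' @param n Samples per group (default 123).
#' @param vars,marginals,seed See [simulate_correlated()].
#' @return A tibble with a two-level `group` column (`"A"`, `"B"`) plus the
#'   variables.
#' @export
simulate_null <- function(R = NULL, n = 123, vars = NULL, marginals = NULL,
                          seed = NULL) {
  R <- R %||% default_structures()$case_admission
  R <- check_spearman_target(R, vars)
  with_seed_opt(seed, {
    a <- simulate_correlated(R, n, marginals)
    b <- simulate_correlated(R, n, marginals)
    bind_two_groups(a, b)
  })
}

bind_two_groups <- function(a, b) {
  a$sample_id <- paste0("A", a$sample_id)
  b$sample_id <- paste0("B", b$sample_id)
  dplyr::bind_rows(dplyr::mutate(a, group = "A", .before = 1),
                   dplyr::mutate(b, group = "B", .before = 1))
}

#' @rdname simulate_null
#' @param edges Data frame with columns `var_i`, `var_j` listing the pairs
#'   to modify in group B.
#' @param delta Amount added to each listed pairwise Spearman correlation
#'   in group B (`delta = 0` reduces to the null scenario).
#' @export
simulate_planted <- function(edges, delta, R = NULL, n = 123, vars = NULL,
                             marginals = NULL, seed = NULL) {
  R <- R %||% default_structures()$case_admission
  R <- check_spearman_target(R, vars)
  RB <- R
  for (k in seq_len(nrow(edges))) {
    i <- as.character(edges$var_i[k])
    j <- as.character(edges$var_j[k])
    if (!all(c(i, j) %in% colnames(R))) {
      abort(paste0("Unknown edge variable(s): ", i, ", ", j))
    }
    RB[i, j] <- RB[j, i] <- max(min(RB[i, j] + delta, 0.99), -0.99)
  }
  ev <- min(eigen(RB, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) RB <- psd_repair(RB, context = "planted Spearman target")
  with_seed_opt(seed, {
    a <- simulate_correlated(R, n, marginals)
    b <- simulate_correlated(RB, n, marginals)
    bind_two_groups(a, b)
  })
}

# ---- synthetic ICU cohort ----------------------------------------------

#' Simulate an encounter-level ICU-like cohort
#'
#' Generates a longitudinal cohort in the shape the study pipeline
#' consumes: one covariate row per encounter (admission time, length of
#' stay of at least 72 h, death flag and time, demographic and score-like
#' covariates) and a long table of time-stamped measurements of the network
#' parameters on a regular grid with jitter, guaranteeing at least one
#' value per variable in the 0-24 h admission window and in any 48-24 h
#' pre-index window.  Measurement values carry the admission-stage Spearman
#' structure before 24 h and the event-stage structure afterwards, per the
#' group- and stage-specific targets of `spec`.
#'
#' @param n_encounters Number of encounters (default 1000).
#' @param mortality Probability of ICU death (default 0.15).
#' @param spec A [cohort_spec()].
#' @param grid_hours Measurement spacing in hours (default 12).
#' @param jitter_hours Uniform timestamp jitter half-width (default 2).
#' @param noise_sd Measurement noise sd on the standardized scale
#'   (default 0.1).
#' @param study_hours Length of the admission accrual window in hours.
#' @param seed Optional integer seed.
#' @return A list with tibbles `encounters` (one row per encounter) and
#'   `measurements` (`encounter_id`, `time` in hours since admission,
#'   `variable`, `value`).
#' @export
simulate_icu_cohort <- function(n_encounters = 1000, mortality = 0.15,
                                spec = cohort_spec(), grid_hours = 12,
                                jitter_hours = 2, noise_sd = 0.1,
                                study_hours = 20000, seed = NULL) {
  vars <- spec$vars
  with_seed_opt(seed, {
    died <- stats::runif(n_encounters) < mortality
    los <- 72 + rgamma(n_encounters, shape = 1.2,
                       scale = ifelse(died, 180, 360))
    admission_time <- stats::runif(n_encounters, 0, study_hours)
    enc <- tibble(
      encounter_id = sprintf("E%04d", seq_len(n_encounters)),
      admission_time = admission_time,
      los_hours = los,
      died = died,
      death_time = ifelse(died, admission_time + los, NA_real_),
      age = pmin(pmax(round(rnorm(n_encounters, 68, 13.5)), 18), 99),
      sex = ifelse(stats::runif(n_encounters) < 0.64, "m", "f"),
      saps2m = pmax(0, round(rnorm(n_encounters, 20, 9.5) + 1.5 * died)),
      tiss10 = pmax(0, round(rnorm(n_encounters, 21, 7) + 0.8 * died)),
      charlson = pmin(round(rgamma(n_encounters, shape = 1.56, scale = 2.24)), 15),
      catecholamines = as.integer(stats::runif(n_encounters) < 0.76)
    )
    # Stage-level latent values per encounter, group- and stage-specific.
    adm_vals <- matrix(NA_real_, n_encounters, length(vars))
    evt_vals <- matrix(NA_real_, n_encounters, length(vars))
    for (grp in c(TRUE, FALSE)) {
      idx <- which(died == grp)
      if (!length(idx)) next
      key <- if (grp) "case" else "control"
      dr <- paired_latent_draw(spec$structures[[paste0(key, "_admission")]],
                               spec$structures[[paste0(key, "_event")]],
                               length(idx), spec$cross_stage_rho)
      adm_vals[idx, ] <- dr$adm
      evt_vals[idx, ] <- dr$evt
    }
    # Measurement grid per encounter (hours since admission).
    times <- lapply(seq_len(n_encounters), function(i) {
      g <- seq(0, los[i], by = grid_hours)
      pmin(pmax(g + stats::runif(length(g), -jitter_hours, jitter_hours), 0),
           los[i])
    })
    n_per <- lengths(times)
    eid <- rep(rep(enc$encounter_id, times = n_per), length(vars))
    tt <- rep(unlist(times), times = length(vars))
    vv <- rep(vars, each = sum(n_per))
    row_i <- rep(rep(seq_len(n_encounters), times = n_per), length(vars))
    col_i <- rep(seq_along(vars), each = sum(n_per))
    stage_evt <- tt >= 24
    base <- ifelse(stage_evt, evt_vals[cbind(row_i, col_i)],
                   adm_vals[cbind(row_i, col_i)])
    value <- base + noise_sd * rnorm(length(base))
    if (!is.null(spec$marginals)) {
      for (v in names(spec$marginals)) {
        sel <- vv == v
        value[sel] <- spec$marginals[[v]](value[sel])
      }
    }
    meas <- tibble(encounter_id = eid, time = tt, variable = vv,
                   value = value)
    meas <- dplyr::arrange(meas, .data$encounter_id, .data$variable,
                           .data$time)
    list(encounters = enc, measurements = meas)
  })
}
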