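make_meas <- function(encounter_id, times, variable = "Bil",
                      values = seq_along(times)) {
  tibble::tibble(encounter_id = encounter_id, time = times,
                 variable = variable, value = values)
}

test_that("window extraction picks the value closest to the anchor", {
  m <- make_meas("E1", c(2, 20), values = c(10, 99))
  expect_equal(extract_window_value(m, "Bil", c(0, 24)), 10)
  # event window relative to a 100 h duration: [52, 76) anchored at 100
  m2 <- make_meas("E1", c(100 - 30, 100 - 10), values = c(5, 7))
  expect_equal(extract_window_value(m2, "Bil", c(52, 76), anchor = 100), 5)
  # -10 h relative to death lies outside the 48-24 h event window
  m3 <- make_meas("E1", 100 - 10, values = 7)
  expect_true(is.na(extract_window_value(m3, "Bil", c(52, 76), anchor = 100)))
  # half-open: a value exactly at the window end is excluded
  m4 <- make_meas("E1", 24, values = 3)
  expect_true(is.na(extract_window_value(m4, "Bil", c(0, 24))))
  expect_equal(extract_window_value(make_meas("E1", c(1, 9), values = c(4, 8)),
                                    "Bil", c(0, 24), select = "mean"), 6)
})

test_that("risk sets apply the length-of-stay and completeness rules", {
  # case 240 h; candidates at 120, 240, 288 h
  enc <- tibble::tibble(
    encounter_id = c("C1", "S1", "S2", "S3"),
    admission_time = 0, los_hours = c(240, 120, 240, 288),
    died = c(TRUE, FALSE, FALSE, TRUE),
    death_time = c(240, NA, NA, 288)
  )
  meas <- dplyr::bind_rows(lapply(enc$encounter_id, function(id) {
    L <- enc$los_hours[enc$encounter_id == id]
    dplyr::bind_rows(lapply(organ_vars, function(v) {
      make_meas(id, c(1, seq(30, L, by = 20)), variable = v,
                values = rnorm(1 + length(seq(30, L, by = 20))))
    }))
  }))
  rs <- build_risk_set("C1", enc, meas)
  # S1 too short; S2 equal stay and S3 longer qualify (S3 despite dying)
  expect_setequal(rs$control_id, c("S2", "S3"))
  expect_equal(unique(rs$index_duration), 240)
  # remove S3's event-window coverage at the case duration: excluded
  meas2 <- meas[!(meas$encounter_id == "S3" & meas$time >= 240 - 48 &
                    meas$time < 240 - 24), ]
  expect_setequal(build_risk_set("C1", enc, meas2)$control_id, "S2")
})

test_that("propensity scores react to predictive covariates and ignore order", {
  set.seed(19)
  n <- 400
  d <- tibble::tibble(
    encounter_id = as.character(1:n),
    risk = rnorm(n),
    noise = rnorm(n),
    died = runif(n) < stats::plogis(-1 + 2 * risk)
  )
  fit <- fit_propensity(d, covariates = c("risk", "noise"))
  expect_true(all(fit$.ps > 0 & fit$.ps < 1))
  expect_gt(mean(fit$.ps[fit$died]), mean(fit$.ps[!fit$died]))
  shuf <- d[sample(n), ]
  fit2 <- fit_propensity(shuf, covariates = c("risk", "noise"))
  expect_equal(fit2$.ps[match(d$encounter_id, fit2$encounter_id)], fit$.ps)
  # covariates unrelated to outcome: scores near the case fraction
  d0 <- d
  d0$died <- runif(n) < 0.3
  fit0 <- fit_propensity(d0, covariates = "noise")
  expect_lt(abs(mean(fit0$.ps) - mean(d0$died)), 0.02)
  expect_lt(sd(fit0$.ps), 0.1)
  # separation is an error
  dsep <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                         died = c(rep(FALSE, 20), rep(TRUE, 20)))
  expect_error(fit_propensity(dsep, covariates = "x"), "separation|usable")
})

test_that("Mahalanobis matching prefers identical controls and honours support", {
  adm <- rbind(case1 = c(1, 2), ctrlA = c(1, 2), ctrlB = c(4, 0),
               other1 = c(0, 0), other2 = c(2, 2), other3 = c(5, 1))
  colnames(adm) <- c("x", "y")
  ps <- c(case1 = 0.4, ctrlA = 0.4, ctrlB = 0.36, other1 = 0.2,
          other2 = 0.6, other3 = 0.35)
  case_flag <- c(case1 = TRUE, ctrlA = FALSE, ctrlB = FALSE, other1 = FALSE,
                 other2 = FALSE, other3 = TRUE)
  pairs <- match_controls(list(case1 = c("ctrlA", "ctrlB")), ps, adm,
                          case_flag)
  expect_equal(pairs$control_id, "ctrlA")
  expect_equal(pairs$distance, 0, tolerance = 1e-10)
  expect_equal(pairs$delta, 0, tolerance = 1e-12)
  # common support: case score outside the controls' range drops the pair
  ps2 <- ps
  ps2["case1"] <- 0.9 # above every control score
  pairs2 <- match_controls(list(case1 = c("ctrlA", "ctrlB")), ps2, adm,
                           case_flag)
  expect_equal(nrow(pairs2), 0)
})

test_that("identity covariance reduces matching to nearest Euclidean neighbour", {
  set.seed(23)
  n <- 40
  adm <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("e%02d", 1:n),
                                                 c("a", "b", "c")))
  ps <- setNames(rep(0.5, n), rownames(adm)) # log ps constant: no influence
  case_flag <- setNames(seq_len(n) <= 5, rownames(adm))
  risk <- list(e01 = rownames(adm)[6:n])
  d_euc <- sqrt(colSums((t(adm[6:n, ]) - adm["e01", ])^2))
  # with a constant log-ps column the covariance is singular: ridge kicks in
  expect_warning(pairs <- match_controls(risk, ps, adm, case_flag),
                 "Near-singular")
  # variables are iid standard normal, so after the ridge repair the
  # Mahalanobis winner coincides with the nearest Euclidean neighbour
  expect_equal(pairs$control_id, names(which.min(d_euc)))
})

test_that("duplicate controls keep only the smallest-delta pair", {
  pairs <- tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4"),
    control_id = c("s1", "s1", "s2", "s3"),
    delta = c(0.03, 0.01, 0.05, 0.02)
  )
  kept <- prune_duplicate_controls(pairs)
  expect_equal(kept$case_id, c("c2", "c3", "c4"))
  # ties break deterministically by case id
  tie <- tibble::tibble(case_id = c("c9", "c2"), control_id = "s1",
                        delta = 0.5)
  expect_equal(prune_duplicate_controls(tie)$case_id, "c2")
  none <- tibble::tibble(case_id = c("a", "b"), control_id = c("x", "y"),
                         delta = c(0.1, 0.2))
  expect_equal(prune_duplicate_controls(none), none)
})

test_that("the matching pipeline is deterministic under cohort row order", {
  co <- simulate_icu_cohort(n_encounters = 150, seed = 31)
  m1 <- match_cohort(co$encounters, co$measurements)
  set.seed(99)
  perm <- sample(nrow(co$encounters))
  m2 <- match_cohort(co$encounters[perm, ],
                     co$measurements[sample(nrow(co$measurements)), ])
  expect_equal(tidy(m1), tidy(m2))
  expect_equal(m1$support, m2$support)
})

test_that("matched pairs satisfy the structural invariants", {
  co <- simulate_icu_cohort(n_encounters = 300, seed = 37)
  m <- match_cohort(co$encounters, co$measurements)
  pairs <- tidy(m)
  expect_gt(nrow(pairs), 10)
  los <- setNames(co$encounters$los_hours, co$encounters$encounter_id)
  expect_true(all(los[pairs$control_id] >= los[pairs$case_id]))
  expect_false(any(duplicated(pairs$control_id)))
  expect_false(any(duplicated(pairs$case_id)))
  expect_true(all(pairs$ps_case >= m$support[1] &
                    pairs$ps_case <= m$support[2]))
  expect_true(all(pairs$ps_control >= m$support[1] &
                    pairs$ps_control <= m$support[2]))
  expect_true(all(pairs$delta == abs(pairs$ps_case - pairs$ps_control)))
  # a non-survivor may serve as a control before becoming a case
  expect_true(all(pairs$control_id != pairs$case_id))
})

test_that("run_study assembles the four comparisons on matched samples", {
  co <- simulate_icu_cohort(n_encounters = 200, seed = 41)
  m <- match_cohort(co$encounters, co$measurements)
  st <- run_study(co$encounters, co$measurements, m, M = 20, seed = 5)
  expect_named(st$comparisons, c("C1", "C2", "C3", "C4"))
  expect_false(st$comparisons$C1$paired[1])
  expect_false(st$comparisons$C2$paired[1])
  expect_true(st$comparisons$C3$paired[1])
  expect_true(st$comparisons$C4$paired[1])
  n_pairs <- nrow(tidy(m))
  for (s in st$samples) expect_equal(nrow(s), n_pairs)
  tt <- tidy(st)
  expect_equal(nrow(tt), 4 * 53)
  expect_setequal(unique(tt$comparison_id), c("C1", "C2", "C3", "C4"))
  g <- glance(st)
  expect_equal(g$comparison_id, c("C1", "C2", "C3", "C4"))
  expect_s3_class(autoplot(st), "ggplot")
  # dual-role sensitivity flag drops cases that also act as controls
  st2 <- run_study(co$encounters, co$measurements, m, M = 5, seed = 5,
                   drop_dual_role = TRUE)
  expect_false(any(st2$pairs$case_id %in% st2$pairs$control_id))
})
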