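tier_records <- function(tiers, combos_per_tier, n_each, hazards, seed,
                         censor_fraction = 0.2) {
  fx <- make_recovery_fixture(tiers, combos_per_tier, n_each, hazards,
                              censor_fraction = censor_fraction, seed = seed)
  list(sim = simulate_cohort(fx$config), truth = fx$truth,
       scheme = fx$config$scheme)
}

test_that("knee selection follows the forward-difference plateau rule", {
  expect_equal(select_knee(c(0.50, 0.60, 0.66, 0.668, 0.669), tol = 0.01), 3)
  expect_equal(select_knee(c(0.6, 0.6, 0.6, 0.6)), 1)              # flat
  expect_warning(k <- select_knee(seq(0.5, 0.7, by = 0.05), tol = 0.01),
                 "no C-index plateau")
  expect_equal(k, 5)
  expect_error(select_knee(0.5), "length")
})

test_that("groups are ordered by decreasing 5-year survival", {
  set.seed(171)
  # three single-combination clusters with very different hazards
  rates <- c(0.002, 0.02, 0.006)       # 5-yr survival ~ 0.89, 0.30, 0.70
  labs <- c("QA", "QB", "QC")
  rec <- do.call(rbind, lapply(1:3, function(i)
    cbind(rexp_obs(400, rates[i]), G = labs[i])))
  co <- build_combinations(rec, factor_scheme(G = labs))
  part <- list(k = 3, assignment = stats::setNames(1:3, labs),
               medoids = labs)
  groups <- order_groups(part, co)
  expect_equal(sapply(groups, `[[`, "id"), 1:3)
  expect_equal(unlist(sapply(groups, `[[`, "members")), c("QA", "QC", "QB"))
  s5 <- sapply(groups, `[[`, "surv5")
  expect_true(all(diff(s5) < 0))                    # non-increasing severity
  expect_equal(sum(sapply(groups, `[[`, "n")), co$n)

  single <- order_groups(list(k = 1, assignment = stats::setNames(rep(1, 3),
                                                                  labs),
                              medoids = labs[1]), co)
  expect_equal(single[[1]]$id, 1)
})

test_that("short follow-up falls back to the common-horizon ordering", {
  labs <- c("QA", "QB")
  rec <- rbind(cbind(data.frame(time = c(10, 20, 30), event = c(1, 0, 1)),
                     G = "QA"),
               cbind(data.frame(time = c(5, 15, 25), event = c(1, 1, 0)),
                     G = "QB"))
  co <- build_combinations(rec, factor_scheme(G = labs))
  part <- list(k = 2, assignment = stats::setNames(1:2, labs), medoids = labs)
  expect_warning(groups <- order_groups(part, co), "common follow-up")
  expect_equal(length(groups), 2)
})

test_that("the C-index curve starts at 0.5 and is permutation invariant", {
  td <- tier_records(2, 2, 120, c(0.005, 0.03), seed = 5)
  co <- build_combinations(td$sim$records, td$scheme)
  d0 <- initial_dissimilarity_matrix(co)
  tree <- minimax_linkage(ensemble_dissimilarity(d0))
  curve <- cindex_curve(tree, co)
  expect_equal(curve$cindex[1], 0.5)
  expect_true(all(curve$cindex >= 0 & curve$cindex <= 1))

  # shuffling the record order leaves every C(k) unchanged
  shuffled <- td$sim$records[sample(nrow(td$sim$records)), ]
  co2 <- build_combinations(shuffled, td$scheme)
  curve2 <- cindex_curve(minimax_linkage(
    ensemble_dissimilarity(initial_dissimilarity_matrix(co2))), co2)
  expect_equal(curve2$cindex, curve$cindex)
})

test_that("identical-hazard combinations yield a single group and C near 0.5", {
  td <- tier_records(1, 4, 150, 0.01, seed = 6)
  co <- build_combinations(td$sim$records, td$scheme)
  # ordering groups by observed survival makes every in-sample C(k) gain
  # slightly optimistic (~0.01 here), so the plateau tolerance must sit
  # above that noise floor to read "no structure" off a finite cohort
  sys <- build_prognostic_system(co, B = 0, knee_tol = 0.02)
  expect_equal(sys$n_star, 1)
  curve_flat <- sys$curve$cindex
  expect_true(all(abs(curve_flat - 0.5) < 0.05))
})

test_that("the full system recovers a 3-tier structure and is consistent", {
  td <- tier_records(3, 4, 300, c(0.002, 0.01, 0.05), seed = 3)
  co <- build_combinations(td$sim$records, td$scheme)
  sys <- build_prognostic_system(co, B = 100, seed = 3)

  expect_equal(sys$n_star, 3)
  expect_equal(adjusted_rand_index(sys$assignments,
                                   td$truth[names(sys$assignments)]), 1)

  # round-trip: stored C equals C recomputed from the system's assignments
  pooled <- pool_observations(co)
  risk <- unname(sys$assignments[pooled$combination])
  again <- harrell_cindex(risk, pooled, B = 0)
  expect_equal(sys$cindex$cindex, again$cindex)

  # conservation of patients and deaths
  expect_equal(sum(sapply(sys$groups, `[[`, "n")), co$n)
  expect_equal(sum(sapply(sys$groups, `[[`, "deaths")),
               sum(td$sim$records$event))

  # 5-year survival ordered with group id
  s5 <- sapply(sys$groups, `[[`, "surv5")
  expect_true(all(diff(s5) <= 0))

  # adjacent groups clearly separated on this fixture
  expect_true(all(sys$adjacent$p < 0.01))

  # deterministic rerun
  sys2 <- build_prognostic_system(co, B = 100, seed = 3)
  expect_identical(group_table(sys), group_table(sys2))
  expect_identical(sys$curve, sys2$curve)
})

test_that("forced group counts and patient assignment behave", {
  td <- tier_records(3, 4, 120, c(0.002, 0.01, 0.05), seed = 4)
  co <- build_combinations(td$sim$records, td$scheme)
  sys <- build_prognostic_system(co, n_groups = 4, B = 0)
  expect_equal(sys$n_star, 4)
  expect_equal(length(sys$groups), 4)

  lab <- names(sys$assignments)[1]
  expect_equal(assign_patient(sys, c(Q = lab)),
               unname(sys$assignments[lab]))
  expect_error(assign_patient(sys, c(Q = "nope")), "invalid")
  expect_error(build_prognostic_system(co, n_groups = 99, B = 0),
               "out of range")
})

test_that("combinations dropped by the filter are explicitly unassignable", {
  set.seed(181)
  rec <- rbind(cbind(rexp_obs(40, 0.01), G = "QA"),
               cbind(rexp_obs(40, 0.05), G = "QB"),
               cbind(rexp_obs(5, 0.02), G = "QC"))    # below min_n
  sch <- factor_scheme(G = c("QA", "QB", "QC"))
  flt <- filter_small_combinations(build_combinations(rec, sch), 15)
  sys <- suppressWarnings(build_prognostic_system(flt$cohort, B = 0))
  expect_warning(gid <- assign_patient(sys, c(G = "QC")), "unassignable")
  expect_true(is.na(gid))
})

test_that("the AJCC rule reproduces the reference stage table exactly", {
  ref <- ajcc_reference_counts()
  lev <- regmatches(ref$combination,
                    regexec("^(T[1-4])(N[01])(M[01])$", ref$combination))
  got <- assign_ajcc_stage(sapply(lev, `[`, 2), sapply(lev, `[`, 3),
                           sapply(lev, `[`, 4))
  expect_equal(as.character(got), ref$stage)
  # the 16 cells partition 1/2/5/8 across stages I-IV
  expect_equal(as.vector(table(got)), c(1, 2, 5, 8))
  expect_error(assign_ajcc_stage("T5", "N0", "M0"), "invalid T")
  expect_error(assign_ajcc_stage("T1", "N2", "M0"), "invalid N")
})
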