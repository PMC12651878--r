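test_that("KM matches hand product-limit calculations", {
  km <- km_estimate(data.frame(time = c(5, 8, 12), event = c(1, 0, 1)))
  expect_equal(survival_at(km, 5), 2 / 3)     # (1 - 1/3)
  expect_equal(survival_at(km, 12), 0)        # (2/3)(1 - 1/1)

  allc <- km_estimate(data.frame(time = c(3, 7, 9), event = 0))
  expect_equal(survival_at(allc, c(0, 3, 9)), c(1, 1, 1))

  one <- km_estimate(data.frame(time = 1, event = 1))
  expect_equal(survival_at(one, 1), 0)

  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))),
               "at least one")
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(11)
  for (i in 1:10) {
    tt <- round(rexp(60, 0.05), 1)
    km <- km_estimate(data.frame(time = tt, event = 1L))
    qs <- sort(unique(tt))
    expect_equal(survival_at(km, qs), sapply(qs, function(q) mean(tt > q)))
  }
})

test_that("survival_at is a right-continuous step that refuses extrapolation", {
  km <- km_estimate(data.frame(time = c(50, 70), event = 1))
  expect_equal(survival_at(km, 60), 0.5)      # value carried from t = 50
  expect_equal(survival_at(km, 0), 1)
  expect_true(is.na(survival_at(km, 71)))
  expect_equal(survival_at(km, 70), 0)        # boundary still defined
})

test_that("restricted mean survival integrates the KM step function", {
  # S = 1 on [0,5), 2/3 on [5,12), 0 after: rmst(12) = 5 + 7*2/3
  km <- km_estimate(data.frame(time = c(5, 8, 12), event = c(1, 0, 1)))
  expect_equal(km_rmst(km, 12), 5 + 7 * 2 / 3)
  expect_equal(km_rmst(km, 5), 5)
})

test_that("Gehan U, permutation variance, and z match hand enumeration", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  g <- gehan_wilcoxon(a, b)
  expect_equal(g$statistic, -4)               # all 4 cross-pairs ordered
  expect_equal(g$variance, 20 / 3)            # pooled scores -3,-1,1,3
  expect_equal(g$z, -4 / sqrt(20 / 3))
  expect_false(g$degenerate)

  same <- gehan_wilcoxon(a, a)
  expect_equal(same$statistic, 0)
})

test_that("Gehan permutation variance equals brute-force enumeration", {
  set.seed(21)
  for (i in 1:8) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    ta <- sample(1:6, m, TRUE); da <- rbinom(m, 1, 0.7)
    tb <- sample(1:6, n, TRUE); db <- rbinom(n, 1, 0.7)
    if (sum(da) + sum(db) == 0) next
    g <- gehan_wilcoxon(data.frame(time = ta, event = da),
                        data.frame(time = tb, event = db))
    expect_equal(g$variance, perm_var_gehan(ta, da, tb, db), tolerance = 1e-10)
  }
})

test_that("Gehan U is antisymmetric and |z| invariant under group swap", {
  set.seed(31)
  for (i in 1:20) {
    a <- rexp_obs(sample(3:15, 1), 0.05, 0.02)
    b <- rexp_obs(sample(3:15, 1), 0.1, 0.02)
    g1 <- gehan_wilcoxon(a, b); g2 <- gehan_wilcoxon(b, a)
    expect_equal(g1$statistic, -g2$statistic)
    if (!g1$degenerate) expect_equal(abs(g1$z), abs(g2$z))
  }
})

test_that("exact permutation p agrees with enumeration and flags big samples", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  ex <- gehan_wilcoxon(a, b, exact = TRUE)
  # |U| = 4 is the extreme of the 6 assignments; two assignments reach it
  expect_equal(ex$p, 2 / 6)
  expect_error(gehan_wilcoxon(rexp_obs(8, 1), rexp_obs(8, 1), exact = TRUE),
               "<= 12")
})

test_that("effect-size dissimilarity is |z|/sqrt(N), symmetric, zero on identity", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  expect_equal(effect_size_dissimilarity(a, b), abs(-4 / sqrt(20 / 3)) / 2)
  expect_equal(effect_size_dissimilarity(a, b),
               effect_size_dissimilarity(b, a))
  expect_equal(effect_size_dissimilarity(a, a), 0)
})

test_that("degenerate (all-censored) pairs return the sentinel with a warning", {
  a <- data.frame(time = c(1, 2), event = 0)
  b <- data.frame(time = c(3, 4), event = 0)
  expect_warning(v <- effect_size_dissimilarity(a, b), "degenerate")
  expect_equal(v, 1)
  expect_warning(v2 <- effect_size_dissimilarity(a, b, degenerate_value = 9))
  expect_equal(v2, 9)
  g <- gehan_wilcoxon(a, b)
  expect_true(g$degenerate)
  expect_equal(g$variance, 0)
})

test_that("log-rank matches the hand O-E table and survdiff", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  lr <- logrank(a, b)
  # hand table over event times 1..4: E_a = 1/2 + 1/3, O_a = 2
  expect_equal(lr$statistic, 7 / 6)
  expect_equal(lr$variance, 17 / 36)
  expect_true(lr$statistic > 0)               # earlier deaths in a

  same <- logrank(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # event-free group has negative observed-minus-expected
  free <- data.frame(time = c(5, 6, 7), event = 0)
  dead <- data.frame(time = c(1, 2, 3), event = 1)
  expect_lt(logrank(free, dead)$statistic, 0)

  none <- logrank(free, data.frame(time = 1, event = 0))
  expect_true(none$degenerate)
})
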