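test_that("read_cohort parses mapped columns and audits dropped rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("months,status,tcat,ncat,mcat",
               "12.0,1,T1,N0,M0",
               "24.5,0,T2,N1,M0",
               "6.0,,T1,N0,M1",          # missing vital status -> dropped
               "8.0,1,T3,N0,M0"), f)
  cm <- list(time = "months", event = "status", T = "tcat", N = "ncat",
             M = "mcat")
  out <- read_cohort(f, cm)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$time[1], 12.0)
  expect_equal(out$audit$n_dropped, 1)
  expect_equal(unname(out$audit$reasons["missing event"]), 1)
  expect_equal(out$audit$n_read, out$audit$n_kept + out$audit$n_dropped)

  expect_error(read_cohort(file.path(tempdir(), "absent.csv"), cm),
               "not found")
  expect_error(read_cohort(f, list(time = "months", event = "nope")),
               "absent")
  expect_error(read_cohort(f, list(time = "months")), "event")
})

test_that("unparseable and negative times are audited, not silently kept", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t\te", "12\t1", "oops\t1", "-3\t0"), f)
  out <- read_cohort(f, list(time = "t", event = "e"))
  expect_equal(out$audit$n_kept, 1)
  expect_equal(unname(out$audit$reasons["unparseable time"]), 1)
  expect_equal(unname(out$audit$reasons["negative time"]), 1)
})

test_that("column map can come from a YAML file and age is dichotomized", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,e,age", "10,1,49", "20,0,50", "30,1,0"), f)
  ymap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("time: t", "event: e", "age: age"), ymap)
  out <- read_cohort(f, ymap)
  expect_equal(out$records$A, c("A1", "A2", "A1"))
})

test_that("age dichotomizes at exactly 50 with >= 50 mapping to A2", {
  expect_equal(dichotomize_age(49), "A1")
  expect_equal(dichotomize_age(50), "A2")
  expect_equal(dichotomize_age(0), "A1")
  expect_equal(dichotomize_age(c(12, 89.5)), c("A1", "A2"))
  expect_error(dichotomize_age(-1), "nonnegative")
})

test_that("enumeration is the ordered Cartesian product of scheme levels", {
  expect_length(enumerate_combinations(tnm_scheme()), 16)
  expect_length(enumerate_combinations(tnm_scheme(include_age = TRUE)), 32)
  expect_equal(enumerate_combinations(factor_scheme(X = c("X1", "X2"))),
               c("X1", "X2"))
  labs <- enumerate_combinations(tnm_scheme())
  expect_equal(labs[1:3], c("T1N0M0", "T1N0M1", "T1N1M0"))  # first factor slowest
  expect_false(anyDuplicated(labs) > 0)

  set.seed(42)
  for (i in 1:20) {
    nf <- sample(1:4, 1)
    sch <- factor_scheme(stats::setNames(
      lapply(seq_len(nf), function(f) paste0(LETTERS[f], seq_len(sample(1:4, 1)))),
      LETTERS[seq_len(nf)]))
    labs <- enumerate_combinations(sch)
    expect_length(labs, prod(lengths(sch$factors)))
    expect_false(anyDuplicated(labs) > 0)
  }
})

test_that("records map to exactly one combination and bad levels error", {
  sch <- tnm_scheme()
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1),
                    T = c("T1", "T1", "T2"), N = "N0", M = "M0")
  co <- build_combinations(rec, sch)
  expect_equal(unname(co$counts[c("T1N0M0", "T2N0M0")]), c(2, 1))
  expect_equal(sum(co$counts), nrow(rec))                    # conservation
  expect_length(co$empty, 14)

  rec$T[2] <- "T5"
  expect_error(build_combinations(rec, sch), "T5")
  expect_error(build_combinations(rec[, -3], sch), "factor column")
})

test_that("small-combination filter applies the threshold and is idempotent", {
  sch <- factor_scheme(G = c("A", "B"))
  rec <- data.frame(time = seq_len(34), event = 1,
                    G = rep(c("A", "B"), c(20, 14)))
  co <- build_combinations(rec, sch)

  f15 <- filter_small_combinations(co, 15)
  expect_equal(names(f15$cohort$groups), "A")
  expect_equal(f15$exclusions$combination, "B")
  expect_equal(sum(f15$exclusions$n), 14)
  expect_equal(f15$cohort$n + sum(f15$exclusions$n), co$n)   # conservation

  # boundary: exactly min_n is kept
  rec15 <- data.frame(time = seq_len(15), event = 1, G = "B")
  expect_equal(names(filter_small_combinations(
    build_combinations(rec15, sch), 15)$cohort$groups), "B")

  f1 <- filter_small_combinations(co, 1)
  expect_equal(length(f1$cohort$groups), 2)

  twice <- filter_small_combinations(f15$cohort, 15)
  expect_identical(twice$cohort$counts, f15$cohort$counts)   # idempotent
  expect_equal(nrow(twice$exclusions), 0)
})

test_that("cohort writer round-trips through read_cohort", {
  rec <- data.frame(time = c(1.5, 2, 3), event = c(1L, 0L, 1L),
                    T = "T1", N = c("N0", "N0", "N1"), M = "M0")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(rec, f)
  back <- read_cohort(f, list(time = "time", event = "event", T = "T",
                              N = "N", M = "M"))
  expect_equal(back$records, rec)
  expect_equal(back$audit$n_dropped, 0)
})
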