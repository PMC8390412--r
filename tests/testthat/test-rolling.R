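# standardization, pooled fit, per-age driver, family-block bootstrap

test_that("standardize_measures matches a hand-computed z-score table", {
  d <- hand_table(5, n_fam = 2)
  d$phenotype <- c(1, 2, 3, 4, 10)
  s <- standardize_measures(d)
  z <- (d$phenotype - mean(d$phenotype)) / sd(d$phenotype)
  expect_equal(s$phenotype, z, tolerance = 1e-12)
  expect_equal(mean(s$phenotype), 0, tolerance = 1e-12)
  expect_equal(sd(s$phenotype), 1, tolerance = 1e-12)
  expect_equal(s$age_sq, s$age_std^2, tolerance = 1e-14)
  expect_identical(s$age, d$age)                 # raw age untouched
})

test_that("standardizing twice is idempotent; zero variance errors by name", {
  d <- hand_table(10, n_fam = 3)
  s1 <- standardize_measures(d)
  s2 <- standardize_measures(s1)
  expect_equal(s1, s2, tolerance = 1e-12, ignore_attr = TRUE)
  d$pgs <- 1
  expect_error(standardize_measures(d), "zero-variance column: pgs")
})

test_that("fit_pooled equals a direct unweighted wlmm fit", {
  # a real signal so the pseudo-R2 sign check is not at the mercy of
  # small-sample REML noise
  d <- make_data(n_families = 200, seed = 21, beta_age = 0.3)
  pf <- fit_pooled(d)
  direct <- fit_wlmm(build_design(d), weights = rep(1, nrow(d)))
  expect_equal(coef(pf), coef(direct), tolerance = 1e-9)
  expect_equal(pf$beta_pgs, unname(coef(direct)["pgs"]))
  expect_gte(pf$pseudo_r2, -1e-8)
  expect_error(fit_pooled(hand_table()), "standardized")
})

test_that("focus-age grid covers the configured range, one record per age", {
  d <- make_data(n_families = 150, seed = 2)
  rr <- run_rolling(d, 20, 40, n_boot = 0, seed = 1)
  expect_s3_class(rr, "rolling_result")
  expect_identical(rr$focus_age, 20:40)
  expect_identical(nrow(rr), 21L)
  expect_true(all(rr$status == "ok"))
  expect_true(all(rr$effective_n <= nrow(d)))
})

test_that("fixed seed and data give bit-identical rolling results", {
  d <- make_data(n_families = 60, seed = 4)
  r1 <- run_rolling(d, 28, 30, n_boot = 8, seed = 99)
  r2 <- run_rolling(d, 28, 30, n_boot = 8, seed = 99)
  expect_identical(r1$estimate, r2$estimate)
  expect_identical(r1$se_boot, r2$se_boot)
  expect_identical(r1$ci_lower, r2$ci_lower)
})

test_that("effective N at a focus age >= raw rows exactly at that age", {
  d <- make_data(n_families = 150, seed = 6)
  d$age <- round(d$age)                      # integer ages so exact hits exist
  rr <- run_rolling(d, 25, 35, n_boot = 0, seed = 1)
  for (i in seq_len(nrow(rr))) {
    raw_n <- sum(d$age == rr$focus_age[i])
    expect_gte(rr$effective_n[i], raw_n)
  }
})

test_that("CI straddles the estimate and flags significance correctly", {
  d <- make_data(n_families = 120, seed = 8, beta_age = 0.5)
  rr <- run_rolling(d, 40, 40, n_boot = 30, seed = 5)
  expect_lt(rr$ci_lower, rr$estimate)
  expect_gt(rr$ci_upper, rr$estimate)
  expect_identical(rr$significant, rr$ci_lower > 0 | rr$ci_upper < 0)
  expect_identical(rr$n_boot_ok, 30L)
})

test_that("one-family data: every resample identical, bootstrap SE = 0", {
  set.seed(15)
  n <- 40
  d <- data.frame(person = paste0("p", 1:n), family = "f1",
                  age = seq(20, 50, length.out = n), phenotype = rnorm(n),
                  pgs = rnorm(n), sex = rep_len(0:1, n),
                  array = rep_len(c("A", "A", "B"), n),
                  pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
                  pc4 = rnorm(n), pc5 = rnorm(n))
  d <- standardize_measures(d)
  rr <- run_rolling(d, 35, 35, n_boot = 10, seed = 3)
  expect_identical(rr$se_boot, 0)
})

test_that("more than 20% failed bootstrap refits is an error", {
  set.seed(44)
  # each PC varies inside exactly one of 5 families, so a resample is full
  # rank only when it contains all 5 families (probability 5!/5^5, about 4%):
  # nearly every refit fails and the 20% failure cap trips
  n <- 40
  fam <- rep(1:5, each = 8)
  d <- data.frame(person = paste0("p", 1:n), family = paste0("f", fam),
                  age = rep(seq(20, 48, by = 4), 5), phenotype = rnorm(n),
                  pgs = rnorm(n), sex = rep_len(0:1, n),
                  array = rep_len(c("A", "A", "B"), n))
  for (j in 1:5)
    d[[paste0("pc", j)]] <- ifelse(fam == j, rnorm(n), 0)
  d <- standardize_measures(d)
  expect_error(run_rolling(d, 30, 30, n_boot = 10, seed = 7),
               "bootstrap refits failed")
})

test_that("failed focus ages are recorded and the run continues", {
  set.seed(46)
  n <- 40
  d <- data.frame(person = paste0("p", 1:n), family = paste0("f", rep(1:10, 4)),
                  age = seq(12, 70, length.out = n), phenotype = rnorm(n),
                  pgs = rnorm(n), sex = rep_len(0:1, n),
                  array = rep_len(c("A", "A", "B"), n),
                  pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
                  pc4 = rnorm(n), pc5 = rnorm(n))
  # pc5 only varies below age 25: high focus ages keep only rows where it is
  # constant, so those fits are rank deficient and must be recorded as failed
  d$pc5 <- ifelse(d$age < 25, d$pc5, 0)
  d <- standardize_measures(d)
  rr <- suppressMessages(run_rolling(d, 58, 62, n_boot = 0, seed = 1))
  expect_identical(nrow(rr), 5L)
  expect_true(all(rr$status == "failed"))
  expect_gte(length(attr(rr, "failures")), 1L)
  # the same data still fits fine at young focus ages
  ok <- run_rolling(d, 18, 20, n_boot = 0, seed = 1)
  expect_true(all(ok$status == "ok"))
})

test_that("a smaller decay (wider kernel) smooths the estimate sequence", {
  d <- make_data(n_families = 250, seed = 12)
  r_wide <- run_rolling(d, 20, 60, decay = 5, n_boot = 0, seed = 1)
  r_narrow <- run_rolling(d, 20, 60, decay = 40, n_boot = 0, seed = 1)
  expect_lt(var(diff(r_wide$estimate)), var(diff(r_narrow$estimate)))
})
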