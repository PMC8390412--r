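# weighted family mixed model: design assembly, fitting, oracles

test_that("build_design assembles the documented fixed-effect columns", {
  d <- standardize_measures(hand_table(14, n_fam = 3))
  des <- build_design(d)
  expect_named_cols <- c("(Intercept)", "pgs", "age_std", "age_sq", "sex",
                         "array_B", "pc1", "pc2", "pc3", "pc4", "pc5")
  expect_identical(colnames(des$X), expect_named_cols)
  # hand-written oracle for the matrix itself
  Xh <- cbind(1, d$pgs, d$age_std, d$age_std^2, d$sex,
              as.numeric(d$array == "B"),
              d$pc1, d$pc2, d$pc3, d$pc4, d$pc5)
  expect_equal(unname(des$X), Xh, tolerance = 1e-14)
  # 2 arrays -> 1 dummy, reference = most frequent level
  expect_identical(sum(grepl("^array_", colnames(des$X))), 1L)
  des0 <- build_design(d, include_pgs = FALSE)
  expect_false("pgs" %in% colnames(des0$X))
})

test_that("rank-deficient non-array columns raise an error naming them", {
  d <- standardize_measures(hand_table(12, n_fam = 4))
  d$pc5 <- d$pc4                      # exact collinearity
  expect_error(build_design(d), "pc")
})

test_that("OLS limit: unit weights, singleton families, zero family variance", {
  set.seed(5)
  d <- hand_table(20, n_fam = 20)     # every person their own family
  d <- standardize_measures(d)
  des <- build_design(d)
  fit <- fit_wlmm(des, weights = NULL, fixed_vc = c(family = 0, resid = 1))
  # independent normal-equations oracle
  beta_ols <- solve(crossprod(des$X), crossprod(des$X, des$y))[, 1]
  expect_equal(unname(coef(fit)), unname(beta_ols), tolerance = 1e-6)
})

test_that("fixed variance components reproduce the dense-matrix GLS oracle", {
  set.seed(9)
  d <- standardize_measures(hand_table(24, n_fam = 3))
  des <- build_design(d)
  w <- runif(24, 0.2, 1)
  fit <- fit_wlmm(des, weights = w, fixed_vc = c(family = 0.4, resid = 0.8))
  fam <- as.integer(factor(d$family))
  oracle <- dense_gls(des$X, des$y, fam, w, fam_var = 0.4, resid_var = 0.8)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
  expect_equal(fit$var_family, 0.4)
  expect_equal(fit$sigma2, 0.8)
})

test_that("random-slope fit matches the dense GLS oracle at fixed components", {
  set.seed(19)
  d <- standardize_measures(hand_table(30, n_fam = 4))
  des <- build_design(d, random_slope = TRUE)
  w <- runif(30, 0.3, 1)
  fit <- fit_wlmm(des, weights = w,
                  fixed_vc = c(family = 0.3, slope = 0.15, resid = 0.7))
  fam <- as.integer(factor(d$family))
  oracle <- dense_gls(des$X, des$y, fam, w, fam_var = 0.3, resid_var = 0.7,
                      slope_var = 0.15, age = d$age_std)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
})

test_that("profiled fit agrees with a brute-force grid maximizer (ML)", {
  set.seed(23)
  sim <- simulate_measures(sim_config(
    n_families = 5, family_size_probs = c("3" = 0.5, "4" = 0.5),
    measures_probs = c("2" = 1), fam_intercept_var = 0.4), seed = 23)
  d <- standardize_measures(sim$data)
  expect_lte(nrow(d), 40)
  des <- build_design(d)
  w <- compute_weights(d$age, kernel_params(median(d$age)))$weight
  keep <- w >= 1e-8
  fit <- fit_wlmm(des, weights = w, method = "ML")
  # grid search over the family-variance ratio using an independent dense
  # likelihood (residual variance profiled by inner grid)
  X <- des$X[keep, , drop = FALSE]; y <- des$y[keep]
  fam <- as.integer(factor(d$family[keep])); wk <- w[keep]
  grid_min <- function(fvs, rvs) {
    grid <- expand.grid(fv = fvs, rv = rvs)
    nll <- mapply(function(fv, rv) dense_neg2ll(X, y, fam, wk, fv, rv),
                  grid$fv, grid$rv)
    grid[which.min(nll), ]
  }
  coarse <- grid_min(seq(0, 2, by = 0.05), seq(0.05, 2.5, by = 0.05))
  best <- grid_min(seq(max(0, coarse$fv - 0.06), coarse$fv + 0.06, by = 0.002),
                   seq(max(0.01, coarse$rv - 0.06), coarse$rv + 0.06,
                       by = 0.002))
  oracle <- dense_gls(X, y, fam, wk, best$fv, best$rv)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 5e-4)
})

test_that("estimated fit agrees with lme4 on unweighted data", {
  skip_if_not_installed("lme4")
  d <- make_data(n_families = 150, seed = 31)
  des <- build_design(d)
  fit <- fit_wlmm(des, method = "REML")
  m <- lme4::lmer(
    phenotype ~ pgs + age_std + age_sq + sex + array +
      pc1 + pc2 + pc3 + pc4 + pc5 + (1 | family),
    data = d, REML = TRUE)
  expect_equal(unname(coef(fit)["pgs"]), unname(lme4::fixef(m)["pgs"]),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$var_family, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
})

test_that("multiplying all weights by a constant leaves beta-hat unchanged", {
  set.seed(11)
  d <- make_data(n_families = 60, seed = 11)
  des <- build_design(d)
  # weights bounded away from the drop threshold so both fits keep the
  # same rows and the invariance is exact
  w <- runif(nrow(d), 0.05, 1)
  f1 <- fit_wlmm(des, weights = w)
  f2 <- fit_wlmm(des, weights = 7.3 * w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("a zero-weight row is equivalent to deleting the row", {
  d <- make_data(n_families = 40, seed = 13)
  des_full <- build_design(d)
  w <- rep(1, nrow(d)); w[5] <- 0
  f_w <- fit_wlmm(des_full, weights = w)
  d2 <- d[-5, ]
  attr(d2, "standardized") <- TRUE    # same scaling, one row removed
  f_del <- fit_wlmm(build_design(d2), weights = rep(1, nrow(d2)))
  expect_equal(coef(f_w), coef(f_del), tolerance = 1e-9)
  expect_equal(f_w$var_family, f_del$var_family, tolerance = 1e-7)
})

test_that("ML log-likelihood is non-decreasing when the PGS is added", {
  d <- make_data(n_families = 80, seed = 17)
  f1 <- fit_wlmm(build_design(d), method = "ML")
  f0 <- fit_wlmm(build_design(d, include_pgs = FALSE), method = "ML")
  expect_gte(f1$logLik, f0$logLik - 1e-6)
})

test_that("zero response gives zero coefficients and zero residual variance", {
  d <- make_data(n_families = 30, seed = 19)
  d$phenotype <- 0
  attr(d, "standardized") <- TRUE     # bypass the zero-variance guard on purpose
  fit <- fit_wlmm(build_design(d))
  expect_equal(unname(coef(fit)), rep(0, length(coef(fit))), tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  expect_true(fit$boundary)
})

test_that("pseudo-R2: null simulation is near zero, mismatches error", {
  sim <- simulate_measures(sim_config(n_families = 1200, beta_age = 0),
                           seed = 29)
  d <- standardize_measures(sim$data)
  f1 <- fit_wlmm(build_design(d))
  f0 <- fit_wlmm(build_design(d, include_pgs = FALSE))
  r2 <- pseudo_r2(f1, f0)
  expect_lt(abs(r2), 0.005)
  expect_error(pseudo_r2(f1, f1), "one fit with a 'pgs' column")
  d_small <- d[1:100, ]; attr(d_small, "standardized") <- TRUE
  f0_small <- fit_wlmm(build_design(d_small, include_pgs = FALSE))
  expect_error(pseudo_r2(f1, f0_small), "n mismatch")
})

test_that("pseudo-R2 approaches beta^2 for a pure standardized effect", {
  # phenotype = 0.2 * pgs + noise, no other structure: expect R2 ~ 0.04
  sim <- simulate_measures(sim_config(
    n_families = 2500, beta_age = 0.2, sex_effect = 0,
    fam_intercept_var = 0.2, resid_var = 0.96 - 0.2), seed = 37)
  d <- standardize_measures(sim$data)
  f1 <- fit_wlmm(build_design(d))
  f0 <- fit_wlmm(build_design(d, include_pgs = FALSE))
  expect_equal(pseudo_r2(f1, f0), 0.04, tolerance = 0.35)
})
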