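#' Configuration for the family-data simulator
#'
#' Describes a synthetic cohort of families with repeated aggression-like
#' measures: family sizes, measures per person, the age distribution, the
#' within-family polygenic-score correlation, an age-varying genetic effect
#' `beta_age(age)`, covariate effects, variance components, and the item
#' structure used to emit ordinal response matrices per wave.
#'
#' Defaults emulate an adult twin-register cohort: families of 1-4 related
#' members, 1-3 questionnaire measures per person at ages 12-70, a
#' sibling-like within-family PGS correlation of 0.5, a constant
#' standardized genetic effect of 0.05, a family intraclass share of about
#' 0.3 of the phenotype variance, and 15 three-category items per wave.
#'
#' @param n_families Number of families.
#' @param family_size_probs Named probabilities for family sizes (names are
#'   the sizes).
#' @param measures_probs Named probabilities for per-person measure counts.
#' @param age_range Two-element numeric range of ages in years.
#' @param age_dist `"uniform"` or `"bimodal"` (adolescent/adult mixture).
#' @param pgs_family_cor Within-family PGS correlation in `[0, 1]`
#'   (shared family component + individual component; marginal variance 1).
#' @param beta_age Function of age giving the genetic effect at that age
#'   (on the standardized scale), or a single number for a constant effect.
#' @param sex_effect Additive effect of sex (coded 1 = female).
#' @param p_female Probability a person is female.
#' @param pc_effects Length-5 effects of the ancestry PCs.
#' @param array_levels Number of genotyping-array categories.
#' @param array_effects Per-array additive effects (length `array_levels`).
#' @param fam_intercept_var Family random-intercept variance.
#' @param fam_slope_var Family random age-slope variance (slope applies to
#'   age centered and scaled within the configured range).
#' @param resid_var Residual variance.
#' @param n_waves,n_items,n_cat Waves of item data, items per wave,
#'   categories per item (3 = never/sometimes/often-like; 5 = Likert-like).
#' @param discrim_range,step_range Uniform ranges for item discriminations
#'   and (sorted) step parameters.
#' @param missing_rate Completely-at-random per-cell missingness for item
#'   data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 500,
                       family_size_probs = c("1" = 0.2, "2" = 0.4,
                                             "3" = 0.25, "4" = 0.15),
                       measures_probs = c("1" = 0.45, "2" = 0.35, "3" = 0.2),
                       age_range = c(12, 70),
                       age_dist = c("uniform", "bimodal"),
                       pgs_family_cor = 0.5,
                       beta_age = 0.05,
                       sex_effect = -0.1,
                       p_female = 0.62,
                       pc_effects = rep(0, 5),
                       array_levels = 3,
                       array_effects = rep(0, array_levels),
                       fam_intercept_var = 0.3,
                       fam_slope_var = 0,
                       resid_var = 0.65,
                       n_waves = 2, n_items = 15, n_cat = 3,
                       discrim_range = c(0.8, 2),
                       step_range = c(-2, 2),
                       missing_rate = 0.05) {
  age_dist <- match.arg(age_dist)
  if (is.numeric(beta_age) && length(beta_age) == 1L) {
    b <- beta_age
    beta_age <- function(age) rep(b, length(age))
  }
  stopifnot(is.function(beta_age))
  if (n_families < 2) stop("need at least 2 families")
  if (fam_intercept_var < 0 || fam_slope_var < 0 || resid_var < 0)
    stop("variances must be >= 0")
  if (pgs_family_cor < 0 || pgs_family_cor > 1)
    stop("pgs_family_cor must lie in [0, 1]")
  if (n_cat < 2) stop("items need at least 2 categories")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  if (length(pc_effects) != 5) stop("pc_effects must have length 5")
  if (length(array_effects) != array_levels)
    stop("array_effects must have length array_levels")
  if (abs(sum(family_size_probs) - 1) > 1e-8 ||
      abs(sum(measures_probs) - 1) > 1e-8)
    stop("size/measure probabilities must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

draw_ages <- function(n, cfg) {
  if (cfg$age_dist == "uniform")
    return(stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
  # young/adult clustering: adolescent peak + broad adult hump
  young <- stats::runif(n) < 0.45
  a <- ifelse(young, stats::rnorm(n, 17, 2.5), stats::rnorm(n, 42, 13))
  pmin(pmax(a, cfg$age_range[1]), cfg$age_range[2])
}

#' Simulate family-structured repeated measures
#'
#' Draws families, within-family-correlated polygenic scores, person-level
#' covariates, measurement ages, and a phenotype
#' `beta_age(age) * PGS + covariate effects + family intercept
#' (+ family age slope) + residual noise`, together with the exact
#' generating values for recovery tests.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (all randomness flows from it).
#' @return List with `data` (the measure table: `measure`, `person`,
#'   `family`, `age`, `phenotype`, `pgs`, `sex`, `array`, `pc1`..`pc5`,
#'   `wave`, `theta`) and `truth` (config plus the realized family effects
#'   and the per-measure linear predictor). `theta` is the noiseless +
#'   noise latent trait that item simulation consumes.
#' @export
simulate_measures <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config

  size_opts <- as.integer(names(cfg$family_size_probs))
  sizes <- size_opts[sample.int(length(size_opts), cfg$n_families,
                                replace = TRUE,
                                prob = cfg$family_size_probs)]
  n_person <- sum(sizes)
  person_fam <- rep(seq_len(cfg$n_families), sizes)

  # PGS: shared family + individual component, marginal N(0, 1),
  # within-family correlation = pgs_family_cor
  u_f <- stats::rnorm(cfg$n_families)
  pgs_p <- sqrt(cfg$pgs_family_cor) * u_f[person_fam] +
    sqrt(1 - cfg$pgs_family_cor) * stats::rnorm(n_person)

  sex_p <- stats::rbinom(n_person, 1, cfg$p_female)
  array_p <- sample(LETTERS[seq_len(cfg$array_levels)], n_person,
                    replace = TRUE)
  pcs_p <- matrix(stats::rnorm(n_person * 5), n_person, 5)

  b0_f <- stats::rnorm(cfg$n_families, 0, sqrt(cfg$fam_intercept_var))
  b1_f <- stats::rnorm(cfg$n_families, 0, sqrt(cfg$fam_slope_var))

  meas_opts <- as.integer(names(cfg$measures_probs))
  n_meas_p <- meas_opts[sample.int(length(meas_opts), n_person,
                                   replace = TRUE,
                                   prob = cfg$measures_probs)]
  idx <- rep(seq_len(n_person), n_meas_p)
  n <- length(idx)
  age <- draw_ages(n, cfg)
  age_c <- (age - mean(cfg$age_range)) / (diff(cfg$age_range) / sqrt(12))
  fam <- person_fam[idx]

  lin <- cfg$beta_age(age) * pgs_p[idx] +
    cfg$sex_effect * sex_p[idx] +
    as.numeric(pcs_p[idx, , drop = FALSE] %*% cfg$pc_effects) +
    cfg$array_effects[match(array_p[idx], LETTERS)] +
    b0_f[fam] + b1_f[fam] * age_c
  phen <- lin + stats::rnorm(n, 0, sqrt(cfg$resid_var))

  # occasion index within person: (person, wave) is unique by construction
  wave <- paste0("w", stats::ave(idx, idx, FUN = seq_along))
  data <- data.frame(
    measure = seq_len(n),
    person = paste0("p", idx),
    family = paste0("f", fam),
    age = age, phenotype = phen, pgs = pgs_p[idx],
    sex = sex_p[idx], array = array_p[idx],
    pc1 = pcs_p[idx, 1], pc2 = pcs_p[idx, 2], pc3 = pcs_p[idx, 3],
    pc4 = pcs_p[idx, 4], pc5 = pcs_p[idx, 5],
    wave = wave,
    theta = phen,
    stringsAsFactors = FALSE
  )
  list(data = data,
       truth = list(config = cfg, seed = seed,
                    family_intercepts = b0_f, family_slopes = b1_f,
                    person_pgs = pgs_p, linear_predictor = lin))
}

#' Simulate ordinal item responses from a Generalized Partial Credit Model
#'
#' Draws per-wave item parameters from the configured ranges and samples
#' category responses for each person's latent trait value, then injects
#' completely-at-random missingness.
#'
#' @param config A [sim_config()] (fields `n_waves`, `n_items`, `n_cat`,
#'   `discrim_range`, `step_range`, `missing_rate`).
#' @param thetas Named numeric vector of latent trait values (names become
#'   row names / person ids). All waves use the same persons.
#' @param seed Integer seed.
#' @return Named list of persons x items integer matrices, one per wave,
#'   with the generating item parameters in attribute `"item_params"`.
#' @export
simulate_items <- function(config, thetas, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cat < 2) stop("items need at least 2 categories")
  set.seed(seed)
  n <- length(thetas)
  if (is.null(names(thetas))) names(thetas) <- paste0("p", seq_len(n))
  waves <- vector("list", config$n_waves)
  params <- vector("list", config$n_waves)
  for (wv in seq_len(config$n_waves)) {
    a <- stats::runif(config$n_items, config$discrim_range[1],
                      config$discrim_range[2])
    b <- lapply(seq_len(config$n_items), function(j)
      sort(stats::runif(config$n_cat - 1, config$step_range[1],
                        config$step_range[2])))
    resp <- matrix(NA_integer_, n, config$n_items,
                   dimnames = list(names(thetas),
                                   paste0("item", seq_len(config$n_items))))
    for (j in seq_len(config$n_items)) {
      pr <- exp(gpcm_logprob(a[j], b[[j]], thetas))   # n x K
      cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)  # row cumsums
      u <- stats::runif(n)
      resp[, j] <- pmin.int(rowSums(cum < u), config$n_cat - 1L)
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * config$n_items) < config$missing_rate,
                     n, config$n_items)
      resp[miss] <- NA_integer_
    }
    waves[[wv]] <- resp
    params[[wv]] <- list(a = a, b = b)
  }
  names(waves) <- names(params) <- paste0("w", seq_len(config$n_waves))
  attr(waves, "item_params") <- params
  waves
}
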