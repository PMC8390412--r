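#' Standardize a measure table for analysis
#'
#' Centers and scales the continuous model columns (phenotype, polygenic
#' score, the five principal components) to mean 0 / SD 1 over the full
#' dataset, once, before any per-age analysis. Adds `age_std` (standardized
#' age) and `age_sq` (the square of standardized age — computed after
#' standardizing, not the standardized square). The raw `age` column is kept
#' untouched: the weight kernel always operates on raw ages.
#'
#' @param data Measure table with columns `person`, `family`, `age`,
#'   `phenotype`, `pgs`, `sex`, `array`, `pc1`..`pc5` (and optionally `wave`).
#' @return The table with standardized columns, `age_std`, `age_sq`, and
#'   attribute `standardized = TRUE`. Standardizing twice is idempotent.
#' @export
standardize_measures <- function(data) {
  req <- c("person", "family", "age", "phenotype", "pgs", "sex", "array",
           paste0("pc", 1:5))
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  zcols <- c("phenotype", "pgs", paste0("pc", 1:5))
  for (cl in c(zcols, "age")) {
    s <- stats::sd(data[[cl]])
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: ", cl, "; cannot standardize")
  }
  for (cl in zcols)
    data[[cl]] <- as.numeric(scale(data[[cl]]))
  data$age_std <- as.numeric(scale(data$age))
  data$age_sq <- data$age_std^2
  attr(data, "standardized") <- TRUE
  data
}

#' Pooled (unweighted) mixed-model fit
#'
#' Fits the family mixed model on the full dataset with unit weights: the
#' total-sample association between the polygenic score and the phenotype,
#' with the full covariate set. Also fits the covariate-only model to report
#' the pseudo-R-squared of the polygenic score.
#'
#' @param data A standardized measure table (see [standardize_measures()]).
#' @param random_slope Family random slope on standardized age (default off).
#' @param method `"REML"` or `"ML"`.
#' @return A `wlmm_fit` with extra elements `pseudo_r2`, `beta_pgs`,
#'   `se_pgs`, `p_pgs` (Wald).
#' @export
fit_pooled <- function(data, random_slope = FALSE, method = "REML") {
  if (!isTRUE(attr(data, "standardized")))
    stop("data must be standardized first (standardize_measures())")
  d1 <- build_design(data, random_slope = random_slope)
  f1 <- fit_wlmm(d1, weights = NULL, method = method)
  d0 <- build_design(data, random_slope = random_slope, include_pgs = FALSE)
  f0 <- fit_wlmm(d0, weights = NULL, method = method)
  f1$pseudo_r2 <- pseudo_r2(f1, f0)
  f1$beta_pgs <- unname(f1$coefficients["pgs"])
  f1$se_pgs <- unname(f1$se["pgs"])
  f1$p_pgs <- 2 * stats::pnorm(-abs(f1$beta_pgs / f1$se_pgs))
  f1
}

# deterministic per-(seed, focus age, replicate) RNG stream seed; < 2^31
derive_seed <- function(seed, focus_age, replicate) {
  s <- (seed %% 1000000) * 1000003 + round(focus_age) * 10007 + replicate
  as.integer(s %% 2147483647 + 1)
}

fit_one_age <- function(data, focus_age, shoulder, decay, random_slope,
                        method, min_weight) {
  wv <- compute_weights(data$age, kernel_params(focus_age, shoulder, decay))
  des <- build_design(data, random_slope = random_slope)
  fit <- fit_wlmm(des, weights = wv$weight, method = method,
                  min_weight = min_weight)
  list(fit = fit,
       effective_n = sum(wv$weight),
       n_rows = sum(wv$weight >= min_weight))
}

#' Per-focus-age rolling-weights analyses
#'
#' For every integer focus age in `[age_min, age_max]`, computes kernel
#' weights over the raw observation ages, drops near-zero-weight rows, fits
#' the weighted family mixed model (age covariates retained, since a range
#' of ages is still present in every fit), and — when `n_boot > 0` —
#' attaches family-block bootstrap standard errors and 95% confidence
#' intervals for the polygenic-score effect.
#'
#' @param data Standardized measure table.
#' @param age_min,age_max Integer bounds of the focus-age grid. Every integer
#'   age in the range gets an analysis, even ages with zero raw observations
#'   (neighbouring ages carry the information).
#' @param shoulder,decay Kernel parameters (defaults 1.5 and 25).
#' @param n_boot Bootstrap replicates per focus age (default 100; 0 skips
#'   the bootstrap).
#' @param seed Integer seed; every replicate draws from its own stream
#'   derived deterministically from `(seed, focus age, replicate)`, so
#'   results do not depend on execution order.
#' @param random_slope,method Passed to the mixed-model fit.
#' @param min_weight Rows with kernel weight below this are dropped from each
#'   fit; the effective N (sum of weights) is computed before dropping.
#' @param ci_type `"normal"` (CI = estimate +/- 1.96 x bootstrap SE, default)
#'   or `"percentile"`.
#' @return An object of class `rolling_result`: a data frame with one row
#'   per focus age — `focus_age`, `estimate` (standardized PGS effect),
#'   `se_model`, `se_boot`, `ci_lower`, `ci_upper`, `effective_n`, `n_rows`,
#'   `n_boot_ok`, `significant`, `status` — carrying the run configuration
#'   in attributes. Focus ages whose fit fails are recorded with
#'   `status = "failed"` and the run continues.
#' @export
run_rolling <- function(data, age_min, age_max, shoulder = 1.5, decay = 25,
                        n_boot = 100, seed = 1, random_slope = FALSE,
                        method = "REML", min_weight = 1e-8,
                        ci_type = c("normal", "percentile")) {
  if (!isTRUE(attr(data, "standardized")))
    stop("data must be standardized first (standardize_measures())")
  ci_type <- match.arg(ci_type)
  stopifnot(age_min <= age_max)
  ages <- seq.int(age_min, age_max)
  out <- data.frame(
    focus_age = ages, estimate = NA_real_, se_model = NA_real_,
    se_boot = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    effective_n = NA_real_, n_rows = NA_integer_, n_boot_ok = NA_integer_,
    significant = NA, status = "failed", stringsAsFactors = FALSE
  )
  failures <- list()
  for (i in seq_along(ages)) {
    res <- tryCatch(
      fit_one_age(data, ages[i], shoulder, decay, random_slope, method,
                  min_weight),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(ages[i])]] <- conditionMessage(res)
      next
    }
    out$estimate[i] <- unname(res$fit$coefficients["pgs"])
    out$se_model[i] <- unname(res$fit$se["pgs"])
    out$effective_n[i] <- res$effective_n
    out$n_rows[i] <- res$n_rows
    out$status[i] <- "ok"
  }
  if (length(failures))
    message(length(failures), " focus age(s) failed: ",
            paste(names(failures), collapse = ", "))
  attr(out, "config") <- list(
    age_min = age_min, age_max = age_max, shoulder = shoulder, decay = decay,
    n_boot = n_boot, seed = seed, random_slope = random_slope,
    method = method, min_weight = min_weight, ci_type = ci_type)
  attr(out, "failures") <- failures
  class(out) <- c("rolling_result", "data.frame")
  if (n_boot > 0) out <- bootstrap_ci(data, out, n_boot = n_boot, seed = seed)
  out
}

#' Family-block bootstrap confidence intervals
#'
#' Resamples complete families with replacement (the resample has the same
#' number of families as the data, and all of a family's rows travel
#' together, preserving within-family dependence), recomputes the kernel
#' weights on the resampled age vector, and refits the focus-age model. The
#' bootstrap SE is the SD of the resampled polygenic-score estimates; the
#' 95% CI is `estimate +/- 1.96 x bootstrap SE` (normal approximation) or
#' the percentile interval when configured. A focus age is flagged
#' significant when its CI excludes zero.
#'
#' @param data The standardized measure table the result was computed from.
#' @param result A `rolling_result` from [run_rolling()] (bootstrap columns
#'   may be empty).
#' @param n_boot Replicates per focus age (default 100).
#' @param seed Base seed; replicate streams derive from
#'   `(seed, focus age, replicate)`.
#' @return The `rolling_result` with `se_boot`, `ci_lower`, `ci_upper`,
#'   `n_boot_ok`, `significant` filled in.
#' @details Replicates whose refit fails are dropped and counted; more than
#'   20% failures at a focus age is an error.
#' @export
bootstrap_ci <- function(data, result, n_boot = 100, seed = 1) {
  stopifnot(inherits(result, "rolling_result"))
  cfg <- attr(result, "config")
  fam_rows <- split(seq_len(nrow(data)), data$family)
  n_fam <- length(fam_rows)
  for (i in seq_len(nrow(result))) {
    if (result$status[i] != "ok") next
    fage <- result$focus_age[i]
    betas <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      set.seed(derive_seed(seed, fage, b))
      draw <- sample.int(n_fam, n_fam, replace = TRUE)
      rows <- unlist(fam_rows[draw], use.names = FALSE)
      bd <- data[rows, , drop = FALSE]
      # each draw of a family is a distinct cluster in the resample
      bd$family <- rep(seq_along(draw), lengths(fam_rows[draw]))
      betas[b] <- tryCatch(
        fit_one_age(bd, fage, cfg$shoulder, cfg$decay, cfg$random_slope,
                    cfg$method, cfg$min_weight)$fit$coefficients[["pgs"]],
        error = function(e) NA_real_)
    }
    ok <- !is.na(betas)
    if (mean(!ok) > 0.2)
      stop(sprintf("focus age %s: %d of %d bootstrap refits failed (> 20%%)",
                   fage, sum(!ok), n_boot))
    result$n_boot_ok[i] <- sum(ok)
    result$se_boot[i] <- stats::sd(betas[ok])
    if (identical(cfg$ci_type, "percentile")) {
      qs <- stats::quantile(betas[ok], c(0.025, 0.975), names = FALSE)
      result$ci_lower[i] <- qs[1]; result$ci_upper[i] <- qs[2]
    } else {
      result$ci_lower[i] <- result$estimate[i] - 1.96 * result$se_boot[i]
      result$ci_upper[i] <- result$estimate[i] + 1.96 * result$se_boot[i]
    }
    result$significant[i] <- result$ci_lower[i] > 0 | result$ci_upper[i] < 0
  }
  cfg$n_boot <- n_boot; cfg$seed <- seed
  attr(result, "config") <- cfg
  result
}

#' @export
print.rolling_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Rolling-weights analysis: %d focus ages (%d-%d), shoulder %g, decay %g\n",
    nrow(x), cfg$age_min, cfg$age_max, cfg$shoulder, cfg$decay))
  nok <- sum(x$status == "ok")
  cat(sprintf("%d fitted, %d failed; bootstrap reps per age: %d\n",
              nok, nrow(x) - nok, cfg$n_boot))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot rolling polygenic-score estimates against age
#'
#' Estimates with the bootstrap 95% confidence band (grey) against focus
#' age, the visual summary of a rolling-weights run.
#'
#' @param x A `rolling_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_rolling <- function(x, ...) {
  ok <- x$status == "ok"
  has_ci <- ok & !is.na(x$ci_lower)
  ylim <- range(0, x$estimate[ok], x$ci_lower[has_ci], x$ci_upper[has_ci],
                na.rm = TRUE)
  graphics::plot(x$focus_age[ok], x$estimate[ok], type = "n", ylim = ylim,
                 xlab = "Focus age (years)",
                 ylab = "Standardized PGS effect", ...)
  if (any(has_ci))
    graphics::polygon(c(x$focus_age[has_ci], rev(x$focus_age[has_ci])),
                      c(x$ci_lower[has_ci], rev(x$ci_upper[has_ci])),
                      col = "grey85", border = NA)
  graphics::lines(x$focus_age[ok], x$estimate[ok], lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
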