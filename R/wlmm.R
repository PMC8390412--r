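#' Assemble design matrices for the weighted family mixed model
#'
#' Builds the fixed-effect design matrix `X` (intercept, polygenic score,
#' standardized age, standardized age squared, sex, genotyping-array dummies,
#' five ancestry principal components), the response vector, and the grouping
#' information for the family random effects.
#'
#' @param data A standardized measure table (see [standardize_measures()]):
#'   must contain `phenotype`, `pgs`, `age_std`, `age_sq`, `sex`, `array`,
#'   `pc1`..`pc5`, `family`.
#' @param random_slope If `TRUE`, families get a random slope on standardized
#'   age in addition to the random intercept.
#' @param include_pgs If `FALSE`, the polygenic-score column is omitted
#'   (covariate-only model, used for the pseudo-R-squared comparison).
#' @return An object of class `wlmm_design`: list with `X` (n x p matrix),
#'   `y`, `family` (integer codes), `age_std`, `random_slope`, `n`, `p`.
#' @details Array dummies use the most frequent array as reference. Dummies
#'   that are aliased with other columns are dropped with a warning; any
#'   other rank deficiency is an error naming the collinear columns.
#' @export
build_design <- function(data, random_slope = FALSE, include_pgs = TRUE) {
  req <- c("phenotype", "pgs", "age_std", "age_sq", "sex", "array",
           paste0("pc", 1:5), "family")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         " (run standardize_measures() first?)")
  n <- nrow(data)
  if (n == 0L) stop("empty data")

  arr <- as.factor(data$array)
  # reference level = most frequent array
  if (nlevels(arr) > 1L) {
    ref <- names(which.max(table(arr)))
    arr <- stats::relevel(arr, ref = ref)
    A <- stats::model.matrix(~arr)[, -1, drop = FALSE]
    colnames(A) <- paste0("array_", levels(arr)[-1])
  } else {
    A <- matrix(numeric(0), nrow = n, ncol = 0)
  }

  X <- cbind(
    "(Intercept)" = rep(1, n),
    if (include_pgs) cbind(pgs = data$pgs),
    age_std = data$age_std,
    age_sq = data$age_sq,
    sex = as.numeric(data$sex),
    A,
    pc1 = data$pc1, pc2 = data$pc2, pc3 = data$pc3,
    pc4 = data$pc4, pc5 = data$pc5
  )
  X <- drop_aliased(X, droppable = colnames(A))

  fam <- as.integer(factor(data$family))
  structure(list(X = X, y = as.numeric(data$phenotype), family = fam,
                 age_std = as.numeric(data$age_std),
                 random_slope = isTRUE(random_slope),
                 n = n, p = ncol(X)),
            class = "wlmm_design")
}

# Drop rank-deficient columns if they are in `droppable` (array dummies);
# otherwise error naming the collinear columns.
drop_aliased <- function(X, droppable = character(0)) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(X)
  aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
  bad <- setdiff(aliased, droppable)
  if (length(bad))
    stop("design matrix is rank deficient; collinear columns: ",
         paste(aliased, collapse = ", "))
  warning("dropping aliased array dummies: ", paste(aliased, collapse = ", "))
  drop_aliased(X[, setdiff(colnames(X), aliased), drop = FALSE], droppable)
}

#' Fit a weighted linear mixed model with family random effects
#'
#' Maximizes the (restricted) likelihood of the marginal model in which each
#' family block has covariance `V_f = Z_f G Z_f' + sigma^2 diag(1/w_f)`:
#' observation weights scale the residual precision (the usual weighted-LMM
#' convention), while the random-effect covariance `G` is unweighted. `G` is
#' a family intercept variance, plus an independent family slope variance on
#' standardized age when the design was built with `random_slope = TRUE`.
#' Fixed effects are the weighted GLS solution at the variance-component
#' optimum; their standard errors come from the GLS information matrix.
#'
#' @param design A [build_design()] object.
#' @param weights Per-row observation weights: a numeric vector, a
#'   `weight_vector` from [compute_weights()], or `NULL` for unit weights.
#'   Rows with weight below `min_weight` are dropped from the fit.
#' @param method `"REML"` (default) or `"ML"`.
#' @param fixed_vc Optional named numeric vector `c(family = , resid = )`
#'   (plus `slope =` when applicable) fixing the variance components instead
#'   of estimating them; the fixed effects are then the closed-form GLS
#'   solution at those values.
#' @param min_weight Rows with weight strictly below this are excluded
#'   (default `1e-8`); a weight-0 row is equivalent to deleting the row.
#' @return An object of class `wlmm_fit` with elements `coefficients`, `se`,
#'   `vcov`, `var_family`, `var_slope`, `sigma2`, `logLik`, `deviance`,
#'   `method`, `converged`, `boundary`, `n`, `p`, `n_dropped`, `message`.
#' @export
fit_wlmm <- function(design, weights = NULL, method = c("REML", "ML"),
                     fixed_vc = NULL, min_weight = 1e-8) {
  stopifnot(inherits(design, "wlmm_design"))
  method <- match.arg(method)
  w <- if (is.null(weights)) rep(1, design$n)
       else if (inherits(weights, "weight_vector")) weights$weight
       else as.numeric(weights)
  if (length(w) != design$n) stop("weights not aligned to design rows")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")

  keep <- w >= min_weight & w > 0   # zero-weight rows carry no information
  n_dropped <- sum(!keep)
  X <- design$X[keep, , drop = FALSE]
  y <- design$y[keep]
  fam <- design$family[keep]
  a <- design$age_std[keep]
  w <- w[keep]
  fam <- as.integer(factor(fam))      # recompact after dropping
  n <- length(y); p <- ncol(X)
  # a single family is permitted (degenerate but well defined: the family
  # intercept is confounded with the fixed intercept); at least 2 families
  # are needed for the variance component to be meaningfully estimated
  if (n <= p) stop("fewer informative rows than fixed-effect columns")

  prec <- precompute_wlmm(X, y, fam, a, w, design$random_slope)
  k <- if (design$random_slope) 2L else 1L

  if (!is.null(fixed_vc)) {
    if (!all(c("family", "resid") %in% names(fixed_vc)))
      stop("fixed_vc must name 'family' and 'resid'")
    if (fixed_vc["resid"] <= 0) stop("fixed resid variance must be > 0")
    gam <- fixed_vc[["family"]] / fixed_vc[["resid"]]
    if (design$random_slope) {
      if (!"slope" %in% names(fixed_vc)) stop("fixed_vc must name 'slope'")
      gam <- c(gam, fixed_vc[["slope"]] / fixed_vc[["resid"]])
    }
    sol <- wlmm_criterion(gam, prec, method, want_fit = TRUE)
    return(finish_wlmm(sol, gam, prec, method, design, n, p, n_dropped,
                       converged = TRUE, boundary = any(gam == 0),
                       msg = "variance components fixed by caller",
                       sigma2_override = fixed_vc[["resid"]]))
  }

  # degenerate response: exact fit at gamma = 0
  if (sum(w * y^2) < 1e-28 * n) {
    gam <- rep(0, k)
    sol <- wlmm_criterion(gam, prec, method, want_fit = TRUE)
    return(finish_wlmm(sol, gam, prec, method, design, n, p, n_dropped,
                       converged = TRUE, boundary = TRUE,
                       msg = "degenerate response (zero weighted sum of squares)"))
  }

  obj <- function(g) wlmm_criterion(g, prec, method)
  if (k == 1L) {
    upper <- 4
    opt <- stats::optimize(obj, c(0, upper), tol = 1e-9)
    while (opt$minimum > 0.95 * upper && upper < 1e6) {
      upper <- upper * 16
      opt <- stats::optimize(obj, c(0, upper), tol = 1e-9)
    }
    gam <- opt$minimum
    if (obj(0) <= opt$objective) gam <- 0
    converged <- TRUE; msg <- "optimize() on [0, upper]"
  } else {
    res <- stats::nlminb(c(0.3, 0.1), obj, lower = c(0, 0), upper = c(1e6, 1e6),
                         control = list(rel.tol = 1e-10, iter.max = 500))
    gam <- res$par
    converged <- res$convergence == 0 ||
      grepl("convergence", res$message, ignore.case = TRUE)
    if (!converged)
      stop("variance-component optimizer did not converge: ", res$message,
           " (objective ", format(res$objective), ", par ",
           paste(format(res$par), collapse = ", "), ")")
    msg <- res$message
  }
  sol <- wlmm_criterion(gam, prec, method, want_fit = TRUE)
  finish_wlmm(sol, gam, prec, method, design, n, p, n_dropped,
              converged = converged, boundary = any(gam <= 1e-10), msg = msg)
}

# Per-family aggregates that the profiled criterion reuses at every
# variance-component evaluation. Uses the Woodbury identity on
# R_f = diag(1/w_f) + U_f Gamma U_f' so no per-family matrix is ever formed.
precompute_wlmm <- function(X, y, fam, a, w, random_slope) {
  sw <- sqrt(w)
  XtWX <- crossprod(sw * X)
  XtWy <- crossprod(X, w * y)
  yWy <- sum(w * y^2)
  logw <- sum(log(w))
  out <- list(XtWX = XtWX, XtWy = XtWy, yWy = yWy, logw = logw,
              n = length(y), p = ncol(X), random_slope = random_slope,
              Sw = rowsum(w, fam)[, 1],
              B1 = rowsum(w * X, fam),
              b1y = rowsum(w * y, fam)[, 1])
  if (random_slope) {
    out$Swa <- rowsum(w * a, fam)[, 1]
    out$Swa2 <- rowsum(w * a^2, fam)[, 1]
    out$B2 <- rowsum(w * a * X, fam)
    out$b2y <- rowsum(w * a * y, fam)[, 1]
  }
  out
}

# Profiled -2 log (restricted) likelihood at relative variance components
# gamma = G / sigma^2; sigma^2 and beta are profiled out analytically.
wlmm_criterion <- function(gam, prec, method, want_fit = FALSE) {
  n <- prec$n; p <- prec$p
  if (!prec$random_slope) {
    g0 <- gam[1]
    cf <- g0 / (1 + g0 * prec$Sw)                       # per-family shrinkage
    XtRX <- prec$XtWX - crossprod(prec$B1, prec$B1 * cf)
    XtRy <- prec$XtWy - crossprod(prec$B1, prec$b1y * cf)
    yRy <- prec$yWy - sum(cf * prec$b1y^2)
    logdetR <- sum(log1p(g0 * prec$Sw)) - prec$logw
  } else {
    g0 <- gam[1]; g1 <- gam[2]
    Sw <- prec$Sw; Swa <- prec$Swa; Swa2 <- prec$Swa2
    # |I + Gamma M_f| and the 2x2 inverse of (Gamma^{-1} + M_f), written so
    # that g0 = 0 or g1 = 0 reduce exactly to the rank-1 / OLS cases
    det_im <- (1 + g0 * Sw) * (1 + g1 * Swa2) - g0 * g1 * Swa^2
    al <- (g0 + g0 * g1 * Swa2) / det_im
    de <- (g1 + g0 * g1 * Sw) / det_im
    be <- -(g0 * g1 * Swa) / det_im
    B1 <- prec$B1; B2 <- prec$B2
    XtRX <- prec$XtWX - crossprod(B1, al * B1) - crossprod(B1, be * B2) -
      crossprod(B2, be * B1) - crossprod(B2, de * B2)
    XtRy <- prec$XtWy - crossprod(B1, al * prec$b1y + be * prec$b2y) -
      crossprod(B2, be * prec$b1y + de * prec$b2y)
    yRy <- prec$yWy - sum(al * prec$b1y^2 + 2 * be * prec$b1y * prec$b2y +
                            de * prec$b2y^2)
    logdetR <- sum(log(det_im)) - prec$logw
  }
  beta <- tryCatch(solve(XtRX, XtRy),
                   error = function(e) stop("singular weighted information ",
                                            "matrix: ", conditionMessage(e)))
  rss <- max(yRy - sum(beta * XtRy), 0)
  denom <- if (method == "REML") n - p else n
  sigma2 <- rss / denom
  ld_fix <- if (method == "REML") determinant(XtRX)$modulus[1] else 0
  dev <- if (sigma2 > 0)
    denom * (log(2 * pi * sigma2) + 1) + logdetR + ld_fix
  else -Inf
  if (!want_fit) return(dev)
  list(beta = beta[, 1], XtRX = XtRX, rss = rss, sigma2 = sigma2,
       deviance = dev)
}

finish_wlmm <- function(sol, gam, prec, method, design, n, p, n_dropped,
                        converged, boundary, msg, sigma2_override = NULL) {
  sigma2 <- if (is.null(sigma2_override)) sol$sigma2 else sigma2_override
  vcv <- sigma2 * solve(sol$XtRX)
  cn <- colnames(design$X)
  beta <- stats::setNames(sol$beta, cn)
  dimnames(vcv) <- list(cn, cn)
  structure(list(
    coefficients = beta,
    se = sqrt(pmax(diag(vcv), 0)),
    vcov = vcv,
    var_family = gam[1] * sigma2,
    var_slope = if (design$random_slope) gam[2] * sigma2 else NA_real_,
    sigma2 = sigma2,
    deviance = sol$deviance,
    logLik = -0.5 * sol$deviance,
    method = method,
    converged = converged,
    boundary = boundary,
    n = n, p = p, n_dropped = n_dropped,
    message = msg,
    random_slope = design$random_slope
  ), class = "wlmm_fit")
}

#' @export
print.wlmm_fit <- function(x, ...) {
  cat(sprintf("Weighted family mixed model (%s), n = %d rows\n", x$method, x$n))
  print(summary(x)$coefficients, digits = 4)
  cat(sprintf("Family intercept variance: %.5f", x$var_family))
  if (!is.na(x$var_slope)) cat(sprintf("; family age-slope variance: %.5f",
                                       x$var_slope))
  cat(sprintf("\nResidual variance: %.5f; logLik (%s): %.2f\n",
              x$sigma2, x$method, x$logLik))
  if (x$boundary) cat("Note: variance component on boundary (0)\n")
  invisible(x)
}

#' Summarize a weighted mixed-model fit
#'
#' @param object A `wlmm_fit`.
#' @param ... Unused.
#' @return List with a coefficient table (estimate, SE, Wald z, p) and the
#'   variance components.
#' @export
summary.wlmm_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(object$se),
                    z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))))
  list(coefficients = tab,
       var_family = object$var_family, var_slope = object$var_slope,
       sigma2 = object$sigma2, logLik = object$logLik, method = object$method)
}

#' Pseudo-R-squared for the polygenic score
#'
#' Proportional reduction in total model variance (family variance components
#' plus residual variance) when the polygenic score is added to the
#' covariate-only model. For a standardized outcome and predictor with
#' marginal effect beta this is approximately beta squared.
#'
#' @param fit_with_pgs,fit_without_pgs `wlmm_fit` objects on identical rows
#'   and weights, differing only by the polygenic-score column.
#' @return Scalar pseudo-R-squared (non-negative up to numerical slack).
#' @export
pseudo_r2 <- function(fit_with_pgs, fit_without_pgs) {
  stopifnot(inherits(fit_with_pgs, "wlmm_fit"),
            inherits(fit_without_pgs, "wlmm_fit"))
  if (fit_with_pgs$n != fit_without_pgs$n)
    stop("fits use different rows (n mismatch); pseudo-R2 undefined")
  if (!("pgs" %in% names(fit_with_pgs$coefficients)) ||
      "pgs" %in% names(fit_without_pgs$coefficients))
    stop("expected one fit with a 'pgs' column and one without")
  tot <- function(f) f$var_family +
    (if (is.na(f$var_slope)) 0 else f$var_slope) + f$sigma2
  (tot(fit_without_pgs) - tot(fit_with_pgs)) / tot(fit_without_pgs)
}
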