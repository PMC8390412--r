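#' Filter persons by missing-item count
#'
#' Keeps persons with at most `max_missing` missing items, the inclusion
#' rule applied before fitting the per-wave item response model.
#'
#' @param raw Persons x items matrix of ordinal responses (integers starting
#'   at 0; `NA` = missing). Row names identify persons.
#' @param max_missing Maximum missing items per retained person (default 2).
#' @return The filtered matrix, with attributes `n_retained` and `n_dropped`.
#' @export
filter_missing <- function(raw, max_missing = 2) {
  raw <- as.matrix(raw)
  if (nrow(raw) == 0L) stop("empty response matrix")
  nmiss <- rowSums(is.na(raw))
  keep <- nmiss <= max_missing
  out <- raw[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  if (any(!keep))
    message(sum(!keep), " person(s) dropped (> ", max_missing,
            " missing items); ", sum(keep), " retained")
  out
}

# log category probabilities for one GPCM item at the quadrature nodes:
# P(k | theta) proportional to exp(sum_{v <= k} a (theta - b_v)), k = 0..K-1.
# Returns a Q x K matrix of log probabilities.
gpcm_logprob <- function(a, b, nodes) {
  K <- length(b) + 1L
  s <- outer(a * nodes, 0:(K - 1)) -
    matrix(a * c(0, cumsum(b)), length(nodes), K, byrow = TRUE)
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  s - (m + log(rowSums(exp(s - m))))
}

# n x Q log-likelihood matrix of the observed responses under item params
gpcm_loglik_matrix <- function(resp, items, nodes) {
  n <- nrow(resp); Q <- length(nodes)
  LL <- matrix(0, n, Q)
  for (j in seq_along(items)) {
    lp <- t(gpcm_logprob(items[[j]]$a, items[[j]]$b, nodes))  # K x Q
    xj <- resp[, j]
    ok <- !is.na(xj)
    LL[ok, ] <- LL[ok, ] + lp[xj[ok] + 1L, , drop = FALSE]
  }
  LL
}

#' Fit a Generalized Partial Credit Model to one wave
#'
#' Marginal maximum likelihood via EM over a standard-normal latent trait
#' with a fixed quadrature grid. Each item has a discrimination `a` and
#' `K - 1` step parameters `b`; category probabilities are
#' `P(k | theta) proportional to exp(sum_{v <= k} a (theta - b_v))`. Missing
#' items contribute nothing to a person's likelihood (ignorable
#' missingness). The latent scale is identified by the standard-normal
#' prior; discrimination signs are anchored by flipping the solution
#' (`a -> -a`, `b -> -b`, an exact symmetry) if the first item's fitted
#' slope is negative.
#'
#' @param data Persons x items response matrix, integer categories from 0,
#'   `NA` allowed. Items observed in fewer than 2 categories are dropped
#'   with a warning; fewer than 2 usable items is an error.
#' @param n_quad Number of equally spaced quadrature nodes on `[-6, 6]`
#'   (default 61), with standard-normal weights.
#' @param tol EM stops when the marginal log-likelihood improves by less
#'   than this (default 1e-6).
#' @param max_iter Iteration cap (default 500); hitting it without
#'   convergence is an error carrying the log-likelihood trace.
#' @return An object of class `gpcm_model`: item parameters, quadrature
#'   specification, `loglik`, the per-iteration `trace`, `n_iter`.
#' @export
fit_gpcm <- function(data, n_quad = 61, tol = 1e-6, max_iter = 500) {
  resp <- as.matrix(data)
  if (is.null(colnames(resp))) colnames(resp) <- paste0("item", seq_len(ncol(resp)))
  ncat_obs <- apply(resp, 2, function(x) length(unique(x[!is.na(x)])))
  bad <- ncat_obs < 2
  if (any(bad)) {
    warning("dropping item(s) with a single observed category: ",
            paste(colnames(resp)[bad], collapse = ", "))
    resp <- resp[, !bad, drop = FALSE]
  }
  if (ncol(resp) < 2L)
    stop("need at least 2 items with >= 2 observed categories")
  if (any(resp[!is.na(resp)] < 0) || any(resp[!is.na(resp)] != round(resp[!is.na(resp)])))
    stop("responses must be non-negative integers (0-based categories)")
  n <- nrow(resp)
  ncat <- apply(resp, 2, max, na.rm = TRUE) + 1L

  nodes <- seq(-6, 6, length.out = n_quad)
  pw <- stats::dnorm(nodes); pw <- pw / sum(pw)
  lpw <- log(pw)

  items <- lapply(seq_len(ncol(resp)), function(j) {
    K <- ncat[j]
    list(a = 1, b = seq(-1, 1, length.out = K - 1))
  })
  names(items) <- colnames(resp)

  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    LL <- gpcm_loglik_matrix(resp, items, nodes)
    pu <- LL + matrix(lpw, n, n_quad, byrow = TRUE)
    m <- pu[cbind(seq_len(n), max.col(pu, ties.method = "first"))]
    lse <- m + log(rowSums(exp(pu - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      return(finish_gpcm(items, nodes, pw, ll, trace, it, n, resp))
    }
    ll_old <- ll
    post <- exp(pu - lse)
    # M-step: per-item maximization of the expected complete-data
    # log-likelihood, warm-started at the current parameters (keeps EM
    # monotone up to optimizer slack)
    for (j in seq_len(ncol(resp))) {
      K <- ncat[j]
      xj <- resp[, j]
      Rj <- matrix(0, K, n_quad)
      for (k in seq_len(K)) {
        rows <- which(!is.na(xj) & xj == (k - 1L))
        if (length(rows))
          Rj[k, ] <- colSums(post[rows, , drop = FALSE])
      }
      obj <- function(par)
        -sum(Rj * t(gpcm_logprob(par[1], par[-1], nodes)))
      cur <- c(items[[j]]$a, items[[j]]$b)
      opt <- stats::nlminb(cur, obj,
                           lower = c(-20, rep(-25, K - 1)),
                           upper = c(20, rep(25, K - 1)))
      if (opt$objective <= obj(cur)) {   # never accept a worse M-step
        items[[j]]$a <- opt$par[1]
        items[[j]]$b <- opt$par[-1]
      }
    }
  }
  stop("GPCM EM did not converge in ", max_iter,
       " iterations; log-likelihood trace (last 5): ",
       paste(format(utils::tail(trace, 5), digits = 10), collapse = ", "))
}

finish_gpcm <- function(items, nodes, pw, ll, trace, it, n, resp) {
  if (items[[1]]$a < 0)
    items <- lapply(items, function(im) list(a = -im$a, b = -im$b))
  structure(list(items = items, item_names = names(items),
                 ncat = vapply(items, function(im) length(im$b) + 1L, 1L),
                 nodes = nodes, prior = pw,
                 loglik = ll, trace = trace, n_iter = it,
                 converged = TRUE, n_persons = n),
            class = "gpcm_model")
}

#' @export
print.gpcm_model <- function(x, ...) {
  cat(sprintf("GPCM: %d items, %d persons, logLik %.2f (%d EM iterations)\n",
              length(x$items), x$n_persons, x$loglik, x$n_iter))
  a <- vapply(x$items, function(im) im$a, 1)
  cat("Discriminations:", paste(sprintf("%.2f", a), collapse = " "), "\n")
  invisible(x)
}

#' Expected-a-posteriori latent trait scores
#'
#' Scores each person as the posterior mean of the latent trait under the
#' fitted model and its standard-normal prior, evaluated on the model's
#' quadrature grid. Persons with missing items are scored on their observed
#' items only.
#'
#' @param model A fitted [fit_gpcm()] model.
#' @param data Response matrix with the model's items (columns matched by
#'   position; same category coding).
#' @return Data frame with `person` (row names or row index), `score`,
#'   `posterior_sd`.
#' @export
score_eap <- function(model, data) {
  stopifnot(inherits(model, "gpcm_model"))
  resp <- as.matrix(data)
  if (!is.null(colnames(resp)) && all(model$item_names %in% colnames(resp)))
    resp <- resp[, model$item_names, drop = FALSE]
  if (ncol(resp) != length(model$items))
    stop("response matrix has ", ncol(resp), " items; model has ",
         length(model$items))
  none <- rowSums(!is.na(resp)) == 0L
  if (any(none))
    stop("person(s) with zero observed items cannot be scored: rows ",
         paste(which(none), collapse = ", "))
  n <- nrow(resp); Q <- length(model$nodes)
  LL <- gpcm_loglik_matrix(resp, model$items, model$nodes)
  pu <- LL + matrix(log(model$prior), n, Q, byrow = TRUE)
  m <- pu[cbind(seq_len(n), max.col(pu, ties.method = "first"))]
  post <- exp(pu - (m + log(rowSums(exp(pu - m)))))
  sc <- as.numeric(post %*% model$nodes)
  v <- as.numeric(post %*% model$nodes^2) - sc^2
  data.frame(person = if (!is.null(rownames(resp))) rownames(resp)
             else seq_len(n),
             score = sc, posterior_sd = sqrt(pmax(v, 0)),
             stringsAsFactors = FALSE)
}

#' Score several waves of item responses
#'
#' Fits an independent Generalized Partial Credit Model per wave and scores
#' each retained person by EAP, so each score is relative to all other
#' participants in the same wave: systematic wave effects (shifted item
#' endorsement tied to a data-collection occasion) are filtered out and the
#' per-wave score mean sits near zero (exactly zero only up to EAP
#' shrinkage; the analysis pipeline standardizes downstream).
#'
#' @param tables Named list of response matrices, one per wave (names are
#'   the wave labels).
#' @param max_missing Per-person missing-item cap applied before fitting
#'   (default 2).
#' @param ... Passed to [fit_gpcm()].
#' @return Data frame with `person`, `wave`, `score`, `posterior_sd`,
#'   stacked over waves; fitted models in attribute `"models"`.
#' @export
score_waves <- function(tables, max_missing = 2, ...) {
  if (length(tables) == 0L) stop("need at least one wave")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("wave", seq_along(tables))
  models <- list()
  out <- lapply(names(tables), function(wv) {
    kept <- filter_missing(tables[[wv]], max_missing = max_missing)
    model <- fit_gpcm(kept, ...)
    models[[wv]] <<- model
    sc <- score_eap(model, kept)
    sc$wave <- wv
    sc[, c("person", "wave", "score", "posterior_sd")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "models") <- models
  res
}
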