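# Shared fixture builders. All randomness takes an explicit seed so tests
# are reproducible and order-independent.

# small standardized measure table via the package generator
make_data <- function(n_families = 120, seed = 1, ...) {
  sim <- simulate_measures(sim_config(n_families = n_families, ...),
                           seed = seed)
  standardize_measures(sim$data)
}

# hand-built measure table with explicit values (no generator involved)
hand_table <- function(n = 20, n_fam = 5, seed = 3) {
  set.seed(seed)
  data.frame(
    person = paste0("p", seq_len(n)),
    family = paste0("f", rep_len(seq_len(n_fam), n)),
    age = seq(15, 60, length.out = n),
    phenotype = rnorm(n),
    pgs = rnorm(n),
    sex = rep_len(0:1, n),
    array = rep_len(c("A", "A", "B"), n),   # period 3: not aliased with sex
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    pc4 = rnorm(n), pc5 = rnorm(n),
    stringsAsFactors = FALSE
  )
}

# independent dense-matrix GLS oracle: beta = (X' V^-1 X)^-1 X' V^-1 y with
# V = Z G Z' + sigma2 * diag(1/w), built explicitly (no Woodbury shortcuts)
dense_gls <- function(X, y, fam, w, fam_var, resid_var,
                      slope_var = 0, age = NULL) {
  Zi <- outer(fam, sort(unique(fam)), "==") * 1
  V <- fam_var * tcrossprod(Zi) + resid_var * diag(1 / w)
  if (slope_var > 0) {
    Zs <- Zi * age
    V <- V + slope_var * tcrossprod(Zs)
  }
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[, 1]
}

# independent dense -2 log profile likelihood in (fam_var, resid_var) for the
# brute-force grid maximizer (ML), used only on tiny instances
dense_neg2ll <- function(X, y, fam, w, fam_var, resid_var) {
  Zi <- outer(fam, sort(unique(fam)), "==") * 1
  V <- fam_var * tcrossprod(Zi) + resid_var * diag(1 / w)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  n * log(2 * pi) + determinant(V)$modulus[1] + t(r) %*% Vi %*% r
}
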