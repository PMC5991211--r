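# Shared in-code fixtures for the test suite.

# Tiny deterministic haplotype panel: 5 variants, hand-constructed so LD
# can be checked against a brute-force double loop.
toy_panel <- function() {
  hap <- rbind(
    c(1L, 1L, 0L, 0L, 1L),
    c(1L, 1L, 0L, 1L, 0L),
    c(0L, 0L, 1L, 0L, 1L),
    c(0L, 0L, 1L, 1L, 0L),
    c(1L, 1L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 1L, 1L),
    c(1L, 1L, 1L, 0L, 0L),
    c(0L, 0L, 0L, 1L, 1L))
  list(hap = hap, cm = c(0.00, 0.05, 0.30, 0.90, 2.50))
}

# Brute-force windowed LD score: O(n^2) double loop over all pairs.
brute_ld_scores <- function(hap, cm, window = 1) {
  n <- ncol(hap)
  sapply(seq_len(n), function(l) {
    tot <- 0
    for (v in seq_len(n)) {
      if (abs(cm[v] - cm[l]) <= window)
        tot <- tot + stats::cor(hap[, l], hap[, v])^2
    }
    tot
  })
}

# A small single-cluster GEE problem with identity-ish correlation,
# suitable for closed-form oracle comparisons.
single_cluster_problem <- function(n_obs = 50, seed = 42, R = NULL) {
  set.seed(seed)
  l <- sort(runif(n_obs, 1, 30))
  X <- cbind(1, l)
  beta0 <- c(1.1, 0.02)
  mu <- as.numeric(X %*% beta0)
  y <- (sqrt(mu) * rnorm(n_obs))^2
  if (is.null(R)) R <- diag(n_obs)
  list(problem = gee_problem(list(y), list(X), list(R)),
       y = y, X = X, beta0 = beta0)
}

# Independent oracle: iteratively reweighted GLS for the identity-link,
# variance-proportional-to-mu^2 model with fixed working correlation.
# Solves the same fixed point as the GEE by dense linear algebra.
irls_oracle <- function(y, X, R, beta_init, n_iter = 200, tol = 1e-12) {
  beta <- beta_init
  Rinv <- solve(R)
  for (k in seq_len(n_iter)) {
    mu <- as.numeric(X %*% beta)
    W <- diag(1 / mu) %*% Rinv %*% diag(1 / mu)
    beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

# Small synthetic LD landscape shared by several tests (cached per session).
small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sh <- synthetic_haplotypes(synthetic_ld_params(variants_per_cm = 60),
                                 region_cm = 3, seed = 314)
      r2 <- band_ld_matrix(sh$haplotypes, sh$cm)
      cache <<- list(sh = sh,
                     r2 = r2,
                     r = band_ld_matrix(sh$haplotypes, sh$cm, stat = "r"),
                     l2 = ld_scores_from_band(r2))
    }
    cache
  }
})
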