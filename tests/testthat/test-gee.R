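test_that("GEE objects match the symbolically expanded formulas", {
  set.seed(7)
  m <- 6
  l <- sort(runif(m, 1, 20))
  X <- cbind(1, l)
  A0 <- crossprod(matrix(rnorm(m * m), m))
  D0 <- diag(1 / sqrt(diag(A0)))
  R <- D0 %*% A0 %*% D0
  y <- rchisq(m, 1)
  pr <- gee_problem(list(y), list(X), list(R))
  beta <- c(1.2, 0.03)
  ob <- gee_objects(pr, beta)[[1]]
  mu <- 1.2 + 0.03 * l
  expect_equal(ob$mu, mu)
  expect_equal(ob$A, mu^2)
  # identity mean link: D_i = d mu / d beta = X_i
  expect_equal(ob$D, unname(X))
  # V = A^{1/2} R A^{1/2} via an independent dense expansion
  expect_equal(ob$V, diag(mu) %*% R %*% diag(mu), tolerance = 1e-12)
  # constant mean, identity R: V = c^2 I
  pr2 <- gee_problem(list(y), list(matrix(1, m, 1)), list(diag(m)))
  ob2 <- gee_objects(pr2, 2)[[1]]
  expect_equal(ob2$V, 4 * diag(m))
  expect_equal(ob2$mu, rep(2, m))
  expect_error(gee_objects(pr, c(-5, 0)), "inadmissible")
})

test_that("estimating function vanishes at exact data and reduces to LS", {
  sc <- single_cluster_problem()
  # y set exactly to mu(beta) -> g(beta) = 0
  mu <- as.numeric(sc$X %*% sc$beta0)
  pr0 <- gee_problem(list(mu), list(sc$X), list(diag(length(mu))))
  expect_equal(estimating_function(pr0, sc$beta0), c(0, 0), tolerance = 1e-10)
  # identity R and constant mean model: g is proportional to the normal
  # equations X'(y - X beta)
  m <- 20
  X <- matrix(1, m, 1)
  y <- rchisq(m, df = 2)
  pr <- gee_problem(list(y), list(X), list(diag(m)))
  b <- 1.7
  expect_equal(estimating_function(pr, b), sum(y - b) / b^2, tolerance = 1e-12)
  # dispersion factor cancels up to scale: g(phi) = g(1)/phi
  g1 <- estimating_function(pr0, c(1.2, 0.01))
  g2 <- estimating_function(pr0, c(1.2, 0.01), phi = 7)
  expect_equal(g2, g1 / 7, tolerance = 1e-12)
})

test_that("finite-difference Jacobian of g matches -H at an exact root", {
  sc <- single_cluster_problem(n_obs = 30, seed = 3)
  mu <- as.numeric(sc$X %*% sc$beta0)
  A0 <- crossprod(matrix(rnorm(900), 30)) / 30
  D0 <- diag(1 / sqrt(diag(A0)))
  R <- psd_repair(D0 %*% A0 %*% D0, floor = 1e-3)
  pr <- gee_problem(list(mu), list(sc$X), list(R))
  s <- polygee:::gee_score(pr, sc$beta0)
  eps <- 1e-6
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- eps
    J[, j] <- (estimating_function(pr, sc$beta0 + e) -
                 estimating_function(pr, sc$beta0 - e)) / (2 * eps)
  }
  # at y = mu the derivative of g is exactly -H (product-rule terms vanish)
  expect_equal(J, -s$H, tolerance = 1e-5 * max(abs(s$H)))
})

test_that("solver recovers an exact root and matches the IRLS-GLS oracle", {
  sc <- single_cluster_problem(n_obs = 40, seed = 12)
  # exact data: solution equals truth to machine precision
  mu <- as.numeric(sc$X %*% sc$beta0)
  pr0 <- gee_problem(list(mu), list(sc$X), list(diag(40)))
  fit0 <- gee_solve(pr0)
  expect_true(fit0$converged)
  expect_equal(fit0$beta, sc$beta0, tolerance = 1e-10)
  # noisy single cluster, non-trivial AR(1) working correlation:
  # agreement with the dense iteratively-reweighted GLS oracle to 1e-8
  R <- 0.5^abs(outer(1:40, 1:40, "-"))
  prn <- gee_problem(list(sc$y), list(sc$X), list(R))
  fitn <- gee_solve(prn)
  expect_true(fitn$converged)
  oracle <- irls_oracle(sc$y, sc$X, R, beta_init = c(mean(sc$y), 0))
  expect_equal(fitn$beta, oracle, tolerance = 1e-8)
  # and the solution really is a root of the estimating function
  expect_lt(max(abs(estimating_function(prn, fitn$beta))), 1e-6)
})

test_that("with identity R the GEE fixed point is 1/mu^2-weighted least squares", {
  sc <- single_cluster_problem(n_obs = 60, seed = 21)
  pr <- gee_problem(list(sc$y), list(sc$X), list(diag(60)))
  fit <- gee_solve(pr)
  mu_hat <- as.numeric(sc$X %*% fit$beta)
  wls <- lm.wfit(sc$X, sc$y, w = 1 / mu_hat^2)
  expect_equal(fit$beta, unname(wls$coefficients), tolerance = 1e-7)
})

test_that("sandwich reduces to the independence estimator and is invariant", {
  ls <- small_landscape()
  set.seed(33)
  z <- simulate_zscores(ls$r, ls$l2, beta1 = 1.1, beta2 = 0.02)
  fit <- polygee(z$chisq, ls$l2, ld = ls$r2)
  pr <- fit$problem
  # empty adjacency equals the plain cluster sandwich
  pr_no <- gee_problem(pr$y, pr$X, pr$R, adjacency = NULL)
  S_adj <- gee_sandwich(pr, fit$coefficients)
  S_ind <- gee_sandwich(pr_no, fit$coefficients)
  s <- polygee:::gee_score(pr, fit$coefficients)
  M_ind <- Reduce(`+`, lapply(s$gi, tcrossprod))
  Hi <- solve(s$H)
  expect_equal(S_ind, (Hi %*% M_ind %*% Hi + t(Hi %*% M_ind %*% Hi)) / 2,
               tolerance = 1e-10)
  expect_true(isSymmetric(S_adj))
  expect_gte(min(eigen(S_adj, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  # reversing the block order leaves the sandwich unchanged
  ord <- rev(seq_len(pr$n))
  adj_r <- cbind(pr$n + 1L - pr$adjacency[, 2], pr$n + 1L - pr$adjacency[, 1])
  pr_rev <- gee_problem(pr$y[ord], pr$X[ord], pr$R[ord], adjacency = adj_r)
  expect_equal(gee_sandwich(pr_rev, fit$coefficients), S_adj,
               tolerance = 1e-10)
})

test_that("dispersion behaves like a Pearson moment estimator", {
  sc <- single_cluster_problem(n_obs = 50, seed = 4)
  mu <- as.numeric(sc$X %*% sc$beta0)
  pr0 <- gee_problem(list(mu), list(sc$X), list(diag(50)))
  expect_equal(gee_dispersion(pr0, sc$beta0), 0)
  # squared centred normals with variance mu^2: phi -> 2
  set.seed(10)
  n <- 20000; mcl <- 100
  l <- rep(seq(1, 30, length.out = mcl), n / mcl)
  beta <- c(1, 0.02)
  mu <- 1 + 0.02 * l
  y <- (sqrt(mu) * rnorm(n))^2
  split_i <- rep(seq_len(n / mcl), each = mcl)
  pr <- gee_problem(split(y, split_i),
                    lapply(split(l, split_i), function(li) cbind(1, li)),
                    rep(list(diag(mcl)), n / mcl))
  expect_equal(gee_dispersion(pr, beta), 2, tolerance = 0.1)
  # scaling the noise by k scales phi by k^2
  y2 <- mu + 2 * (y - mu)
  ok <- y2 >= 0  # keep responses non-negative for the constructor
  pr_a <- gee_problem(list(y[ok][1:500]), list(cbind(1, l[ok][1:500])),
                      list(diag(500)))
  pr_b <- gee_problem(list(y2[ok][1:500]), list(cbind(1, l[ok][1:500])),
                      list(diag(500)))
  expect_equal(gee_dispersion(pr_b, beta), 4 * gee_dispersion(pr_a, beta),
               tolerance = 1e-10)
})

test_that("Wald statistic and p-value follow the chi-squared(1) reference", {
  Sigma <- diag(c(1e-4, 1e-4))
  expect_equal(wald_test(c(0, 0.5), Sigma, 1), list(W = 0, p = 1))
  w <- wald_test(c(0.02, 0), 1e-4 * diag(2), 1)
  expect_equal(w$W, 4)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(w$p, 0.04550026, tolerance = 1e-7)
  expect_error(wald_test(c(1, 1), matrix(0, 2, 2), 2), "variance")
})

test_that("the fitted model object supports the standard methods", {
  ls <- small_landscape()
  set.seed(77)
  z <- simulate_zscores(ls$r, ls$l2, beta1 = 1.1, beta2 = 0.05)
  fit <- polygee(z$chisq, ls$l2, ld = ls$r2)
  expect_s3_class(fit, "polygee")
  expect_named(coef(fit), c("beta1", "beta2"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_true(all(diag(vcov(fit, type = "model")) > 0))
  expect_equal(length(fitted(fit)), length(ls$l2))
  expect_equal(residuals(fit, type = "response"),
               z$chisq - fitted(fit), tolerance = 1e-10)
  expect_equal(predict(fit, newdata = c(1, 10)),
               coef(fit)[1] + c(1, 10) * coef(fit)[2], ignore_attr = TRUE)
  ci <- confint(fit)
  expect_true(ci["beta1", 1] < coef(fit)[1] && coef(fit)[1] < ci["beta1", 2])
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(length(ls$l2), 2))
  expect_true(all(sim >= 0))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("dispersion", out)))
  # JSON serialization carries the shared result schema
  f <- withr::local_tempfile(fileext = ".json")
  write_polygee_json(fit, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$estimator, "gee")
  expect_equal(j$beta$beta1, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_true(j$converged)
})

test_that("phi scaling of the variance function leaves the fit unchanged", {
  # multiplying all A_i by a constant rescales g and H identically, so
  # beta-hat and the sandwich are invariant
  sc <- single_cluster_problem(n_obs = 30, seed = 15)
  pr <- gee_problem(list(sc$y), list(sc$X), list(diag(30)))
  fit <- gee_solve(pr)
  g_scaled <- estimating_function(pr, fit$beta, phi = 5)
  expect_equal(g_scaled * 5, estimating_function(pr, fit$beta),
               tolerance = 1e-9)
  # root is the same regardless of phi
  expect_lt(max(abs(g_scaled)), 1e-6)
})
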