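#' Assemble a clustered GEE problem
#'
#' Groups responses, covariates and working correlations into the clustered
#' form the estimating equations operate on.  The marginal model is
#' gamma-type with identity mean link: `mu_ij = x_ij' beta`,
#' `Var(y_ij) = phi mu_ij^2`.  Clusters are statistically independent
#' except for pairs listed in `adjacency`, which enter the sandwich
#' variance cross-term.
#'
#' @param y List of numeric response vectors (chi-squared statistics), one
#'   per cluster.
#' @param X List of covariate matrices, one per cluster, `m_i` rows each;
#'   all with the same column count `p`.
#' @param R List of working-correlation matrices (positive definite, unit
#'   diagonal), dimensions matching `y`.
#' @param adjacency Two-column integer matrix of unordered correlated
#'   cluster pairs (e.g. [block_adjacency()]); `NULL` for none.
#' @return Object of class `"gee_problem"`.
#' @export
gee_problem <- function(y, X, R, adjacency = NULL) {
  stopifnot(is.list(y), is.list(X), is.list(R),
            length(y) == length(X), length(y) == length(R))
  m <- lengths(y)
  if (any(m < 1L)) stop("every cluster must contain at least one observation",
                        call. = FALSE)
  p <- unique(vapply(X, ncol, 0L))
  if (length(p) != 1L) stop("all clusters must share the covariate dimension",
                            call. = FALSE)
  X <- lapply(X, function(x) { dimnames(x) <- NULL; x })
  for (i in seq_along(y)) {
    if (nrow(X[[i]]) != m[i] || !all(dim(R[[i]]) == m[i]))
      stop("dimension mismatch in cluster ", i, call. = FALSE)
    if (any(y[[i]] < 0))
      stop("responses must be non-negative (squared statistics); cluster ", i,
           call. = FALSE)
  }
  if (is.null(adjacency))
    adjacency <- matrix(integer(0), ncol = 2L)
  adjacency <- as.matrix(adjacency)
  Rinv <- lapply(R, function(r) chol2inv(chol(r)))
  structure(list(y = y, X = X, R = R, Rinv = Rinv, adjacency = adjacency,
                 n = length(y), m = m, p = p),
            class = "gee_problem")
}

#' @export
print.gee_problem <- function(x, ...) {
  cat(sprintf("GEE problem: %d clusters, %d observations, %d covariate(s), %d correlated pair(s)\n",
              x$n, sum(x$m), x$p, nrow(x$adjacency)))
  invisible(x)
}

#' Per-cluster GEE objects at a parameter value
#'
#' Evaluates, for each cluster, the mean `mu_i = X_i beta`, the variance
#' diagonal `A_i = phi diag(mu_i^2)`, the derivative matrix
#' `D_i = d mu_i / d beta = X_i` (the product `A_i Delta_i` of the gamma
#' exponential-family representation is the identity under the linear mean
#' model) and the working covariance
#' `V_i = A_i^{1/2} R_i A_i^{1/2}`.
#'
#' @param problem A [gee_problem()].
#' @param beta Parameter vector (must be admissible: all means positive).
#' @param phi Dispersion factor carried through `A_i` and `V_i`; it cancels
#'   from the estimating equations, so estimation uses `phi = 1`.
#' @return List with one element per cluster: `mu`, `A` (vector of
#'   diagonal entries), `D`, `V`.
#' @export
gee_objects <- function(problem, beta, phi = 1) {
  stopifnot(inherits(problem, "gee_problem"))
  lapply(seq_len(problem$n), function(i) {
    mu <- as.numeric(problem$X[[i]] %*% beta)
    if (any(mu <= 0))
      stop("inadmissible beta: non-positive mean in cluster ", i, call. = FALSE)
    A <- phi * mu^2
    V <- sqrt(A) * t(sqrt(A) * problem$R[[i]])  # A^{1/2} R A^{1/2}
    list(mu = mu, A = A, D = problem$X[[i]], V = V)
  })
}

# Internal: g, per-cluster g_i and H at beta, using precomputed R inverses.
# Returns NULL if beta is inadmissible.
gee_score <- function(problem, beta, phi = 1) {
  p <- problem$p
  g <- numeric(p)
  H <- matrix(0, p, p)
  gi <- vector("list", problem$n)
  for (i in seq_len(problem$n)) {
    mu <- as.numeric(problem$X[[i]] %*% beta)
    if (any(mu <= 0)) return(NULL)
    Xs <- problem$X[[i]] / mu
    es <- (problem$y[[i]] - mu) / mu
    RiXs <- problem$Rinv[[i]] %*% Xs
    gi[[i]] <- as.numeric(crossprod(RiXs, es)) / phi
    g <- g + gi[[i]]
    H <- H + crossprod(Xs, RiXs) / phi
  }
  list(g = g, gi = gi, H = H)
}

#' Generalized estimating function
#'
#' `g_n(beta) = sum_i D_i' V_i^{-1} (y_i - mu_i(beta))`, the score whose
#' root defines the GEE estimator.
#'
#' @inheritParams gee_objects
#' @return Numeric vector of length `p`.
#' @export
estimating_function <- function(problem, beta, phi = 1) {
  stopifnot(inherits(problem, "gee_problem"))
  s <- gee_score(problem, beta, phi = phi)
  if (is.null(s))
    stop("inadmissible beta: some mean E[x2] <= 0", call. = FALSE)
  s$g
}

#' Solver control parameters
#'
#' @param tol Convergence tolerance on both `max|delta beta|` and
#'   `max|g_n|/n` (default `1e-8`).
#' @param max_iter Maximum Fisher-scoring iterations (default 100).
#' @param max_halvings Maximum step halvings per iteration when a step is
#'   inadmissible or fails to decrease `|g_n|` (default 30).
#' @return List of control values.
#' @export
polygee_control <- function(tol = 1e-8, max_iter = 100L, max_halvings = 30L) {
  stopifnot(tol > 0, max_iter >= 1, max_halvings >= 1)
  list(tol = tol, max_iter = max_iter, max_halvings = max_halvings)
}

#' Solve the generalized estimating equations
#'
#' Fisher-scoring (Newton-Raphson with the model-based derivative
#' `H_n = sum_i D_i' V_i^{-1} D_i`) with step halving: a step is halved
#' while it leaves the admissible region (some mean non-positive) or fails
#' to decrease the score norm.
#'
#' @param problem A [gee_problem()].
#' @param init Initial parameter vector; default: intercept at `mean(y)`
#'   (when the first covariate column is constant 1) and 0 elsewhere.
#' @param control A [polygee_control()] list.
#' @return List with `beta`, `H` (at the solution), `iterations`,
#'   `converged`, `g` (final score).
#' @export
gee_solve <- function(problem, init = NULL, control = polygee_control()) {
  stopifnot(inherits(problem, "gee_problem"))
  p <- problem$p
  yall <- unlist(problem$y)
  if (is.null(init)) {
    init <- numeric(p)
    ones <- vapply(problem$X, function(x) all(x[, 1] == 1), TRUE)
    init[1] <- if (all(ones)) mean(yall) else {
      # fall back to a positive constant fit through OLS on pooled data
      max(mean(yall), 1e-3)
    }
  }
  beta <- init
  s <- gee_score(problem, beta)
  if (is.null(s))
    stop("initial beta is inadmissible (non-positive mean)", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(s$H, s$g), error = function(e)
      stop("singular Fisher-scoring matrix H_n; covariates may be collinear",
           call. = FALSE))
    step <- 1
    gnorm <- max(abs(s$g))
    s_new <- NULL
    for (h in seq_len(control$max_halvings)) {
      cand <- beta + step * delta
      s_try <- gee_score(problem, cand)
      if (!is.null(s_try) &&
          (max(abs(s_try$g)) < gnorm || max(abs(step * delta)) < control$tol)) {
        s_new <- s_try
        break
      }
      step <- step / 2
    }
    if (is.null(s_new)) {  # no acceptable step found
      break
    }
    beta <- beta + step * delta
    s <- s_new
    if (max(abs(step * delta)) < control$tol ||
        max(abs(s$g)) / problem$n < control$tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, H = s$H, g = s$g, gi = s$gi, iterations = iter,
       converged = converged)
}

#' Sandwich covariance with correlated-cluster correction
#'
#' `Sigma_hat = H_n^{-1} M_hat_n H_n^{-1}` where
#' `M_hat_n = sum_i g_ni g_ni' + sum_(i,j adjacent) (g_ni g_nj' + g_nj g_ni')`.
#' The cross-term accounts for the residual correlation between genetically
#' adjacent clusters; with an empty adjacency set this is the classical
#' independence-cluster sandwich.
#'
#' @param problem A [gee_problem()] (its `adjacency` supplies the
#'   correlated pairs).
#' @param beta Parameter vector at which to evaluate (typically the
#'   solution from [gee_solve()]).
#' @return Symmetric covariance matrix for `beta`.
#' @export
gee_sandwich <- function(problem, beta) {
  stopifnot(inherits(problem, "gee_problem"))
  s <- gee_score(problem, beta)
  if (is.null(s)) stop("inadmissible beta", call. = FALSE)
  p <- problem$p
  M <- matrix(0, p, p)
  for (gi in s$gi) M <- M + tcrossprod(gi)
  if (nrow(problem$adjacency)) {
    for (r in seq_len(nrow(problem$adjacency))) {
      i <- problem$adjacency[r, 1]; j <- problem$adjacency[r, 2]
      cross <- tcrossprod(s$gi[[i]], s$gi[[j]])
      M <- M + cross + t(cross)
    }
    # the cross-terms can make M indefinite in finite samples; clip
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    if (min(e$values) < 0)
      M <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  }
  Hi <- tryCatch(solve(s$H), error = function(e)
    stop("singular H_n: covariate columns are collinear", call. = FALSE))
  Sigma <- Hi %*% M %*% Hi
  (Sigma + t(Sigma)) / 2
}

#' Pearson moment estimator of the dispersion
#'
#' `phi_hat = sum_ij ((y_ij - mu_ij)^2 / mu_ij^2) / (sum_i m_i - p)`.
#' Under normally distributed genetic effects the marginal model holds with
#' `phi = 2` (the squared-normal variance ratio); `phi` is treated as a
#' nuisance parameter and does not enter the point estimation.
#'
#' @inheritParams gee_sandwich
#' @return The scalar dispersion estimate.
#' @export
gee_dispersion <- function(problem, beta) {
  stopifnot(inherits(problem, "gee_problem"))
  num <- 0
  for (i in seq_len(problem$n)) {
    mu <- as.numeric(problem$X[[i]] %*% beta)
    num <- num + sum(((problem$y[[i]] - mu) / mu)^2)
  }
  num / (sum(problem$m) - problem$p)
}

#' Wald test of a single coordinate
#'
#' `W = beta_b^2 / Sigma_bb` referred to a chi-squared distribution with
#' one degree of freedom.
#'
#' @param beta Estimated parameter vector.
#' @param Sigma Its (sandwich) covariance matrix.
#' @param b Coordinate to test.
#' @return List with `W` and `p`.
#' @export
wald_test <- function(beta, Sigma, b) {
  v <- Sigma[b, b]
  if (!is.finite(v) || v <= 0)
    stop("non-positive variance for coordinate ", b, call. = FALSE)
  W <- beta[b]^2 / v
  list(W = as.numeric(W), p = stats::pchisq(W, df = 1, lower.tail = FALSE))
}

#' Fit the polygenic-effect marginal model by GEE
#'
#' Estimates the confounding intercept `beta1` and the polygenic slope
#' `beta2` of the marginal model
#' `E[x2_l] = beta1 + C_study l_l beta2`,
#' `Var(x2_l) = phi (E[x2_l])^2`
#' from genome-wide chi-squared association statistics.  Statistics are
#' grouped into 1 cM LD blocks; reference-panel `r^2` matrices serve as
#' working correlations; standard errors come from a sandwich estimator
#' with cross-terms for genetically adjacent blocks.
#'
#' Supply either `ld` (a band `r^2` matrix carrying the genetic
#' coordinates, from which blocks, working correlations and adjacency are
#' derived) or the pre-built `blocks`/`R`/`adjacency` triple.
#'
#' @param chisq Chi-squared association statistics, one per variant, in
#'   genomic order matching the LD input.
#' @param ld_score LD scores of the same variants.
#' @param ld Optional [band_ld_matrix()] with `stat = "r2"`.
#' @param blocks,R,adjacency Optional explicit clustering: a
#'   [partition_blocks()] result, a list of working-correlation matrices
#'   and an adjacency pair matrix.
#' @param design Optional [study_design()]; its [c_study()] constant scales
#'   the LD-score covariate.  Ignored when `C` is given.
#' @param C Design constant multiplying `l` (default 1, i.e. `beta2` is
#'   estimated on the scale of the supplied covariate).
#' @param shrink Shrinkage factor applied to the working correlations when
#'   they are built from `ld` (default 1).
#' @param block_cm Block length in cM when blocks are built from `ld`.
#' @param control A [polygee_control()].
#' @return An object of class `"polygee"` with components `coefficients`
#'   (`beta1`, `beta2`), `vcov` (sandwich), `vcov_model`
#'   (dispersion-scaled model-based `H^{-1}`), `phi`, `wald` (per-coefficient
#'   statistic and p-value), `iterations`, `converged`, `n_clusters`,
#'   `n_snps`, `C`, `fitted.values`, `residuals` (Pearson), and the
#'   underlying `problem`.  Methods: `print`, `summary`, `coef`, `vcov`,
#'   `fitted`, `residuals`, `predict`, `confint`, `simulate`.
#' @examples
#' set.seed(1)
#' sim <- synthetic_haplotypes(synthetic_ld_params(variants_per_cm = 40),
#'                             region_cm = 4, seed = 7)
#' r2 <- band_ld_matrix(sim$haplotypes, sim$cm)
#' l2 <- ld_scores_from_band(r2)
#' z <- simulate_zscores(band_ld_matrix(sim$haplotypes, sim$cm, stat = "r"),
#'                       l2, beta1 = 1, beta2 = 0.01, seed = 7)
#' fit <- polygee(z$chisq, l2, ld = r2)
#' coef(fit)
#' @export
polygee <- function(chisq, ld_score, ld = NULL, blocks = NULL, R = NULL,
                    adjacency = NULL, design = NULL, C = NULL, shrink = 1,
                    block_cm = 1, control = polygee_control()) {
  stopifnot(length(chisq) == length(ld_score))
  if (is.null(C))
    C <- if (is.null(design)) 1 else c_study(design)
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "band_ld"))
    if (ld$stat != "r2")
      stop("working correlations require an r^2 band LD matrix", call. = FALSE)
    if (length(ld$cm) != length(chisq))
      stop("LD matrix and statistics cover different variant sets", call. = FALSE)
    blocks <- partition_blocks(ld$cm, ld$chr, block_cm = block_cm)
    R <- working_correlations(ld, blocks, shrink = shrink)
    adjacency <- block_adjacency(blocks)
  }
  if (is.null(blocks) || is.null(R))
    stop("supply either `ld` or both `blocks` and `R`", call. = FALSE)
  idx <- lapply(blocks, `[[`, "index")
  y <- lapply(idx, function(i) chisq[i])
  X <- lapply(idx, function(i) cbind(1, C * ld_score[i]))
  problem <- gee_problem(y, X, R, adjacency = adjacency)
  sol <- gee_solve(problem, control = control)
  if (!sol$converged)
    warning("GEE solver did not converge in ", sol$iterations, " iterations",
            call. = FALSE)
  Sigma <- gee_sandwich(problem, sol$beta)
  phi <- gee_dispersion(problem, sol$beta)
  Hi <- solve(sol$H)
  cf <- sol$beta
  names(cf) <- c("beta1", "beta2")[seq_along(cf)]
  dimnames(Sigma) <- list(names(cf), names(cf))
  wald <- do.call(rbind, lapply(seq_along(cf), function(b) {
    wt <- wald_test(cf, Sigma, b)
    data.frame(coef = names(cf)[b], W = wt$W, p = wt$p)
  }))
  mu_all <- unlist(lapply(seq_along(y), function(i)
    as.numeric(X[[i]] %*% sol$beta)))
  y_all <- unlist(y)
  structure(list(coefficients = cf, vcov = Sigma,
                 vcov_model = phi * Hi, phi = phi, wald = wald,
                 iterations = sol$iterations, converged = sol$converged,
                 n_clusters = problem$n, n_snps = sum(problem$m), C = C,
                 fitted.values = mu_all,
                 residuals = (y_all - mu_all) / mu_all,
                 ld_score = ld_score, problem = problem,
                 call = match.call()),
            class = "polygee")
}

#' @export
print.polygee <- function(x, digits = 4, ...) {
  cat("Polygenic-effect GEE fit\n")
  cat(sprintf("  %d variants in %d LD blocks; converged: %s (%d iterations)\n",
              x$n_snps, x$n_clusters, x$converged, x$iterations))
  se <- sqrt(diag(x$vcov))
  out <- rbind(estimate = x$coefficients, `sandwich se` = se)
  print(signif(out, digits))
  cat(sprintf("  dispersion phi = %.4g\n", x$phi))
  invisible(x)
}

#' @export
summary.polygee <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(Estimate = object$coefficients, `Std. Error` = se,
                    W = object$wald$W, `Pr(>W)` = object$wald$p,
                    check.names = FALSE,
                    row.names = names(object$coefficients))
  structure(list(coefficients = tab, phi = object$phi,
                 n_snps = object$n_snps, n_clusters = object$n_clusters,
                 converged = object$converged, iterations = object$iterations,
                 call = object$call),
            class = "summary.polygee")
}

#' @export
print.summary.polygee <- function(x, digits = 4, ...) {
  cat("Polygenic-effect GEE fit\n\nCall: ")
  print(x$call)
  cat(sprintf("\n%d variants in %d LD blocks; dispersion phi = %.4g\n\n",
              x$n_snps, x$n_clusters, x$phi))
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  if (!x$converged) cat("\nWarning: solver did not converge\n")
  invisible(x)
}

#' @export
coef.polygee <- function(object, ...) object$coefficients

#' Covariance of the fitted coefficients
#' @param object A [polygee()] fit.
#' @param type `"sandwich"` (robust, default) or `"model"`
#'   (dispersion-scaled model-based `H^{-1}`, for diagnostics).
#' @param ... Unused.
#' @export
vcov.polygee <- function(object, type = c("sandwich", "model"), ...) {
  switch(match.arg(type), sandwich = object$vcov, model = object$vcov_model)
}

#' @export
fitted.polygee <- function(object, ...) object$fitted.values

#' @export
residuals.polygee <- function(object, type = c("pearson", "response"), ...) {
  switch(match.arg(type),
         pearson = object$residuals,
         response = object$residuals * object$fitted.values)
}

#' Predicted mean statistics at new LD scores
#' @param object A [polygee()] fit.
#' @param newdata Numeric vector of LD scores; default: the fitted ones.
#' @param ... Unused.
#' @export
predict.polygee <- function(object, newdata = NULL, ...) {
  l <- if (is.null(newdata)) object$ld_score else newdata
  mean_vector(object$coefficients[1], object$coefficients[2], object$C, l)
}

#' @export
confint.polygee <- function(object, parm = seq_along(object$coefficients),
                            level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out[parm, , drop = FALSE]
}

#' Parametric simulation from a fitted model
#'
#' Draws new chi-squared statistics block by block: per block, z-scores
#' with correlation `sqrt(R_i)` (elementwise, PSD-repaired) and marginal
#' variance equal to the fitted means, squared.  Cross-block correlation
#' is not reproduced.
#'
#' @param object A [polygee()] fit.
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one simulated chi-squared
#'   vector per column (rows in the fitted variant order).
#' @export
simulate.polygee <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- object$problem
  mu <- object$fitted.values
  offs <- c(0L, cumsum(pr$m))
  roots <- lapply(seq_len(pr$n), function(i) {
    Cz <- psd_repair(sqrt(abs(pr$R[[i]])))
    e <- eigen(Cz, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  out <- matrix(NA_real_, nrow = sum(pr$m), ncol = nsim)
  for (s in seq_len(nsim)) {
    for (i in seq_len(pr$n)) {
      rows <- (offs[i] + 1L):offs[i + 1L]
      z <- sqrt(mu[rows]) * as.numeric(roots[[i]] %*% stats::rnorm(pr$m[i]))
      out[rows, s] <- z^2
    }
  }
  as.data.frame(out)
}

#' Serialize a fit to JSON
#'
#' Writes the result schema shared by the GEE and WLS estimators:
#' coefficient estimates, sandwich and model-based standard errors,
#' dispersion, per-coefficient Wald tests and convergence diagnostics.
#'
#' @param fit A [polygee()] fit.
#' @param path Output path.
#' @export
write_polygee_json <- function(fit, path) {
  stopifnot(inherits(fit, "polygee"))
  out <- list(estimator = "gee",
              beta = as.list(fit$coefficients),
              se = as.list(stats::setNames(sqrt(diag(fit$vcov)),
                                           names(fit$coefficients))),
              se_model = as.list(stats::setNames(sqrt(diag(fit$vcov_model)),
                                                 names(fit$coefficients))),
              phi = fit$phi,
              wald = lapply(seq_len(nrow(fit$wald)), function(i)
                list(coef = fit$wald$coef[i], W = fit$wald$W[i],
                     p = fit$wald$p[i])),
              n_clusters = fit$n_clusters, n_snps = fit$n_snps,
              iterations = fit$iterations, converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
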