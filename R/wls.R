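#' Regression weights for the explicit LD Score regression estimator
#'
#' The comparator estimates the same mean model by weighted linear
#' regression with the product of two per-variant weight components:
#' a heteroscedasticity part `1 / (2 mu_l^2)` with
#' `mu_l = beta1 + C l_l beta2` evaluated at supplied (in simulations:
#' true) parameter values, and an overcounting part `1 / l_l^(win)`, the
#' reciprocal LD score of the variant restricted to the regression SNP
#' set.
#'
#' @param ld_score LD scores entering the covariate.
#' @param beta1,beta2 Parameter values for the heteroscedasticity part.
#' @param C Design constant (default 1).
#' @param ld_score_win LD scores restricted to the regression SNP set;
#'   defaults to `ld_score` (the sets coincide when every variant within
#'   the window is regressed on).
#' @return Object of class `"wls_weights"`: list with `w` (the product),
#'   `hetero`, `overcount`.
#' @export
wls_weights <- function(ld_score, beta1, beta2, C = 1,
                        ld_score_win = ld_score) {
  mu <- mean_vector(beta1, beta2, C, ld_score)
  if (any(ld_score_win < 1 - 1e-12))
    stop("window LD scores must be >= 1", call. = FALSE)
  hetero <- 1 / (2 * mu^2)
  overcount <- 1 / ld_score_win
  structure(list(w = hetero * overcount, hetero = hetero,
                 overcount = overcount),
            class = "wls_weights")
}

#' Explicit weighted-least-squares LD Score regression
#'
#' Closed-form weighted linear regression of the chi-squared statistics on
#' `[1, C l_l]`: `beta_hat = (X'WX)^{-1} X'Wy`.  This is the explicit
#' estimator of the LD Score regression model used for efficiency
#' benchmarking; its standard errors are obtained empirically over
#' independent replications, not by a jackknife.
#'
#' @param chisq Chi-squared statistics.
#' @param ld_score LD scores.
#' @param weights A [wls_weights()] object or a positive numeric vector.
#' @param C Design constant scaling the LD-score covariate (default 1).
#' @return Object of class `"polygee_wls"` with `coefficients`
#'   (`beta1`, `beta2`), `fitted.values`, `residuals`, `C`.
#' @export
wls_fit <- function(chisq, ld_score, weights, C = 1) {
  w <- if (inherits(weights, "wls_weights")) weights$w else as.numeric(weights)
  stopifnot(length(chisq) == length(ld_score), length(w) == length(chisq))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  X <- cbind(1, C * ld_score)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  if (rcond(XtWX) < 1e-14)
    stop("rank-deficient design: LD-score covariate is constant", call. = FALSE)
  beta <- as.numeric(solve(XtWX, XtW %*% chisq))
  names(beta) <- c("beta1", "beta2")
  mu <- as.numeric(X %*% beta)
  structure(list(coefficients = beta, fitted.values = mu,
                 residuals = chisq - mu, C = C, weights = w),
            class = "polygee_wls")
}

#' @export
print.polygee_wls <- function(x, digits = 4, ...) {
  cat("Explicit WLS LD Score regression fit\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.polygee_wls <- function(object, ...) object$coefficients

#' Feasible (iterated) weighted LD Score regression
#'
#' When the true parameters behind the heteroscedasticity weights are
#' unknown, they are replaced by fitted values: an unweighted (overcounting
#' only) fit seeds the parameters, then weights and estimates are iterated.
#' On large instances the estimate changes by far less than its standard
#' error between iterations.
#'
#' @inheritParams wls_fit
#' @param n_iter Number of reweighting iterations (default 3).
#' @return A `"polygee_wls"` fit (with attribute `"iterations"`).
#' @export
wls_fit_feasible <- function(chisq, ld_score, C = 1, n_iter = 3) {
  fit <- wls_fit(chisq, ld_score, 1 / ld_score, C = C)
  for (k in seq_len(n_iter)) {
    b <- fit$coefficients
    mu_ok <- b[1] + C * ld_score * b[2]
    if (any(mu_ok <= 0)) break  # keep the last admissible weighting
    w <- wls_weights(ld_score, b[1], b[2], C = C)
    fit <- wls_fit(chisq, ld_score, w, C = C)
  }
  attr(fit, "iterations") <- n_iter
  fit
}

#' Relative efficiency of two estimators
#'
#' `RE = 100 * var_ref / var_alt` per coordinate.  With the GEE variance
#' as `var_ref` and the WLS comparator as `var_alt`, values below 100
#' mean the GEE estimator is more efficient (needs proportionally fewer
#' observations for the same precision).
#'
#' @param var_ref,var_alt Per-coordinate variances from paired
#'   replications; all positive.
#' @return Percentage (vector if the inputs are vectors).
#' @export
relative_efficiency <- function(var_ref, var_alt) {
  if (any(var_ref <= 0) || any(var_alt <= 0))
    stop("variances must be positive", call. = FALSE)
  100 * var_ref / var_alt
}

#' @rdname write_polygee_json
#' @param beta,se Named estimates and empirical standard errors for the
#'   WLS comparator.
#' @export
write_wls_json <- function(beta, se, path) {
  out <- list(estimator = "wls", beta = as.list(beta), se = as.list(se))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
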