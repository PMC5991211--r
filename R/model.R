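#' Liability-threshold context for a dichotomous trait
#'
#' For a disease with prevalence `K`, the liability-threshold model places
#' the affection threshold at the `1 - K` quantile of a standard normal
#' liability.  The scaling factor `c = t / K`, where `t` is the standard
#' normal density at that quantile, converts relative-risk effect sizes to
#' the liability scale.
#'
#' @param K Disease prevalence, strictly between 0 and 1.
#' @return An object of class `"liability_context"`: a list with elements
#'   `K`, `t` (normal density at the `1 - K` quantile) and `c` (`t / K`).
#' @examples
#' ctx <- liability_context(0.01)
#' ctx$c  # about 2.665
#' @export
liability_context <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0 || K >= 1)
    stop("prevalence K must be a single number in (0, 1)", call. = FALSE)
  t <- stats::dnorm(stats::qnorm(1 - K))
  structure(list(K = K, t = t, c = t / K), class = "liability_context")
}

#' @export
print.liability_context <- function(x, ...) {
  cat(sprintf("Liability-threshold context: K = %g, t = %.6g, c = %.6g\n",
              x$K, x$t, x$c))
  invisible(x)
}

#' Liability-scale variance explained by a causal variant
#'
#' Under a multiplicative relative-risk model, a causal variant with minor
#' allele frequency `p` and relative risk `lambda` explains approximately
#' `q^2 = 2 p (1 - p) (lambda - 1)^2 / c^2` of the phenotypic variance on
#' the liability scale, with `c` from [liability_context()].
#'
#' @param p Minor allele frequency, in (0, 0.5].
#' @param lambda Relative risk of the minor allele, positive.
#' @param ctx A [liability_context()].
#' @return The explained variance fraction `q^2` (non-negative; zero iff
#'   `lambda = 1`).
#' @export
explained_variance <- function(p, lambda, ctx) {
  stopifnot(inherits(ctx, "liability_context"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 0.5))
    stop("minor allele frequency p must lie in (0, 0.5]", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("relative risk lambda must be positive", call. = FALSE)
  2 * p * (1 - p) * (lambda - 1)^2 / ctx$c^2
}

#' Describe an association study design
#'
#' Collects the a-priori known study parameters that determine the constant
#' `C_study` in the marginal mean model `E[x2_l] = beta1 + C_study l_l beta2`.
#' Supported designs: population-based case-control and quantitative-trait
#' studies of unrelated individuals, family-based case-control studies
#' tested with the FBAT statistic, and weighted mixtures of such designs.
#'
#' For a family design, `N` counts nuclear families (all of the same type,
#' `n_a` affected and `n_u` unaffected offspring with parental genotypes),
#' and `z` is the FBAT offset.  Mixtures are built with [mixture_design()].
#'
#' @param kind One of `"case_control"`, `"quantitative"`, `"family"`.
#' @param N Sample size: individuals (population designs) or families.
#' @param M Number of common SNPs (MAF above 5 percent) used to scale the
#'   per-SNP heritability `h^2 / M`.
#' @param n_cases,n_controls Case and control counts (`case_control` only;
#'   must sum to `N`).
#' @param K Disease prevalence (`case_control` and `family`).
#' @param z FBAT offset in `[0, 1]` (`family` only).
#' @param n_a,n_u Affected / unaffected offspring per family (`family` only).
#' @return An object of class `"study_design"`.
#' @seealso [c_study()], [mixture_design()], [read_study_design()]
#' @examples
#' study_design("quantitative", N = 10000, M = 1e6)
#' study_design("case_control", N = 10000, n_cases = 5000,
#'              n_controls = 5000, K = 0.01, M = 1e6)
#' study_design("family", N = 2359, K = 0.01, M = 1e6,
#'              z = 0, n_a = 1, n_u = 0)  # affected-offspring trios
#' @export
study_design <- function(kind = c("case_control", "quantitative", "family"),
                         N, M, n_cases = NULL, n_controls = NULL, K = NULL,
                         z = NULL, n_a = NULL, n_u = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(N) || N <= 0) stop("N must be positive", call. = FALSE)
  if (!is.numeric(M) || M <= 0) stop("M must be positive", call. = FALSE)
  d <- list(kind = kind, N = N, M = M)
  if (kind == "case_control") {
    if (is.null(n_cases) || is.null(n_controls) || is.null(K))
      stop("case_control design needs n_cases, n_controls and K", call. = FALSE)
    if (abs(n_cases + n_controls - N) > 1e-8)
      stop("n_cases + n_controls must equal N", call. = FALSE)
    d$n_cases <- n_cases; d$n_controls <- n_controls
    d$K <- liability_context(K)$K
  } else if (kind == "family") {
    if (is.null(K) || is.null(z) || is.null(n_a) || is.null(n_u))
      stop("family design needs K, z, n_a and n_u", call. = FALSE)
    if (z < 0 || z > 1) stop("FBAT offset z must lie in [0, 1]", call. = FALSE)
    if (n_a < 0 || n_u < 0) stop("offspring counts must be non-negative", call. = FALSE)
    if ((1 - z)^2 * n_a + z^2 * n_u <= 0)
      stop("degenerate family design: (1-z)^2 n_a + z^2 n_u must be positive",
           call. = FALSE)
    d$K <- liability_context(K)$K
    d$z <- z; d$n_a <- n_a; d$n_u <- n_u
  }
  structure(d, class = "study_design")
}

#' Combine study designs into a mixture
#'
#' A meta-analysis combining population-based and family-based designs has
#' `C_study` equal to a weighted sum of the component constants.  By default
#' each component is weighted by its share of the total sample size
#' (`w_j` proportional to `N_j`); supply `weights` to override.
#'
#' @param components List of [study_design()] objects.
#' @param weights Optional numeric weights, one per component; normalised to
#'   sum to one.  Default: proportional to the component sample sizes.
#' @return A `"study_design"` of kind `"mixture"`.
#' @export
mixture_design <- function(components, weights = NULL) {
  if (!length(components) || !all(vapply(components, inherits, TRUE, "study_design")))
    stop("components must be a non-empty list of study_design objects", call. = FALSE)
  if (is.null(weights))
    weights <- vapply(components, `[[`, 0, "N")
  if (length(weights) != length(components) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative, one per component, with positive sum",
         call. = FALSE)
  structure(list(kind = "mixture", components = components,
                 weights = weights / sum(weights)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  if (x$kind == "mixture") {
    cat(sprintf("Mixed study design (%d components):\n", length(x$components)))
    for (i in seq_along(x$components))
      cat(sprintf("  [%d] weight %.3f: %s, N = %g\n", i, x$weights[i],
                  x$components[[i]]$kind, x$components[[i]]$N))
  } else {
    cat(sprintf("Study design: %s, N = %g, M = %g\n", x$kind, x$N, x$M))
  }
  invisible(x)
}

#' Design constant of the marginal mean model
#'
#' Computes `C_study`, the per-variant slope multiplier that converts the
#' polygenic term `beta2 = h^2` into the expected inflation of the study's
#' association test statistics:
#' \itemize{
#'   \item case-control: `n_cases n_controls c^2 / ((1-K)^2 N M)`
#'   \item quantitative: `N / M`
#'   \item family (FBAT, offset `z`):
#'     `c^2 (N/2) ((1-z) n_a + z K/(1-K) n_u)^2 /
#'      (((1-z)^2 n_a + z^2 n_u) M)`
#'   \item mixture: the weighted sum of the component constants.
#' }
#'
#' @param design A [study_design()].
#' @return The scalar `C_study`.
#' @examples
#' c_study(study_design("quantitative", N = 10000, M = 1e6))  # 0.01
#' @export
c_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  switch(design$kind,
    quantitative = design$N / design$M,
    case_control = {
      c2 <- liability_context(design$K)$c^2
      design$n_cases * design$n_controls * c2 /
        ((1 - design$K)^2 * design$N * design$M)
    },
    family = {
      c2 <- liability_context(design$K)$c^2
      num <- ((1 - design$z) * design$n_a +
                design$z * design$K / (1 - design$K) * design$n_u)^2
      den <- (1 - design$z)^2 * design$n_a + design$z^2 * design$n_u
      c2 * (design$N / 2) * num / den / design$M
    },
    mixture = sum(design$weights * vapply(design$components, c_study, 0)),
    stop("unknown design kind: ", design$kind, call. = FALSE)
  )
}

#' Marginal mean of the association test statistics
#'
#' Evaluates `mu_l = beta1 + C * l_l * beta2` for a vector of LD scores.
#' Every mean must be positive for the gamma-type variance model
#' `Var(x2_l) = phi mu_l^2` to make sense; non-positive means signal an
#' inadmissible parameter vector.
#'
#' @param beta1 Intercept (houses `1 + N a`, the stratification term).
#' @param beta2 Polygenic slope (houses `h^2`; the per-SNP scaling `1/M`
#'   lives inside `C`).
#' @param C Design constant from [c_study()] (use 1 for pre-scaled
#'   covariates).
#' @param l LD scores, each at least 1 (a variant's LD score includes its
#'   self-correlation).
#' @return Numeric vector of means, all positive.
#' @export
mean_vector <- function(beta1, beta2, C, l) {
  if (any(l < 1 - 1e-12))
    stop("LD scores must be >= 1 (they include the self r^2)", call. = FALSE)
  mu <- beta1 + C * l * beta2
  if (any(mu <= 0))
    stop("inadmissible parameters: some mean E[x2_l] <= 0", call. = FALSE)
  mu
}

#' Read a study design from a key = value configuration file
#'
#' Plain-text format: one `key = value` pair per line, `#` comments allowed.
#' A mixture is written as a `kind = mixture` header followed by
#' `[component]` sections, each holding a complete single-design block plus
#' an optional `weight`.  If any weight is given all components must carry
#' one; otherwise weights default to the component sample sizes.
#'
#' @param path Path to the configuration file.
#' @return A [study_design()].
#' @export
read_study_design <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- cumsum(grepl("^\\[", lines))
  parse_kv <- function(ls) {
    kv <- strsplit(ls, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed design config line: ", ls[bad][1], call. = FALSE)
    vals <- trimws(vapply(kv, `[[`, "", 2L))
    names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
    as.list(vals)
  }
  build <- function(kv) {
    num <- function(k) if (is.null(kv[[k]])) NULL else as.numeric(kv[[k]])
    study_design(kind = kv$kind, N = num("N"), M = num("M"),
                 n_cases = num("n_cases"), n_controls = num("n_controls"),
                 K = num("K"), z = num("z"), n_a = num("n_a"), n_u = num("n_u"))
  }
  head_kv <- parse_kv(lines[sec == 0 & !grepl("^\\[", lines)])
  if (identical(head_kv$kind, "mixture")) {
    comps <- list(); wts <- numeric(0)
    for (s in setdiff(unique(sec), 0)) {
      body <- lines[sec == s & !grepl("^\\[", lines)]
      kv <- parse_kv(body)
      comps[[length(comps) + 1L]] <- build(kv)
      wts <- c(wts, if (is.null(kv$weight)) NA_real_ else as.numeric(kv$weight))
    }
    if (all(is.na(wts))) wts <- NULL
    else if (anyNA(wts))
      stop("either all mixture components carry a weight or none does",
           call. = FALSE)
    mixture_design(comps, weights = wts)
  } else {
    build(head_kv)
  }
}
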