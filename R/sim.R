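#' Parameters of the synthetic mosaic-haplotype generator
#'
#' The generator builds a reference-panel stand-in with a banded, distance-
#' decaying LD structure: each output haplotype is a mosaic of a small
#' founder pool, switching founders along the genetic coordinate at
#' exponentially distributed distances, with per-site allele flips.
#' Variants closer than a segment length tend to be copied from the same
#' founder and are therefore correlated; LD decays towards zero around
#' 1 cM.  It replaces a real phased panel in tests and simulations and is
#' labelled synthetic throughout.
#'
#' @param n_hap Number of output haplotypes (default 200, the order of a
#'   reference-panel subpopulation).
#' @param n_founders Founder-pool size (default 6; smaller pools give
#'   stronger short-range LD, comparable to the r^2 levels seen between
#'   nearby common variants in European reference panels).
#' @param segment_cm Mean copied-segment length in cM (default 0.5).
#' @param flip_rate Per-site, per-haplotype allele flip probability
#'   (default 0.03; the flip noise keeps the panel's correlation matrices
#'   away from exact low-rank degeneracy, as finite real panels are).
#' @param variants_per_cm Variant density (default 100).
#' @param maf_min Minimum panel MAF; rarer variants are rejected
#'   (default 0.05, the common-variant convention).
#' @return List of class `"synthetic_ld_params"`.
#' @export
synthetic_ld_params <- function(n_hap = 200, n_founders = 6, segment_cm = 0.5,
                                flip_rate = 0.03, variants_per_cm = 100,
                                maf_min = 0.05) {
  stopifnot(n_hap >= 2, n_founders >= 2, segment_cm > 0, flip_rate >= 0,
            flip_rate < 0.5, variants_per_cm > 0, maf_min >= 0, maf_min < 0.5)
  structure(list(n_hap = n_hap, n_founders = n_founders,
                 segment_cm = segment_cm, flip_rate = flip_rate,
                 variants_per_cm = variants_per_cm, maf_min = maf_min),
            class = "synthetic_ld_params")
}

#' Generate synthetic phased haplotypes with banded LD
#'
#' Copying-mosaic construction (see [synthetic_ld_params()]): founder
#' haplotypes carry independent Bernoulli alleles with variant-specific
#' frequencies; output haplotypes copy founder segments whose boundaries
#' follow a Poisson process along the genetic map, then sites flip with a
#' small probability.  Variants whose realised MAF falls below the floor
#' are rejected, so the returned matrix is free of (near-)monomorphic
#' columns.
#'
#' @param params A [synthetic_ld_params()] object.
#' @param region_cm Length of the region in cM.
#' @param seed Optional integer seed.
#' @param chr Chromosome label for the map track (default `"1"`).
#' @return List with `haplotypes` (0/1 matrix, haplotypes x variants),
#'   `cm` (sorted genetic positions), `map` (a `genetic_map` data frame
#'   with bp positions at 1 Mb per cM).
#' @export
synthetic_haplotypes <- function(params = synthetic_ld_params(), region_cm,
                                 seed = NULL, chr = "1") {
  stopifnot(inherits(params, "synthetic_ld_params"), region_cm > 0)
  if (!is.null(seed)) set.seed(seed)
  n_var <- max(2L, round(params$variants_per_cm * region_cm))
  cm <- sort(stats::runif(n_var, 0, region_cm))
  freq <- stats::runif(n_var, 0.1, 0.9)
  founders <- matrix(stats::rbinom(params$n_founders * n_var, 1L,
                                   rep(freq, each = params$n_founders)),
                     nrow = params$n_founders)
  hap <- matrix(0L, nrow = params$n_hap, ncol = n_var)
  for (h in seq_len(params$n_hap)) {
    n_br <- stats::rpois(1L, region_cm / params$segment_cm)
    breaks <- sort(stats::runif(n_br, 0, region_cm))
    seg <- findInterval(cm, breaks) + 1L
    fid <- sample.int(params$n_founders, n_br + 1L, replace = TRUE)
    hap[h, ] <- founders[cbind(fid[seg], seq_len(n_var))]
  }
  if (params$flip_rate > 0) {
    flips <- matrix(stats::rbinom(length(hap), 1L, params$flip_rate),
                    nrow = nrow(hap))
    hap <- (hap + flips) %% 2L
  }
  maf <- colMeans(hap); maf <- pmin(maf, 1 - maf)
  keep <- maf >= params$maf_min
  if (!any(keep)) stop("no variant passed the MAF floor; relax maf_min",
                       call. = FALSE)
  hap <- hap[, keep, drop = FALSE]
  cm <- cm[keep]
  map <- data.frame(chr = chr, bp = round(cm * 1e6) + 1, cm = cm)
  class(map) <- c("genetic_map", "data.frame")
  list(haplotypes = hap, cm = cm, map = map)
}

#' Square root of a band LD correlation matrix
#'
#' Eigen-decomposition square root of the (PSD-repaired) dense correlation
#' matrix of a band LD object; the expensive half of z-score simulation,
#' exposed so replication loops can compute it once.
#'
#' @param ld A [band_ld_matrix()].  `stat = "r"` is used as the signed
#'   z-score correlation directly; for `stat = "r2"` the elementwise
#'   square root (`|r|`) is used.
#' @return Dense symmetric matrix `Q` with `Q Q' =` repaired correlation.
#' @export
ld_correlation_root <- function(ld) {
  stopifnot(inherits(ld, "band_ld"))
  Cz <- as.matrix(ld$mat)
  if (ld$stat == "r2") Cz <- sqrt(Cz)
  diag(Cz) <- 1
  Cz <- psd_repair(Cz)
  e <- eigen(Cz, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate association z-scores under the marginal model
#'
#' Draws mean-zero normal z-scores whose correlation matrix is the
#' (band-truncated, PSD-repaired) LD matrix and whose marginal variances
#' are `beta1 + C l_l beta2`.  The squared scores then follow the
#' gamma-type marginal model with dispersion 2 and squared-statistic
#' correlation `r^2`.
#'
#' @param ld A [band_ld_matrix()] for one region (see
#'   [ld_correlation_root()] for the statistic handling).
#' @param ld_score LD scores of the same variants.
#' @param beta1,beta2 True model parameters.
#' @param C Design constant (default 1).
#' @param seed Optional integer seed.
#' @param root Optional precomputed [ld_correlation_root()].
#' @return List with `z` and `chisq = z^2`.
#' @export
simulate_zscores <- function(ld, ld_score, beta1, beta2, C = 1, seed = NULL,
                             root = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root)) root <- ld_correlation_root(ld)
  stopifnot(length(ld_score) == nrow(root))
  sd <- sqrt(mean_vector(beta1, beta2, C, ld_score))
  z <- sd * as.numeric(root %*% stats::rnorm(nrow(root)))
  list(z = z, chisq = z^2)
}

#' Simulation configuration
#'
#' Describes a replication study: the true parameters, the synthetic
#' genome geometry (independent regions, each with its own LD structure,
#' optionally repeated as independent draws to mimic genome-scale data),
#' the working-correlation scenarios and the replication count.
#'
#' @param beta1,beta2 True intercept and polygenic slope (defaults 1.02
#'   and 5e-4, a scenario from the evaluated parameter grid).
#' @param n_regions Number of independent LD regions (default 5).
#' @param region_cm Region length in cM (default 5).
#' @param draws Independent repeats of the whole region set (default 1).
#' @param shrink Shrinkage factor(s) for the working-correlation
#'   scenarios; each value yields one fitted scenario per replication
#'   (default `c(1, 0.64)`: correctly specified and strongly shrunk).
#' @param replications Number of replications (default 500).
#' @param seed Integer seed (default 1).
#' @param ld_params [synthetic_ld_params()] for the haplotype generator.
#' @param C Design constant used in generation and fitting (default 1;
#'   the slope is then the polygenic term itself).
#' @return List of class `"sim_config"`.
#' @seealso [simulation_preset()] for named geometries.
#' @export
sim_config <- function(beta1 = 1.02, beta2 = 5e-4, n_regions = 5,
                       region_cm = 5, draws = 1, shrink = c(1, 0.64),
                       replications = 500, seed = 1,
                       ld_params = synthetic_ld_params(), C = 1) {
  stopifnot(replications >= 1, all(shrink >= 0), all(shrink <= 1),
            n_regions >= 1, region_cm > 0, draws >= 1)
  structure(list(beta1 = beta1, beta2 = beta2, n_regions = n_regions,
                 region_cm = region_cm, draws = draws, shrink = shrink,
                 replications = replications, seed = seed,
                 ld_params = ld_params, C = C),
            class = "sim_config")
}

#' Named simulation geometries
#'
#' `"desk"`: the default reduced geometry (5 regions of 5 cM at 100
#' variants per cM, one draw, 500 replications) that runs in minutes.
#' `"null"`: `beta2 = 0` with sixteen independent draws of the desk
#' region set (400 clusters) and 1,000 replications, for size calibration
#' of the Wald test -- the cluster count is chosen large enough that the
#' chi-squared(1) limit of the test statistic is a usable approximation,
#' which it is not at a handful of clusters.
#' `"genome"`: the genome-scale geometry of the original evaluation
#' design -- 11 regions of 25 cM, about 62,500 variants, 13 independent
#' draws (about 812,500 statistics) and 1,000 replications; intended for
#' cluster-scale runs, not routine testing.
#'
#' @param name One of `"desk"`, `"null"`, `"genome"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
simulation_preset <- function(name = c("desk", "null", "genome"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    desk = list(),
    null = list(beta2 = 0, draws = 16, replications = 1000, shrink = 1),
    genome = list(n_regions = 11, region_cm = 25, draws = 13,
                  replications = 1000,
                  ld_params = synthetic_ld_params(variants_per_cm = 227)))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Run a replication study
#'
#' Generates one synthetic LD landscape (haplotypes, band LD matrices, LD
#' scores, 1 cM blocks), then repeatedly draws z-scores under the marginal
#' model and fits, for every working-correlation scenario in
#' `config$shrink`, the GEE estimator with its sandwich standard errors,
#' plus the explicit WLS LD Score regression comparator with
#' true-parameter heteroscedasticity weights.  The same draws feed every
#' scenario and the comparator, so the efficiency comparison is paired.
#'
#' @param config A [sim_config()].
#' @param progress Print a dot every 50 replications (default `FALSE`).
#' @return Object of class `"replication_study"`: list with `config`,
#'   `estimates` (one row per replication x scenario x estimator, with
#'   estimates, sandwich SEs where applicable, convergence flag),
#'   `summary` (per scenario and coordinate: mean estimate, empirical SE,
#'   mean estimated SE, relative efficiency vs WLS), `n_nonconverged`,
#'   `n_snps`, `n_blocks`.  Identical seeds give identical results.
#' @export
replication_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # --- fixed LD landscape -------------------------------------------------
  # The z-score correlation of each region is the PSD-repaired band-
  # truncated signed-r matrix of the synthetic panel; the squared
  # statistics then have correlation equal to its elementwise square, so
  # that matrix (masked back to the 1 cM band) is both the working r^2
  # source for the full-information scenario and the LD-score source --
  # generation and fitting see one self-consistent marginal model.
  regions <- lapply(seq_len(config$n_regions), function(r)
    synthetic_haplotypes(config$ld_params, config$region_cm))
  band_r <- lapply(regions, function(rg)
    band_ld_matrix(rg$haplotypes, rg$cm, stat = "r",
                   maf_min = config$ld_params$maf_min))
  corr_z <- lapply(band_r, function(b) psd_repair(as.matrix(b$mat)))
  roots <- lapply(corr_z, function(Cz) {
    e <- eigen(Cz, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  band_r2 <- lapply(seq_along(band_r), function(r) {
    cmr <- band_r[[r]]$cm
    W <- corr_z[[r]]^2
    W[abs(outer(cmr, cmr, "-")) > band_r[[r]]$cutoff_cm] <- 0
    structure(list(mat = methods::as(Matrix::Matrix(W, sparse = TRUE),
                                     "symmetricMatrix"),
                   cm = cmr, chr = band_r[[r]]$chr,
                   cutoff_cm = band_r[[r]]$cutoff_cm, stat = "r2",
                   keep = band_r[[r]]$keep),
              class = "band_ld")
  })
  l_region <- lapply(band_r2, ld_scores_from_band)
  m_region <- vapply(l_region, length, 0L)
  # global layout: draws x regions, each copy on its own pseudo-chromosome
  copies <- expand.grid(region = seq_len(config$n_regions),
                        draw = seq_len(config$draws))
  global_cm <- unlist(lapply(seq_len(nrow(copies)),
                             function(k) band_r2[[copies$region[k]]]$cm))
  global_chr <- unlist(lapply(seq_len(nrow(copies)), function(k)
    rep(sprintf("r%d_d%d", copies$region[k], copies$draw[k]),
        m_region[copies$region[k]])))
  global_l <- unlist(l_region[copies$region])
  global_mat <- Matrix::bdiag(lapply(copies$region, function(r) band_r2[[r]]$mat))
  global_band <- structure(list(mat = global_mat, cm = global_cm,
                                chr = global_chr, cutoff_cm = band_r2[[1]]$cutoff_cm,
                                stat = "r2", keep = seq_along(global_cm)),
                           class = "band_ld")
  blocks <- partition_blocks(global_cm, global_chr)
  adj <- block_adjacency(blocks)
  idx <- lapply(blocks, `[[`, "index")
  Xb <- lapply(idx, function(i) cbind(1, config$C * global_l[i]))
  problems <- lapply(config$shrink, function(s) {
    R <- working_correlations(global_band, blocks, shrink = s)
    gee_problem(lapply(idx, function(i) rep(1, length(i))), Xb, R,
                adjacency = adj)
  })
  w_true <- wls_weights(global_l, config$beta1, config$beta2, C = config$C)
  sd_region <- lapply(l_region, function(l)
    sqrt(mean_vector(config$beta1, config$beta2, config$C, l)))
  # --- replications -------------------------------------------------------
  rows <- vector("list", config$replications * (length(config$shrink) + 1L))
  ri <- 0L
  n_nonconv <- 0L
  for (rep_i in seq_len(config$replications)) {
    chisq <- unlist(lapply(seq_len(nrow(copies)), function(k) {
      r <- copies$region[k]
      z <- sd_region[[r]] * as.numeric(roots[[r]] %*% stats::rnorm(m_region[r]))
      z^2
    }))
    yb <- lapply(idx, function(i) chisq[i])
    for (si in seq_along(config$shrink)) {
      pr <- problems[[si]]
      pr$y <- yb
      fit <- tryCatch(gee_solve(pr), error = function(e) NULL)
      ok <- !is.null(fit) && fit$converged
      if (!ok) n_nonconv <- n_nonconv + 1L
      se <- c(NA_real_, NA_real_)
      est <- c(NA_real_, NA_real_)
      if (!is.null(fit)) {
        est <- fit$beta
        if (ok) se <- sqrt(diag(gee_sandwich(pr, fit$beta)))
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(rep = rep_i, estimator = "gee",
                               shrink = config$shrink[si],
                               beta1 = est[1], beta2 = est[2],
                               se1 = se[1], se2 = se[2], converged = ok)
    }
    wf <- wls_fit(chisq, global_l, w_true, C = config$C)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(rep = rep_i, estimator = "wls", shrink = NA_real_,
                             beta1 = wf$coefficients[1],
                             beta2 = wf$coefficients[2],
                             se1 = NA_real_, se2 = NA_real_, converged = TRUE)
    if (progress && rep_i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  res <- structure(list(config = config, estimates = estimates,
                        n_nonconverged = n_nonconv,
                        n_snps = length(global_l), n_blocks = length(blocks)),
                   class = "replication_study")
  res$summary <- summarize_replications(res)
  res
}

# Per-scenario summaries: empirical SE, mean estimated SE, relative
# efficiency (paired, on replications where the GEE fit converged).
summarize_replications <- function(res) {
  est <- res$estimates
  wls <- est[est$estimator == "wls", ]
  out <- list()
  for (s in unique(est$shrink[est$estimator == "gee"])) {
    g <- est[est$estimator == "gee" & est$shrink == s, ]
    ok <- g$converged
    w <- wls[match(g$rep[ok], wls$rep), ]
    for (b in 1:2) {
      gb <- g[[paste0("beta", b)]][ok]
      sb <- g[[paste0("se", b)]][ok]
      wb <- w[[paste0("beta", b)]]
      out[[length(out) + 1L]] <- data.frame(
        shrink = s, coef = paste0("beta", b),
        mean_est = mean(gb), emp_se = stats::sd(gb),
        mean_est_se = mean(sb),
        wls_mean_est = mean(wb), wls_emp_se = stats::sd(wb),
        re = relative_efficiency(stats::var(gb), stats::var(wb)),
        n_used = sum(ok))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.replication_study <- function(x, digits = 4, ...) {
  cf <- x$config
  cat(sprintf("Replication study: %d replications, truth (beta1, beta2) = (%g, %g)\n",
              cf$replications, cf$beta1, cf$beta2))
  cat(sprintf("  %d SNPs in %d blocks (%d region(s) x %g cM x %d draw(s))\n",
              x$n_snps, x$n_blocks, cf$n_regions, cf$region_cm, cf$draws))
  if (x$n_nonconverged)
    cat(sprintf("  %d non-converged fit(s) excluded from summaries\n",
                x$n_nonconverged))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.replication_study <- function(object, ...) object$summary

#' Write replication-study outputs
#'
#' `write_replication_tsv` writes the per-scenario summary as a
#' tab-separated table (empirical and mean estimated standard errors,
#' relative efficiencies); `write_replication_json` writes the summary
#' plus configuration and per-replication estimates as JSON.
#'
#' @param res A [replication_study()] result.
#' @param path Output path.
#' @export
write_replication_tsv <- function(res, path) {
  utils::write.table(res$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_replication_tsv
#' @export
write_replication_json <- function(res, path) {
  cf <- res$config
  out <- list(config = cf[setdiff(names(cf), "ld_params")],
              ld_params = unclass(cf$ld_params),
              n_snps = res$n_snps, n_blocks = res$n_blocks,
              n_nonconverged = res$n_nonconverged,
              summary = res$summary, estimates = res$estimates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
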