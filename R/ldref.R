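#' Read a genetic map
#'
#' Accepts the common whitespace-delimited `genetic_map` dialect with
#' columns (chromosome, bp, cM) -- a header line is detected and skipped --
#' or a PLINK `.map` file (chromosome, id, cM, bp).  Positions are 1-based.
#'
#' @param path Path to the map file.
#' @param format `"auto"` (by extension), `"genetic_map"` or `"plink"`.
#' @return A data frame of class `"genetic_map"` with columns `chr`, `bp`,
#'   `cm`, sorted by (chr, bp); `cm` is non-decreasing within chromosome.
#' @export
read_genetic_map <- function(path, format = c("auto", "genetic_map", "plink")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.map$", path)) "plink" else "genetic_map"
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  # header iff the numeric columns of the dialect are not numeric
  num_cols <- if (format == "plink") c(3L, 4L) else c(2L, 3L)
  skip <- if (anyNA(suppressWarnings(as.numeric(first[num_cols])))) 1L else 0L
  raw <- utils::read.table(path, skip = skip, header = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "plink") {
    map <- data.frame(chr = as.character(raw[[1]]), bp = as.numeric(raw[[4]]),
                      cm = as.numeric(raw[[3]]))
  } else {
    map <- data.frame(chr = as.character(raw[[1]]), bp = as.numeric(raw[[2]]),
                      cm = as.numeric(raw[[3]]))
  }
  map <- map[order(map$chr, map$bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chr)) {
    cm <- map$cm[map$chr == ch]
    if (is.unsorted(cm)) stop("genetic map cM positions decrease within chromosome ",
                              ch, call. = FALSE)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Interpolate genetic positions for arbitrary base-pair coordinates
#'
#' Linear interpolation in bp between flanking map points, per chromosome.
#' Positions outside the map's span (or on an unmapped chromosome) get `NA`
#' and should be dropped by the caller.
#'
#' @param map A [read_genetic_map()] result (or a data frame with columns
#'   `chr`, `bp`, `cm`).
#' @param chr,bp Chromosome labels and 1-based bp positions of the query
#'   variants.
#' @return Numeric vector of cM positions (`NA` where not interpolable).
#' @export
interpolate_cm <- function(map, chr, bp) {
  stopifnot(length(chr) == length(bp))
  out <- rep(NA_real_, length(bp))
  for (ch in unique(chr)) {
    m <- map[map$chr == ch, , drop = FALSE]
    if (nrow(m) < 2L) next
    idx <- which(chr == ch)
    inside <- bp[idx] >= min(m$bp) & bp[idx] <= max(m$bp)
    out[idx[inside]] <- stats::approx(m$bp, m$cm, xout = bp[idx][inside],
                                      ties = "ordered")$y
  }
  out
}

#' Read a plain-text haplotype matrix
#'
#' Whitespace-delimited 0/1 integers, one haplotype per row, one variant per
#' column, variants in genomic order.  This is the text format used for
#' small test panels; see [read_haplotypes_vcf()] for phased VCF input.
#'
#' @param path File path.
#' @return Integer matrix (haplotypes x variants).
#' @export
read_haplotypes <- function(path) {
  h <- as.matrix(utils::read.table(path, header = FALSE))
  storage.mode(h) <- "integer"
  if (!all(h %in% c(0L, 1L)))
    stop("haplotype matrix must contain only 0/1 alleles", call. = FALSE)
  dimnames(h) <- NULL
  h
}

#' Read phased haplotypes from a VCF reference panel
#'
#' Requires phased GT fields (`|` separator); each sample contributes two
#' haplotypes.  Multi-allelic or unphased records are rejected.
#'
#' @param path Path to a VCF (may be bgzipped).
#' @return A list with `haplotypes` (0/1 matrix, haplotypes x variants),
#'   `chr`, `bp`, `id`, `ref`, `alt` vectors in file order.
#' @export
read_haplotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF reference panels requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("VCF contains unphased genotypes; phased GT (|) required", call. = FALSE)
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("only biallelic 0|0, 0|1, 1|0, 1|1 genotypes are supported", call. = FALSE)
  n_var <- nrow(gt); n_sam <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_sam, ncol = n_var)
  hap[seq(1L, 2L * n_sam, by = 2L), ] <- t(matrix(as.integer(a1), n_var, n_sam))
  hap[seq(2L, 2L * n_sam, by = 2L), ] <- t(matrix(as.integer(a2), n_var, n_sam))
  list(haplotypes = hap, chr = as.character(fix[, "CHROM"]),
       bp = as.numeric(fix[, "POS"]), id = as.character(fix[, "ID"]),
       ref = as.character(fix[, "REF"]), alt = as.character(fix[, "ALT"]))
}

#' Band LD matrix from phased haplotypes
#'
#' Computes pairwise LD between variants within a genetic-distance cutoff
#' and truncates it to exactly zero beyond the cutoff, yielding a sparse
#' symmetric band matrix.  `stat = "r2"` stores the squared Pearson
#' correlation of the haplotype allele indicators (the working-correlation
#' measure for squared test statistics); `stat = "r"` stores the signed
#' correlation (the correlation of the underlying z-scores).
#'
#' Monomorphic or near-monomorphic variants (panel MAF below `maf_min`)
#' have undefined correlation and are excluded with a warning; the returned
#' object's coordinates refer to the retained variants only (`keep` maps
#' back to input columns).
#'
#' @param haplotypes 0/1 matrix, haplotypes x variants, variants ordered by
#'   genomic position.
#' @param cm Genetic positions (cM) of the variants, non-decreasing within
#'   chromosome.
#' @param chr Optional chromosome labels (default: a single chromosome).
#' @param cutoff_cm Truncation distance in cM (default 1).
#' @param stat `"r2"` or `"r"`.
#' @param maf_min Exclusion threshold for the panel MAF (default `1e-6`).
#' @param adjusted If `TRUE`, apply the small-sample bias adjustment
#'   `r2 - (1 - r2) / (n_hap - 2)` to squared correlations (floored at 0).
#'   Default `FALSE`: raw `r^2`, the quantity a correlation matrix of test
#'   statistics requires.
#' @return Object of class `"band_ld"`: list with sparse symmetric `mat`,
#'   and vectors `cm`, `chr`, plus `cutoff_cm`, `stat`, `keep`.
#' @export
band_ld_matrix <- function(haplotypes, cm, chr = NULL, cutoff_cm = 1,
                           stat = c("r2", "r"), maf_min = 1e-6,
                           adjusted = FALSE) {
  stat <- match.arg(stat)
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) == length(cm),
            cutoff_cm > 0)
  if (is.null(chr)) chr <- rep("1", length(cm))
  chr <- as.character(chr)
  for (ch in unique(chr))
    if (is.unsorted(cm[chr == ch]))
      stop("variants must be ordered by genetic position within chromosome",
           call. = FALSE)
  maf <- colMeans(haplotypes)
  maf <- pmin(maf, 1 - maf)
  keep <- which(maf >= maf_min)
  if (length(keep) < length(cm))
    warning(sprintf("excluding %d monomorphic/near-monomorphic variant(s) (MAF < %g)",
                    length(cm) - length(keep), maf_min), call. = FALSE)
  h <- haplotypes[, keep, drop = FALSE]
  cm <- cm[keep]; chr <- chr[keep]
  n <- length(keep); nh <- nrow(h)
  z <- scale(h)  # centred, unit sd columns
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  for (i in seq_len(n)) {
    hi <- i
    while (hi < n && chr[hi + 1L] == chr[i] && cm[hi + 1L] - cm[i] <= cutoff_cm)
      hi <- hi + 1L
    js <- i:hi
    r <- as.numeric(crossprod(z[, js, drop = FALSE], z[, i])) / (nh - 1)
    r <- pmax(pmin(r, 1), -1)
    v <- if (stat == "r2") r^2 else r
    if (stat == "r2" && adjusted) v <- pmax(v - (1 - v) / (nh - 2), 0)
    ii[[i]] <- rep.int(i, length(js)); jj[[i]] <- js; xx[[i]] <- v
  }
  mat <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n), symmetric = TRUE)
  structure(list(mat = mat, cm = cm, chr = chr, cutoff_cm = cutoff_cm,
                 stat = stat, keep = keep),
            class = "band_ld")
}

#' @export
print.band_ld <- function(x, ...) {
  cat(sprintf("Band LD matrix (%s): %d variants, cutoff %g cM, %d stored entries\n",
              x$stat, length(x$cm), x$cutoff_cm, Matrix::nnzero(x$mat)))
  invisible(x)
}

#' @export
dim.band_ld <- function(x) dim(x$mat)

#' LD scores
#'
#' The LD score of a variant is the sum of its `r^2` with every variant
#' within `window_cm` of genetic distance, including itself, so every LD
#' score is at least 1.
#'
#' @param haplotypes,cm,chr,maf_min As in [band_ld_matrix()].
#' @param window_cm Window half-width in cM (default 1).
#' @return Numeric vector of LD scores for the retained variants (see
#'   [band_ld_matrix()] for the monomorphic-exclusion rule); the `keep`
#'   attribute maps to input columns.
#' @export
ld_scores <- function(haplotypes, cm, chr = NULL, window_cm = 1,
                      maf_min = 1e-6) {
  b <- band_ld_matrix(haplotypes, cm, chr = chr, cutoff_cm = window_cm,
                      stat = "r2", maf_min = maf_min)
  structure(ld_scores_from_band(b), keep = b$keep)
}

#' @rdname ld_scores
#' @param band A `"band_ld"` object with `stat = "r2"`.
#' @export
ld_scores_from_band <- function(band) {
  stopifnot(inherits(band, "band_ld"))
  m <- band$mat
  if (band$stat != "r2") m <- m^2
  as.numeric(Matrix::rowSums(m))
}

#' Partition variants into consecutive genetic-distance blocks
#'
#' Splits each chromosome into half-open intervals
#' `[k * block_cm, (k + 1) * block_cm)` of genetic distance, anchored at
#' cM coordinate 0, and groups the variants accordingly.  Empty blocks are
#' dropped; every variant lands in exactly one block.
#'
#' @param cm Genetic positions, sorted within chromosome.
#' @param chr Optional chromosome labels.
#' @param block_cm Block length in cM (default 1).
#' @return List of class `"ld_blocks"`; each element has `index` (variant
#'   indices), `chr`, `k` (interval number), `start_cm`, `end_cm`.
#' @export
partition_blocks <- function(cm, chr = NULL, block_cm = 1) {
  if (is.null(chr)) chr <- rep("1", length(cm))
  chr <- as.character(chr)
  for (ch in unique(chr))
    if (is.unsorted(cm[chr == ch]))
      stop("variants must be sorted by genetic position within chromosome",
           call. = FALSE)
  k <- floor(cm / block_cm)
  key <- paste(chr, k, sep = ":")
  groups <- split(seq_along(cm), factor(key, levels = unique(key)))
  blocks <- lapply(groups, function(idx) {
    list(index = idx, chr = chr[idx[1]], k = k[idx[1]],
         start_cm = k[idx[1]] * block_cm, end_cm = (k[idx[1]] + 1) * block_cm)
  })
  names(blocks) <- NULL
  structure(blocks, class = "ld_blocks", block_cm = block_cm)
}

#' @export
print.ld_blocks <- function(x, ...) {
  m <- lengths(lapply(x, `[[`, "index"))
  cat(sprintf("%d LD blocks of %g cM; block sizes %d-%d (median %g) variants\n",
              length(x), attr(x, "block_cm"), min(m), max(m), stats::median(m)))
  invisible(x)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue clipping at `floor` followed by rescaling the diagonal back
#' to 1.  Used to turn estimated (possibly rank-deficient) LD submatrices
#' into valid working-correlation matrices.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param floor Smallest admissible eigenvalue (default `1e-6`).
#' @return Positive-definite correlation matrix.
#' @export
psd_repair <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Working-correlation matrices for LD blocks
#'
#' Extracts, for each block, the principal submatrix of the band `r^2`
#' matrix, repairs it to positive definiteness ([psd_repair()]) and
#' optionally shrinks it towards the identity.
#'
#' @param band An `r^2` [band_ld_matrix()].
#' @param blocks A [partition_blocks()] result over the same variants.
#' @param floor Eigenvalue floor for the PSD repair.
#' @param shrink Shrinkage factor `s` in `[0, 1]` applied to the
#'   off-diagonal entries (see [shrink_correlation()]); default 1 (none).
#' @return List of dense positive-definite matrices, one per block.
#' @export
working_correlations <- function(band, blocks, floor = 1e-6, shrink = 1) {
  stopifnot(inherits(band, "band_ld"), inherits(blocks, "ld_blocks"))
  lapply(blocks, function(b) {
    R <- as.matrix(band$mat[b$index, b$index, drop = FALSE])
    diag(R) <- 1
    if (shrink < 1) R <- shrink_correlation(R, shrink)
    psd_repair(R, floor = floor)
  })
}

#' Shrink a correlation matrix towards the identity
#'
#' `R' = s R + (1 - s) I`: off-diagonal entries are multiplied by `s`, the
#' diagonal stays 1.  A convex combination with the identity, so positive
#' semi-definiteness is preserved for any `s` in `[0, 1]`.
#'
#' @param R Correlation matrix.
#' @param s Shrinkage factor in `[0, 1]` (1 = unchanged, 0 = identity).
#' @return Shrunk matrix.
#' @export
shrink_correlation <- function(R, s) {
  stopifnot(s >= 0, s <= 1)
  out <- s * R
  diag(out) <- 1
  out
}

#' Correlated block pairs
#'
#' Two blocks are flagged as correlated iff they are genetically adjacent:
#' same chromosome and consecutive interval numbers (`|k_i - k_j| = 1`).
#' With block length equal to the LD truncation distance, variants two or
#' more blocks apart are beyond the band and their statistics uncorrelated;
#' the flagged pairs feed the cross-term of the sandwich variance.
#'
#' @param blocks A [partition_blocks()] result.
#' @return Two-column integer matrix of unordered block-index pairs
#'   (possibly zero rows).
#' @export
block_adjacency <- function(blocks) {
  stopifnot(inherits(blocks, "ld_blocks"))
  n <- length(blocks)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("i", "j"))))
  chr <- vapply(blocks, `[[`, "", "chr")
  k <- vapply(blocks, `[[`, 0, "k")
  i <- seq_len(n - 1L)
  adj <- i[chr[i] == chr[i + 1L] & abs(k[i + 1L] - k[i]) == 1]
  cbind(i = adj, j = adj + 1L)
}

#' Principal-submatrix subset of a band LD matrix
#'
#' Restricts a band LD object to a subset of its variants (order
#' preserved), e.g. after matching to summary statistics or perfect-LD
#' filtering.
#'
#' @param band A [band_ld_matrix()] object.
#' @param idx Increasing integer indices of the variants to keep.
#' @return A `"band_ld"` over the retained variants.
#' @export
band_ld_subset <- function(band, idx) {
  stopifnot(inherits(band, "band_ld"), !is.unsorted(idx))
  structure(list(mat = band$mat[idx, idx, drop = FALSE], cm = band$cm[idx],
                 chr = band$chr[idx], cutoff_cm = band$cutoff_cm,
                 stat = band$stat, keep = band$keep[idx]),
            class = "band_ld")
}

#' Read and write LD score files
#'
#' Tab-separated with header columns CHR, SNP, BP, L2 (the common ldscore
#' dialect).  Pre-computed files can replace on-the-fly computation from a
#' reference panel.
#'
#' @param path File path (a `.gz` suffix is handled transparently).
#' @return `read_ldscores`: data frame with columns `chr`, `id`, `bp`, `l2`.
#' @export
read_ldscores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("CHR", "SNP", "BP", "L2")
  if (!all(need %in% names(d)))
    stop("LD score file must have columns CHR, SNP, BP, L2", call. = FALSE)
  data.frame(chr = as.character(d$CHR), id = as.character(d$SNP),
             bp = as.numeric(d$BP), l2 = as.numeric(d$L2))
}

#' @rdname read_ldscores
#' @param chr,id,bp,l2 Per-variant fields to write.
#' @export
write_ldscores <- function(path, chr, id, bp, l2) {
  d <- data.frame(CHR = chr, SNP = id, BP = bp, L2 = l2)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist and load band LD matrices
#'
#' The matrix is stored as gzip-compressed coordinate triplets
#' (`i j value`, upper triangle including the diagonal) next to a JSON
#' sidecar `<path>.json` holding the cutoff, the statistic, the coordinate
#' vectors and a checksum of the variant coordinates.
#'
#' @param band A [band_ld_matrix()] object.
#' @param path Output path for the triplet file (`.gz` appended if absent).
#' @return `write_band_ld` returns the triplet path; `read_band_ld` the
#'   reconstructed `"band_ld"` object.
#' @export
write_band_ld <- function(band, path) {
  stopifnot(inherits(band, "band_ld"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  tr <- Matrix::mat2triplet(Matrix::triu(band$mat))
  con <- gzfile(path, "w")
  utils::write.table(data.frame(i = tr$i, j = tr$j, x = tr$x), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  side <- list(cutoff_cm = band$cutoff_cm, stat = band$stat,
               n_variants = length(band$cm), chr = band$chr, cm = band$cm,
               keep = band$keep,
               cm_checksum = signif(sum(band$cm * seq_along(band$cm)), 12))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_band_ld
#' @export
read_band_ld <- function(path) {
  if (!grepl("\\.gz$", path) && file.exists(paste0(path, ".gz")))
    path <- paste0(path, ".gz")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- utils::read.table(gzfile(path), header = FALSE,
                          col.names = c("i", "j", "x"))
  chk <- signif(sum(side$cm * seq_along(side$cm)), 12)
  if (!isTRUE(all.equal(chk, side$cm_checksum)))
    stop("band LD sidecar checksum mismatch", call. = FALSE)
  mat <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = rep(side$n_variants, 2), symmetric = TRUE)
  structure(list(mat = mat, cm = side$cm, chr = as.character(side$chr),
                 cutoff_cm = side$cutoff_cm, stat = side$stat,
                 keep = side$keep),
            class = "band_ld")
}
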