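#' Read association summary statistics
#'
#' Tab-separated text with a header, in the common summary-statistics
#' dialect.  Column-name synonyms are resolved case-insensitively:
#' `SNP`/`ID`/`RSID`, `CHR`/`CHROM`, `BP`/`POS`, `A1`, `A2`/`REF`,
#' `CHISQ` or `Z` (z-scores are squared on ingest), `N`, optional `INFO`
#' and `P`/`PVAL`.  Malformed rows (missing values in mandatory fields,
#' negative statistics, alleles outside A/C/G/T) are rejected with a
#' warning listing their line numbers.
#'
#' @param path File path (plain or gzipped).
#' @return Data frame of class `"sumstats"` with columns `id`, `chr`,
#'   `bp`, `a1`, `a2`, `chisq`, `n`, `info`, `p` (the last two `NA` when
#'   absent).
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  nm <- toupper(names(d))
  pick <- function(...) {
    hit <- which(nm %in% c(...))
    if (length(hit)) d[[hit[1]]] else NULL
  }
  id <- pick("SNP", "ID", "RSID")
  chr <- pick("CHR", "CHROM")
  bp <- pick("BP", "POS")
  a1 <- pick("A1", "ALT", "EA")
  a2 <- pick("A2", "REF", "OA")
  z <- pick("Z"); chisq <- pick("CHISQ")
  n <- pick("N")
  info <- pick("INFO")
  p <- pick("P", "PVAL", "PVALUE")
  if (is.null(id) || is.null(chr) || is.null(bp) || is.null(a1) ||
      is.null(a2) || (is.null(z) && is.null(chisq)) || is.null(n))
    stop("summary statistics need columns SNP, CHR, BP, A1, A2, N and Z or CHISQ",
         call. = FALSE)
  stat <- if (!is.null(chisq)) as.numeric(chisq) else as.numeric(z)^2
  neg <- !is.null(chisq) & !is.na(stat) & stat < 0
  out <- data.frame(id = as.character(id), chr = as.character(chr),
                    bp = as.numeric(bp),
                    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
                    chisq = stat, n = as.numeric(n),
                    info = if (is.null(info)) NA_real_ else as.numeric(info),
                    p = if (is.null(p)) NA_real_ else as.numeric(p),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$id) | is.na(out$bp) | is.na(out$chisq) | is.na(out$n) |
    neg | !(out$a1 %in% c("A", "C", "G", "T")) |
    !(out$a2 %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20L), collapse = ", ")),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("sumstats", "data.frame")
  out
}

#' @rdname read_sumstats
#' @param records A `"sumstats"` data frame to write.
#' @export
write_sumstats <- function(records, path) {
  d <- data.frame(SNP = records$id, CHR = records$chr, BP = records$bp,
                  A1 = records$a1, A2 = records$a2, CHISQ = records$chisq,
                  N = records$n, INFO = records$info, P = records$p)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_filter_report <- function(counts, n_input, n_surviving) {
  stopifnot(sum(counts) + n_surviving == n_input)
  structure(list(counts = counts, n_input = n_input,
                 n_surviving = n_surviving),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d input, %d surviving\n", x$n_input,
              x$n_surviving))
  for (nm in names(x$counts))
    if (x$counts[[nm]] > 0) cat(sprintf("  removed (%s): %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Quality filters for summary statistics
#'
#' Applies the standard pre-analysis rules: strand-ambiguous variants
#' (A/T or C/G allele pairs) are removed; variants with an imputation info
#' score below `info_min` are removed where the score is available; where
#' no info score is available the input can instead be restricted to a
#' well-imputed SNP id set (e.g. HapMap3); variants with p-values below
#' `p_min` are removed where a p-value is present (extreme outliers
#' distort the mean model).  Each removed variant is attributed to the
#' first rule it violates, in the order above.
#'
#' @param records A [read_sumstats()] data frame.
#' @param info_min Info-score threshold (default 0.9).
#' @param p_min P-value floor (default `1e-16`).
#' @param snp_set Optional character vector of ids to restrict to when the
#'   info score is missing.
#' @return List with `records` (survivors) and `report` (a filter report
#'   whose per-rule counts reconcile with the input size).
#' @export
filter_sumstats <- function(records, info_min = 0.9, p_min = 1e-16,
                            snp_set = NULL) {
  n0 <- nrow(records)
  pair <- paste0(pmin(records$a1, records$a2), pmax(records$a1, records$a2))
  ambiguous <- pair %in% c("AT", "CG")
  low_info <- !is.na(records$info) & records$info < info_min
  not_in_set <- if (!is.null(snp_set))
    is.na(records$info) & !(records$id %in% snp_set)
  else rep(FALSE, n0)
  low_p <- !is.na(records$p) & records$p < p_min
  # priority attribution so the counts reconcile
  r_amb <- ambiguous
  r_info <- low_info & !r_amb
  r_set <- not_in_set & !r_amb & !r_info
  r_p <- low_p & !r_amb & !r_info & !r_set
  drop <- r_amb | r_info | r_set | r_p
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  report <- new_filter_report(
    c(ambiguous = sum(r_amb), low_info = sum(r_info),
      not_in_set = sum(r_set), low_p = sum(r_p)),
    n0, nrow(out))
  list(records = out, report = report)
}

#' Remove variants in perfect LD
#'
#' Within each group of variants whose pairwise `r^2` exceeds `r2_max`,
#' only the first by position is kept: scanning in genomic order, a
#' variant is dropped when it is in (near-)perfect LD with an
#' already-kept variant.  Deterministic; prevents degenerate
#' working-correlation matrices.
#'
#' @param records A `"sumstats"` data frame whose row `i` corresponds to
#'   variant `i` of `ld`.
#' @param ld An `r^2` [band_ld_matrix()] over the same variants.
#' @param r2_max Threshold above which LD counts as perfect
#'   (default 0.999).
#' @return List with `records`, `keep` (retained LD-matrix indices) and
#'   `report`.
#' @export
filter_perfect_ld <- function(records, ld, r2_max = 0.999) {
  stopifnot(inherits(ld, "band_ld"), ld$stat == "r2",
            nrow(records) == length(ld$cm))
  tr <- Matrix::mat2triplet(Matrix::triu(ld$mat, k = 1))
  hit <- tr$x > r2_max
  partners <- split(tr$i[hit], tr$j[hit])  # earlier partners per variant
  n <- length(ld$cm)
  kept <- rep(TRUE, n)
  for (j in sort(as.integer(names(partners)))) {
    if (any(kept[partners[[as.character(j)]]])) kept[j] <- FALSE
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  report <- new_filter_report(c(perfect_ld = sum(!kept)), n, sum(kept))
  list(records = out, keep = which(kept), report = report)
}

complement_allele <- function(a)
  c(A = "T", C = "G", G = "C", T = "A")[a]

#' Match summary statistics to a reference panel
#'
#' Matches by (chromosome, bp) and checks allele consistency against the
#' panel's ref/alt pair; strand flips of unambiguous pairs are resolved
#' automatically.  Unmatched or allele-inconsistent variants are dropped
#' and counted.
#'
#' @param records A `"sumstats"` data frame.
#' @param chr,bp,ref,alt Panel variant coordinates and alleles, in panel
#'   order.
#' @return List with `records` (matched survivors, in panel order),
#'   `panel_index` (their positions in the panel) and `report`.
#' @export
match_sumstats <- function(records, chr, bp, ref, alt) {
  key_panel <- paste(chr, bp, sep = ":")
  key_rec <- paste(records$chr, records$bp, sep = ":")
  pos <- match(key_panel, key_rec)
  found <- !is.na(pos)
  rec <- records[pos[found], , drop = FALSE]
  pr <- toupper(ref[found]); pa <- toupper(alt[found])
  direct <- (rec$a1 == pa & rec$a2 == pr) | (rec$a1 == pr & rec$a2 == pa)
  flipped <- (complement_allele(rec$a1) == pa & complement_allele(rec$a2) == pr) |
    (complement_allele(rec$a1) == pr & complement_allele(rec$a2) == pa)
  ok <- direct | flipped
  out <- rec[ok, , drop = FALSE]
  rownames(out) <- NULL
  n0 <- nrow(records)
  report <- new_filter_report(
    c(unmatched = n0 - nrow(rec), allele_mismatch = sum(!ok)),
    n0, nrow(out))
  list(records = out, panel_index = which(found)[ok], report = report)
}

#' Number of common SNPs in a reference panel
#'
#' Counts panel variants with MAF at or above the threshold; the standard
#' choice for the per-SNP heritability scale `M`.
#'
#' @param haplotypes 0/1 haplotype matrix.
#' @param maf_min Common-variant MAF threshold (default 0.05).
#' @return Integer count.
#' @export
count_common_variants <- function(haplotypes, maf_min = 0.05) {
  maf <- colMeans(haplotypes)
  sum(pmin(maf, 1 - maf) >= maf_min)
}

#' Read a simulation configuration from JSON
#'
#' The JSON mirrors [sim_config()] (optionally with a nested `ld_params`
#' object mirroring [synthetic_ld_params()]).
#'
#' @param path JSON file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lp <- if (is.null(j$ld_params)) synthetic_ld_params()
        else do.call(synthetic_ld_params, as.list(j$ld_params))
  j$ld_params <- NULL
  do.call(sim_config, c(as.list(j), list(ld_params = lp)))
}
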