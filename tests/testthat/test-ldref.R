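test_that("windowed LD scores equal the brute-force all-pairs sum", {
  tp <- toy_panel()
  l <- ld_scores(tp$hap, tp$cm)
  expect_equal(as.numeric(l), brute_ld_scores(tp$hap, tp$cm), tolerance = 1e-12)
  # larger random instance, exact agreement with the O(n^2) oracle
  sh <- small_landscape()$sh
  l2 <- ld_scores(sh$haplotypes, sh$cm)
  expect_equal(as.numeric(l2), brute_ld_scores(sh$haplotypes, sh$cm),
               tolerance = 1e-10)
  expect_true(all(l2 >= 1))
  # an isolated variant scores exactly 1
  hap <- matrix(rbinom(40, 1, 0.5), nrow = 20)
  li <- ld_scores(hap, cm = c(0, 5))
  expect_equal(as.numeric(li), c(1, 1))
})

test_that("band LD matrix truncates beyond the cutoff and squares r", {
  tp <- toy_panel()
  b <- band_ld_matrix(tp$hap, tp$cm)
  m <- as.matrix(b$mat)
  expect_equal(diag(m), rep(1, 5))
  expect_true(isSymmetric(m))
  # identical columns are in perfect LD
  expect_equal(m[1, 2], 1)
  # beyond 1 cM: exactly zero (variant 5 at 2.5 cM vs all others)
  expect_equal(m[5, 1:4], rep(0, 4))
  # variant 4 at 0.9 cM is within 1 cM of variants 1-3
  expect_true(all(m[4, 1:3] > 0 | abs(cor(tp$hap[, 4], tp$hap[, 1:3])) < 1e-8))
  # within cutoff entries equal squared Pearson correlation
  expect_equal(m[1, 3], cor(tp$hap[, 1], tp$hap[, 3])^2)
  # signed variant keeps the sign
  bs <- band_ld_matrix(tp$hap, tp$cm, stat = "r")
  expect_equal(as.matrix(bs$mat)[1, 3], cor(tp$hap[, 1], tp$hap[, 3]))
  # independent random columns have near-zero r2
  set.seed(9)
  big <- matrix(rbinom(2e4, 1, 0.5), nrow = 1e4)
  b2 <- band_ld_matrix(big, cm = c(0, 0.1))
  expect_lt(as.matrix(b2$mat)[1, 2], 0.01)
})

test_that("monomorphic variants are excluded with a warning", {
  hap <- cbind(matrix(rbinom(60, 1, 0.5), nrow = 20), 0L)
  expect_warning(b <- band_ld_matrix(hap, cm = c(0, 0.1, 0.2, 0.3)),
                 "monomorphic")
  expect_equal(b$keep, 1:3)
  expect_equal(length(b$cm), 3)
})

test_that("block partition forms half-open 1 cM intervals per chromosome", {
  bl <- partition_blocks(c(0.2, 0.8, 1.3))
  expect_length(bl, 2)
  expect_equal(bl[[1]]$index, 1:2)
  expect_equal(bl[[2]]$index, 3L)
  expect_equal(bl[[2]]$start_cm, 1)
  # all variants within one cM: single block
  expect_length(partition_blocks(c(0.1, 0.4, 0.9)), 1)
  # exact boundary goes to the upper block (half-open intervals)
  bl2 <- partition_blocks(c(0.5, 1.0))
  expect_length(bl2, 2)
  # ~uniform variants over 25 cM: about 25 blocks
  set.seed(2)
  expect_equal(length(partition_blocks(sort(runif(2500, 0, 25)))), 25)
  # chromosomes partition independently
  bl3 <- partition_blocks(c(0.1, 0.2, 0.1), chr = c("1", "1", "2"))
  expect_length(bl3, 2)
  expect_error(partition_blocks(c(1, 0.5)), "sorted")
})

test_that("every variant lands in exactly one block", {
  sh <- small_landscape()$sh
  bl <- partition_blocks(sh$cm)
  idx <- sort(unlist(lapply(bl, `[[`, "index")))
  expect_equal(idx, seq_along(sh$cm))
})

test_that("working correlations are PSD with unit diagonal after repair", {
  ls <- small_landscape()
  bl <- partition_blocks(ls$sh$cm)
  Rs <- working_correlations(ls$r2, bl)
  for (R in Rs) {
    expect_true(isSymmetric(R))
    expect_equal(diag(R), rep(1, nrow(R)))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  # single-variant block and identity block degenerate correctly
  one <- structure(list(mat = Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                                   symmetric = TRUE),
                        cm = 0.5, chr = "1", cutoff_cm = 1, stat = "r2",
                        keep = 1L), class = "band_ld")
  expect_equal(working_correlations(one, partition_blocks(0.5))[[1]],
               matrix(1, 1, 1))
})

test_that("PSD repair stays close in Frobenius norm and fixes eigenvalues", {
  # a 3x3 'correlation' with a negative eigenvalue
  R <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)
  Rr <- psd_repair(R)
  expect_gte(min(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(Rr), rep(1, 3))
  # repair perturbation is bounded by the clipped mass (loose bound)
  expect_lt(norm(Rr - R, "F"), 2 * abs(min(ev)) * sqrt(3))
  # already-PSD input untouched
  expect_equal(psd_repair(diag(3)), diag(3))
})

test_that("shrinking interpolates between the matrix and the identity", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(shrink_correlation(R, 1), R)
  expect_equal(shrink_correlation(R, 0), diag(2))
  expect_equal(shrink_correlation(R, 0.64)[1, 2], 0.32)
  # convex combination preserves PSD for random correlation matrices
  set.seed(5)
  for (k in 1:5) {
    A <- crossprod(matrix(rnorm(25), 5))
    D <- diag(1 / sqrt(diag(A)))
    C <- D %*% A %*% D
    s <- runif(1)
    expect_gte(min(eigen(shrink_correlation(C, s), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
  }
})

test_that("adjacency flags consecutive same-chromosome blocks only", {
  bl <- partition_blocks(c(0.5, 1.5, 2.5))
  expect_equal(unname(block_adjacency(bl)), cbind(c(1L, 2L), c(2L, 3L)),
               ignore_attr = TRUE)
  # gap of one empty block breaks adjacency
  bl2 <- partition_blocks(c(0.5, 2.5))
  expect_equal(nrow(block_adjacency(bl2)), 0L)
  # different chromosomes never adjacent
  bl3 <- partition_blocks(c(0.5, 0.2), chr = c("1", "2"))
  expect_equal(nrow(block_adjacency(bl3)), 0L)
  expect_equal(nrow(block_adjacency(partition_blocks(0.3))), 0L)
})

test_that("genetic map reading and interpolation work on both dialects", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr position cM", "1 1000 0.0", "1 3000 1.0", "1 5000 4.0",
               "2 1000 0.0", "2 2000 0.5"), path)
  map <- read_genetic_map(path)
  expect_s3_class(map, "genetic_map")
  expect_equal(interpolate_cm(map, c("1", "1", "1"), c(1000, 2000, 4000)),
               c(0, 0.5, 2.5))
  # outside span / unknown chromosome -> NA
  expect_true(is.na(interpolate_cm(map, "1", 10000)))
  expect_true(is.na(interpolate_cm(map, "7", 1500)))
  # PLINK .map dialect: chr, id, cM, bp
  pl <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0.0\t1000", "1\trs2\t1.0\t3000"), pl)
  map2 <- read_genetic_map(pl)
  expect_equal(map2$cm, c(0, 1))
  expect_equal(map2$bp, c(1000, 3000))
})

test_that("band LD matrices and LD scores round-trip through files", {
  ls <- small_landscape()
  dir <- withr::local_tempdir()
  p <- write_band_ld(ls$r2, file.path(dir, "chr1.ld"))
  back <- read_band_ld(p)
  expect_equal(as.matrix(back$mat), as.matrix(ls$r2$mat), tolerance = 1e-12)
  expect_equal(back$cm, ls$r2$cm)
  expect_equal(back$stat, "r2")
  lsc <- file.path(dir, "scores.l2")
  write_ldscores(lsc, chr = rep("1", length(ls$l2)),
                 id = sprintf("rs%d", seq_along(ls$l2)),
                 bp = round(ls$sh$cm * 1e6), l2 = ls$l2)
  got <- read_ldscores(lsc)
  expect_equal(got$l2, ls$l2, tolerance = 1e-6)
})

test_that("plain-text haplotype matrices load and validate", {
  tp <- toy_panel()
  f <- withr::local_tempfile()
  write.table(tp$hap, f, row.names = FALSE, col.names = FALSE)
  expect_equal(read_haplotypes(f), tp$hap)
  writeLines("0 1 2", f)
  expect_error(read_haplotypes(f), "0/1")
})
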