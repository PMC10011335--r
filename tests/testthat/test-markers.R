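test_that("coded CSV matrices round-trip through write/read unchanged", {
  s <- matrix(c(1, 0, -1, NA, 1, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  g <- ssdGP:::newGenotypeMatrix(s)
  path <- withr::local_tempfile(fileext = ".csv")
  writeGenotypesCsv(g, path)
  g2 <- readGenotypes(path, "csv-matrix")
  expect_identical(individualIds(g2), c("a", "b", "c"))
  expect_identical(markerIds(g2), c("m1", "m2"))
  expect_equal(scoreMatrix(g2), scoreMatrix(g))
  expect_true(missingMask(g2)[1, 2])
  expect_identical(sum(missingMask(g2)), 1L)
})

test_that("CSV values outside the -1/0/1 coding are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,m1,m2", "a,1,2", "b,0,-1", "c,0,1"), path)
  expect_error(readGenotypes(path, "csv-matrix"), "outside \\{-1, 0, 1")
})

test_that("tab-separated matrices are autodetected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "a\t1\t0", "b\t-1\tNA"), path)
  g <- readGenotypes(path, "csv-matrix")
  expect_equal(unname(scoreMatrix(g)[2, ]), c(-1, NA))
})

vcfHeader <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4")

test_that("VCF genotypes are coded by the per-locus major allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader,
    # REF allele major (3 of 8 ALT copies): 0/0 -> 1, 0/1 -> 0, 1/1 -> -1
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/1",
    # ALT allele major (6 of 8): 1/1 -> 1, 0/1 -> 0, 0/0 -> -1
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1|1\t0/1\t0/1",
    # 50/50 tie: REF treated as major, missing stays NA
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1\t./."), path)
  g <- readGenotypes(path, "vcf")
  s <- scoreMatrix(g)
  expect_equal(unname(s[, "1_100"]), c(1, 0, -1, 0))
  expect_equal(unname(s[, "1_200"]), c(1, 1, 0, 0))
  expect_equal(unname(s[, "1_300"]), c(1, -1, 0, NA))
  expect_true(missingMask(g)["s4", "1_300"])
})

test_that("multi-allelic VCF records are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader,
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/1",
    "1\t150\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2\t2/2"), path)
  expect_warning(g <- readGenotypes(path, "vcf"), "multi-allelic")
  expect_identical(markerIds(g), "1_100")
})

test_that("QC filters apply marker call rate, individual missing rate, then MAF", {
  # 10 individuals; m1 observed in 8 of 10 (call rate 0.8 < 0.9) must go
  set.seed(1)
  s <- matrix(sample(c(-1, 0, 1), 50, replace = TRUE), nrow = 10,
              dimnames = list(paste0("i", 1:10), paste0("m", 1:5)))
  s[1:2, 1] <- NA
  g <- ssdGP:::newGenotypeMatrix(s)
  f <- suppressMessages(filterQC(g, callRateMin = 0.9, indMissingMax = 1,
                                 mafMin = 0))
  expect_identical(markerIds(f), paste0("m", 2:5))

  # MAF 0.04 < 0.05 is filtered: 1 het among 25 diploids -> maf = 1/50 = 0.02
  s2 <- matrix(1, nrow = 25, ncol = 2,
               dimnames = list(paste0("i", 1:25), c("rare", "common")))
  s2[1, 1] <- 0
  s2[1:10, 2] <- -1
  g2 <- ssdGP:::newGenotypeMatrix(s2)
  f2 <- suppressMessages(filterQC(g2, callRateMin = 0, indMissingMax = 1,
                                  mafMin = 0.05))
  expect_identical(markerIds(f2), "common")
  expect_error(
    suppressMessages(filterQC(g2, callRateMin = 0, indMissingMax = 1,
                              mafMin = 0.6)),
    "all markers")
})

test_that("no-op thresholds return the input unchanged and QC is idempotent", {
  set.seed(2)
  s <- matrix(sample(c(-1, 0, 1, NA), 60, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 10,
              dimnames = list(paste0("i", 1:10), paste0("m", 1:6)))
  g <- ssdGP:::newGenotypeMatrix(s)
  f0 <- suppressMessages(filterQC(g, 0, 1, 0))
  expect_equal(scoreMatrix(f0), scoreMatrix(g))
  f1 <- suppressMessages(filterQC(g, 0.8, 0.3, 0.1))
  f2 <- suppressMessages(filterQC(f1, 0.8, 0.3, 0.1))
  expect_equal(scoreMatrix(f2), scoreMatrix(f1))
})

test_that("mean imputation fills missing cells with column means only", {
  s <- cbind(m1 = c(1, 1, NA), m2 = c(-1, 1, NA), m3 = c(0, NA, 1))
  rownames(s) <- c("a", "b", "c")
  g <- imputeMean(ssdGP:::newGenotypeMatrix(s))
  expect_true(isImputed(g))
  expect_equal(unname(scoreMatrix(g)[3, "m1"]), 1)      # mean of (1, 1)
  expect_equal(unname(scoreMatrix(g)[3, "m2"]), 0)      # mean of (-1, 1)
  expect_equal(unname(scoreMatrix(g)[2, "m3"]), 0.5)    # mean of (0, 1)
  expect_equal(unname(scoreMatrix(g)[1, ]), c(1, -1, 0))  # observed untouched
  expect_identical(sum(missingMask(g)), 3L)             # mask preserved

  sBad <- cbind(m1 = c(1, 0, -1), m2 = c(NA_real_, NA, NA))
  rownames(sBad) <- c("a", "b", "c")
  expect_error(imputeMean(ssdGP:::newGenotypeMatrix(sBad)), "fully-missing")
})

test_that("a hand-built 4x3 grid imputes to the hand-computed matrix", {
  s <- cbind(m1 = c(1, -1, NA, 1), m2 = c(0, 0, 1, -1), m3 = c(NA, 1, 1, 0))
  rownames(s) <- paste0("i", 1:4)
  expected <- cbind(m1 = c(1, -1, 1 / 3, 1), m2 = c(0, 0, 1, -1),
                    m3 = c(2 / 3, 1, 1, 0))
  rownames(expected) <- paste0("i", 1:4)
  expect_equal(scoreMatrix(imputeMean(ssdGP:::newGenotypeMatrix(s))), expected)
})

test_that("standardization centers and scales with the n-1 denominator", {
  s <- cbind(m1 = c(0, 0, 1, -1), m2 = c(1, 1, 1, 1), m3 = c(1, 0, -1, 0))
  rownames(s) <- paste0("i", 1:4)
  g <- ssdGP:::newGenotypeMatrix(s, imputed = TRUE)
  expect_warning(m <- standardizeMarkers(g), "zero-variance")
  expect_identical(colnames(scoreMatrix(m)), c("m1", "m3"))
  expect_equal(unname(scoreMatrix(m)[, "m1"]),
               c(0, 0, 1, -1) / 0.816496580927726, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(scoreMatrix(m)))), 1e-10)
  expect_equal(unname(apply(scoreMatrix(m), 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("PC scores preserve the individual-by-individual Gram matrix", {
  set.seed(3)
  m <- matrix(rnorm(5 * 50), 5, 50, dimnames = list(paste0("i", 1:5), NULL))
  m[2, ] <- m[1, ]   # identical individuals
  pc <- pcScores(m)
  L <- scoreMatrix(pc)
  expect_lt(max(abs(tcrossprod(L) - tcrossprod(m))), 1e-8)
  expect_equal(L[1, ], L[2, ], tolerance = 1e-10)
  # eigenvalues match an independent dense decomposition of M'M
  evDense <- eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(eigenvalues(pc), evDense[seq_along(eigenvalues(pc))],
               tolerance = 1e-8)
  # rank 4 (one duplicated row): null component truncated
  expect_identical(ncol(L), 4L)
  expect_true(all(diff(eigenvalues(pc)) <= 0))
  # loadings orthonormal
  Q <- pcLoadings(pc)
  expect_lt(max(abs(crossprod(Q) - diag(ncol(Q)))), 1e-8)
})

test_that("the QC -> impute -> standardize -> PC pipeline composes", {
  p <- panel120()
  g <- p$genotypes
  expect_false(anyNA(scoreMatrix(g)))
  pc <- p$pc
  expect_identical(nrow(scoreMatrix(pc)), 120L)
  M <- scoreMatrix(suppressWarnings(standardizeMarkers(g)))
  expect_lt(max(abs(tcrossprod(scoreMatrix(pc)) - tcrossprod(M))), 1e-8)
})
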