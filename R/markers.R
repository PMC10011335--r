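#' @include AllClasses.R AllGenerics.R
NULL

newGenotypeMatrix <- function(scores, imputed = FALSE, missing = is.na(scores)) {
  storage.mode(scores) <- "double"
  new("GenotypeMatrix", scores = scores, missing = missing, imputed = imputed)
}

#' Read coded SNP genotypes
#'
#' Reads an individuals-by-markers genotype matrix either from a CSV/TSV
#' matrix of already-coded scores or from a VCF file. Scores follow the
#' -1/0/1 coding: homozygote of the minor allele, heterozygote, homozygote of
#' the major allele. For VCF input the major/minor allele is determined per
#' locus from the observed allele counts, with ties broken toward the VCF
#' reference allele; missing GT calls become `NA`.
#'
#' @param path file path.
#' @param format `"csv-matrix"` (header row = marker ids, first column =
#'   individual ids, cells in \{-1, 0, 1, NA\}, comma- or tab-separated,
#'   autodetected) or `"vcf"` (VCF 4.x, GT field only; non-diploid records and
#'   multi-allelic sites are skipped with a warning).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("csv-matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv-matrix") readGenotypesCsv(path) else readGenotypesVcf(path)
}

readGenotypesCsv <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("genotype matrix contains non-numeric cells")
  bad <- !is.na(m) & !(m %in% c(-1, 0, 1))
  if (any(bad))
    stop(sum(bad), " coded values outside {-1, 0, 1, NA} in ", path)
  newGenotypeMatrix(m)
}

readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  ## strip phasing, count ALT alleles; anything non-diploid is dropped
  alleles <- function(x) strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
  n <- ncol(gt)
  scores <- matrix(NA_real_, nrow = n, ncol = nrow(gt),
                   dimnames = list(colnames(gt), paste0(fix[, "CHROM"], "_",
                                                        fix[, "POS"])))
  keep <- rep(TRUE, nrow(gt))
  for (j in seq_len(nrow(gt))) {
    parts <- alleles(gt[j, ])
    len2 <- lengths(parts) == 2L
    if (!any(len2)) { keep[j] <- FALSE; next }
    if (!all(len2)) warning("non-diploid call(s) at ", colnames(scores)[j],
                            " treated as missing")
    dose <- rep(NA_real_, n)  # ALT allele dose 0..2
    ok <- which(len2)
    a <- vapply(parts[ok], function(p)
      if (any(p == ".")) NA_real_ else sum(p != "0"), numeric(1))
    dose[ok] <- a
    obs <- dose[!is.na(dose)]
    if (!length(obs)) { keep[j] <- FALSE; next }
    altFreq <- sum(obs) / (2 * length(obs))
    ## major-hom -> 1, het -> 0, minor-hom -> -1; ties favour the REF allele
    refMajor <- altFreq <= 0.5
    scores[, j] <- ifelse(is.na(dose), NA_real_,
                          if (refMajor) 1 - dose else dose - 1)
  }
  scores <- scores[, keep, drop = FALSE]
  if (!ncol(scores)) stop("no usable biallelic diploid records in ", path)
  newGenotypeMatrix(scores)
}

#' Write a coded genotype matrix as CSV
#'
#' Inverse of [readGenotypes()] for the `csv-matrix` dialect.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesCsv <- function(g, path) {
  stopifnot(is(g, "GenotypeMatrix"))
  df <- data.frame(individual_id = individualIds(g), scoreMatrix(g),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-filter a genotype matrix
#'
#' Applies, in order: (1) markers with call rate below `callRateMin` are
#' removed; (2) individuals with missing rate above `indMissingMax` are
#' removed; (3) markers with minor allele frequency (computed on observed
#' calls of the retained grid) below `mafMin` are removed. Defaults express
#' the common published rules (call rate 0.9, individual missing rate 0.1, no
#' MAF filter).
#'
#' @param g a [GenotypeMatrix-class], not yet imputed.
#' @param callRateMin minimum fraction of non-missing calls per marker.
#' @param indMissingMax maximum fraction of missing calls per individual.
#' @param mafMin minimum minor allele frequency.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterQC <- function(g, callRateMin = 0.9, indMissingMax = 0.1, mafMin = 0) {
  stopifnot(is(g, "GenotypeMatrix"))
  stopifnot(callRateMin >= 0, callRateMin <= 1, indMissingMax >= 0,
            indMissingMax <= 1, mafMin >= 0, mafMin <= 1)
  s <- g@scores
  callRate <- 1 - colMeans(is.na(s))
  dropM1 <- callRate < callRateMin
  if (all(dropM1)) stop("all markers removed by the call-rate filter")
  s <- s[, !dropM1, drop = FALSE]
  indMiss <- rowMeans(is.na(s))
  dropI <- indMiss > indMissingMax
  if (all(dropI)) stop("all individuals removed by the missing-rate filter")
  if (sum(!dropI) < 2L) stop("fewer than 2 individuals left after filtering")
  s <- s[!dropI, , drop = FALSE]
  maf <- apply(s, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) return(0)
    pMajor <- mean(obs + 1) / 2   # frequency of the allele coded +1
    min(pMajor, 1 - pMajor)
  })
  dropM2 <- maf < mafMin
  if (all(dropM2)) stop("all markers removed by the MAF filter")
  s <- s[, !dropM2, drop = FALSE]
  message(sprintf(
    "filterQC: removed %d marker(s) by call rate, %d individual(s) by missing rate, %d marker(s) by MAF",
    sum(dropM1), sum(dropI), sum(dropM2)))
  newGenotypeMatrix(s)
}

#' Mean-impute missing genotype calls
#'
#' Replaces every missing entry by the mean of the observed values in its
#' marker column. Observed entries are untouched.
#'
#' @param g a [GenotypeMatrix-class].
#' @return an imputed [GenotypeMatrix-class] (no `NA` left; the original
#'   missingness mask is preserved).
#' @export
imputeMean <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  s <- g@scores
  nObs <- colSums(!is.na(s))
  if (any(nObs == 0L))
    stop("fully-missing marker column(s): ",
         paste(utils::head(colnames(s)[nObs == 0L], 5L), collapse = ", "),
         " (filter them out first)")
  mu <- colMeans(s, na.rm = TRUE)
  idx <- which(is.na(s), arr.ind = TRUE)
  if (nrow(idx)) s[idx] <- mu[idx[, 2L]]
  newGenotypeMatrix(s, imputed = TRUE, missing = g@missing)
}

#' Standardize a genotype matrix
#'
#' Computes m_ij = (x_ij - xbar_j) / s_j with the sample (n-1) standard
#' deviation. Zero-variance columns cannot be standardized and are dropped
#' with a warning.
#'
#' @param g a fully imputed [GenotypeMatrix-class].
#' @return a [StandardizedGenotypes-class].
#' @export
standardizeMarkers <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!isImputed(g) && anyNA(g@scores))
    stop("genotypes must be imputed before standardization")
  s <- g@scores
  if (nrow(s) < 2L) stop("need at least 2 individuals")
  mu <- colMeans(s)
  sds <- apply(s, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all markers have zero variance")
  if (any(!keep))
    warning(sum(!keep), " zero-variance marker(s) dropped during standardization")
  v <- sweep(sweep(s[, keep, drop = FALSE], 2L, mu[keep]), 2L, sds[keep], "/")
  new("StandardizedGenotypes", values = v, columnMeans = unname(mu[keep]),
      columnSds = unname(sds[keep]))
}

#' Principal-component scores of a standardized marker matrix
#'
#' Spectral decomposition of M'M (computed through the thin SVD of M, which
#' gives the identical result), retaining as many components as individuals
#' minus numerically null ones: components with eigenvalue
#' u_i <= tol * u_1 are truncated. The score matrix L = M Q satisfies
#' L L' = M M', so the pairwise inner products among individuals — all the
#' r-score and kinship computations need — are preserved exactly.
#'
#' @param m a [StandardizedGenotypes-class] (or any numeric matrix).
#' @param tol relative eigenvalue truncation tolerance.
#' @return a [PCScores-class].
#' @export
pcScores <- function(m, tol = 1e-10) {
  v <- if (is(m, "StandardizedGenotypes")) m@values else as.matrix(m)
  if (!all(is.finite(v))) stop("non-finite values in the standardized matrix")
  sv <- svd(v, nu = min(dim(v)), nv = min(dim(v)))
  ev <- sv$d^2
  keep <- ev > tol * ev[1]
  if (!any(keep)) stop("matrix is numerically null")
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(scores) <- rownames(v)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  new("PCScores", scores = scores, eigenvalues = ev[keep],
      loadings = sv$v[, keep, drop = FALSE])
}
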