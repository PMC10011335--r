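#' @include AllClasses.R
NULL

#' Validate a run configuration
#'
#' Checks a configuration list (parsed from YAML/JSON or assembled in code)
#' against the fields the pipeline needs, returning every problem found
#' rather than stopping at the first.
#'
#' @param config named list with (a subset of) the fields: `genotypes`
#'   (path), `format`, `scenario` (`"fixed"`/`"non-fixed"`), `method`
#'   (`"targeted"`/`"untargeted"`), `n_c`, `n_0`, `n_min`, `n_max`, `delta`,
#'   `m`, `targets`, `lambda`, `family`, `seed`, `clusters` (path),
#'   `phenotypes` (path), `out` (output prefix).
#' @param requireGenotypes whether a genotype source is mandatory.
#' @return character vector of error messages (length 0 when valid).
#' @export
validateRunConfig <- function(config, requireGenotypes = TRUE) {
  errs <- character()
  addIf <- function(cond, msg) if (isTRUE(cond)) errs <<- c(errs, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  if (requireGenotypes) {
    if (is.null(config$genotypes)) {
      errs <- c(errs, "field 'genotypes' (path to genotype file) is missing")
    } else addIf(!file.exists(config$genotypes),
                 paste0("genotype file not found: ", config$genotypes))
  }
  if (!is.null(config$format))
    addIf(!config$format %in% c("csv-matrix", "vcf"),
          "field 'format' must be 'csv-matrix' or 'vcf'")
  if (!is.null(config$scenario))
    addIf(!config$scenario %in% c("fixed", "non-fixed"),
          "field 'scenario' must be 'fixed' or 'non-fixed'")
  if (!is.null(config$method))
    addIf(!config$method %in% c("targeted", "untargeted"),
          "field 'method' must be 'targeted' or 'untargeted'")
  for (f in c("n_c", "n_0", "n_min", "n_max", "delta", "m", "seed")) {
    v <- config[[f]]
    if (!is.null(v))
      addIf(!num1(v) || v != round(v) || v < 0,
            paste0("field '", f, "' must be a non-negative integer"))
  }
  if (!is.null(config$targets)) {
    t <- config$targets
    addIf(!is.numeric(t) || !length(t) || any(!is.finite(t)) ||
            any(t <= 0 | t > 1),
          "field 'targets' must be numeric values in (0, 1]")
  }
  if (!is.null(config$lambda))
    addIf(!num1(config$lambda) || config$lambda <= 0,
          "field 'lambda' must be a positive number")
  if (!is.null(config$family))
    addIf(!config$family %in% c("logistic", "weibull"),
          "field 'family' must be 'logistic' or 'weibull'")
  for (f in c("clusters", "phenotypes"))
    if (!is.null(config[[f]]))
      addIf(!file.exists(config[[f]]),
            paste0(f, " file not found: ", config[[f]]))
  if (!is.null(config$n_min) && !is.null(config$n_max) &&
      num1(config$n_min) && num1(config$n_max)) {
    addIf(config$n_min >= config$n_max, "'n_min' must be < 'n_max'")
    if (!is.null(config$delta) && num1(config$delta) && config$delta >= 1)
      addIf((config$n_max - config$n_min) %% config$delta != 0,
            "'n_max - n_min' must be divisible by 'delta'")
  }
  errs
}

#' Read cluster labels from CSV
#'
#' Expects columns `individual_id` and `cluster`.
#'
#' @param path CSV file path.
#' @return named character vector of cluster labels.
#' @export
readClusters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "cluster") %in% names(df)))
    stop("cluster file needs columns 'individual_id' and 'cluster'")
  stats::setNames(as.character(df$cluster), df$individual_id)
}

#' Read a phenotype table from CSV
#'
#' Expects an `individual_id` column; every remaining numeric column is
#' treated as a trait.
#'
#' @param path CSV file path.
#' @return data.frame with rownames = individual ids and one column per
#'   trait.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df))
    stop("phenotype file needs an 'individual_id' column")
  rownames(df) <- df$individual_id
  df$individual_id <- NULL
  df
}
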