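#' Trimmed-mean-of-M-values normalization factors
#'
#' Composition-robust per-sample scaling factors: a precision-weighted
#' trimmed mean of per-gene log2 expression ratios (M-values) against a
#' reference sample, trimming 30% of M-values and 5% of A-values on each
#' tail, rescaled to geometric mean 1. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean across samples.
#'
#' @param counts nonnegative count matrix (miRNA x sample).
#' @return named numeric vector of factors with attribute
#'   \code{method = "tmm"}; geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  check_counts(counts)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  f <- stats::setNames(y$samples$norm.factors, colnames(counts))
  attr(f, "method") <- "tmm"
  f
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count-to-geometric-mean ratios over miRNAs with
#' all-positive counts (the pseudo-reference approach used by
#' negative-binomial Wald pipelines).
#'
#' @param counts nonnegative count matrix.
#' @return named numeric vector with attribute \code{method = "median_ratio"}.
#' @export
median_ratio_factors <- function(counts) {
  check_counts(counts)
  if (!any(rowSums(counts > 0) == ncol(counts)))
    stop("no miRNA has positive counts in every sample; ",
         "median-of-ratios needs at least one all-positive row ",
         "(pseudo-reference fallback is disabled)")
  f <- DESeq2::estimateSizeFactorsForMatrix(counts)
  f <- stats::setNames(as.numeric(f), colnames(counts))
  attr(f, "method") <- "median_ratio"
  f
}

#' Log2 counts-per-million
#'
#' \code{log2((count + prior) / (effective library size scaled consistently
#' with the prior) * 1e6)}: the per-sample prior is scaled by relative
#' library size so that doubling all counts and depths leaves values
#' unchanged.
#'
#' @param counts count matrix.
#' @param factors optional normalization factors (e.g. [tmm_factors()]);
#'   effective library size is \code{colSums(counts) * factors}.
#' @param prior_count prior added to counts before the log (default 0.5),
#'   expressed relative to a one-million-read library: each sample's prior is
#'   \code{prior_count * lib_size / 1e6}, which makes the transform exactly
#'   invariant to a global rescaling of counts and depths.
#' @return matrix of log2 CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  check_counts(counts)
  lib <- colSums(counts)
  if (!is.null(factors)) {
    if (any(factors <= 0)) stop("normalization factors must be positive")
    lib <- lib * as.numeric(factors)
  }
  prior <- prior_count * lib / 1e6
  log2(sweep(sweep(counts, 2, prior, "+"), 2, lib + 2 * prior, "/") * 1e6)
}

#' Average log2 CPM abundance per miRNA
#'
#' The abundance measure used for the expression filter (logCPM > threshold)
#' and reported as \code{logCPM} in engine results; computed once from the
#' TMM-normalized library sizes so that all engines share one filter
#' universe.
#'
#' @inheritParams log_cpm
#' @param prior_count prior count (default 2, the convention of
#'   likelihood-based count pipelines' reported logCPM).
#' @return numeric vector, one value per miRNA.
#' @export
avg_log_cpm <- function(counts, factors = NULL, prior_count = 2) {
  check_counts(counts)
  lib <- colSums(counts)
  if (!is.null(factors)) lib <- lib * as.numeric(factors)
  as.numeric(edgeR::aveLogCPM(counts, lib.size = lib,
                              prior.count = prior_count))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in (0, 1]; values outside are
#'   rejected. Exact zeros should be floored by the caller (engines floor at
#'   the smallest positive double before adjusting).
#' @return adjusted values, clipped at 1, in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must be numeric in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be nonnegative")
  invisible(counts)
}
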