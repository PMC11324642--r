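#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the median-of-ratios method: for sample j,
#' the median over eligible genes of K_ij / mu_i, where mu_i is gene i's
#' geometric mean across samples and a gene is eligible when all its counts
#' are positive (a single zero makes the geometric mean zero). The factors
#' are then rescaled so their geometric mean is exactly 1, leaving
#' normalized values on the counts scale. (The median is taken on the
#' ratio scale; DESeq2's estimator is the same construction with the
#' median on the log scale, which differs only in how an even number of
#' eligible genes is interpolated.)
#'
#' @param counts gene x sample matrix of non-negative counts with row and
#'   column names.
#' @return named positive numeric vector, one size factor per sample, with
#'   geometric mean 1 and the per-gene geometric means attached as
#'   attribute `reference_means`.
#' @export
size_factors <- function(counts) {
  counts <- check_count_matrix(counts)
  geo <- exp(rowMeans(log(counts)))  # 0 whenever a count is 0
  ok <- is.finite(geo) & geo > 0
  if (!any(ok))
    stopf("no gene with all-positive counts: size factors are undefined")
  s <- apply(counts, 2, function(col) median(col[ok] / geo[ok]))
  s <- s / exp(mean(log(s)))
  attr(s, "reference_means") <- geo
  s
}

check_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("count matrix needs at least 2 samples")
  if (any(counts < 0)) stopf("count matrix has negative entries")
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  counts
}

#' Normalize counts by size factors
#'
#' Divides each column by its size factor. With factors from
#' [size_factors()] this is median-of-ratios normalization; sequencing
#' depth and RNA-composition differences are divided out while the values
#' stay on the counts scale (factor geometric mean is 1).
#'
#' @param counts gene x sample count matrix.
#' @param s per-sample positive size factors; computed with
#'   [size_factors()] when omitted.
#' @return normalized matrix with the same dimnames; the size factors and
#'   per-gene geometric means are attached as attributes `size_factors`
#'   and `reference_means`.
#' @export
normalize_counts <- function(counts, s = NULL) {
  counts <- check_count_matrix(counts)
  if (is.null(s)) s <- size_factors(counts)
  if (length(s) != ncol(counts))
    stopf("length of size factors (%d) does not match sample count (%d)",
          length(s), ncol(counts))
  if (any(s <= 0)) stopf("size factors must be strictly positive")
  out <- sweep(counts, 2, s, `/`)
  attr(out, "size_factors") <- setNames(as.numeric(s), colnames(counts))
  attr(out, "reference_means") <- exp(rowMeans(log(counts)))
  out
}

#' log2(x + 1) transform of a normalized matrix
#'
#' The pipeline's default working scale for the weighting, penalized
#' selection and correlation stages: variance-compressing, defined at zero.
#'
#' @param x normalized (non-negative) matrix.
#' @return log2(x + 1), attributes dropped.
#' @export
log2_normalized <- function(x) {
  if (any(x < 0)) stopf("log2 transform expects non-negative values")
  log2(unclass(x) + 1)
}
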