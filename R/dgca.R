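#' @name dgca
#' @title Differential gene correlation analysis
#'
#' @description For every gene pair, the per-condition correlations are
#' mapped through the Fisher z-transformation `z = atanh(r)`, which is
#' approximately normal with variance `1/(n-3)` (Pearson) or `1.06/(n-3)`
#' (Spearman). The standardized difference
#' `dz = (z_stress - z_control) / sqrt(var_control + var_stress)` gets a
#' two-tailed standard-normal p-value, and each pair is labelled by the
#' per-condition correlation signs ("+", "0" or "-"; "0" when that
#' condition's correlation p-value is not below `sig_threshold`), rendered
#' control/stress, e.g. `"0/+"` for a pair uncorrelated in control but
#' positively correlated under stress.
NULL

#' Correlation of two expression vectors with a t-based p-value
#'
#' @param x,y numeric vectors of equal length n >= 4 (finite, non-constant).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `cor_result`: `r`, `p` (two-tailed, from
#'   `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 df), `n`, `method`.
#' @export
condition_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (length(x) < 4) stopf("need n >= 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant vector: correlation undefined")
  r <- cor(x, y, method = method)
  structure(list(r = r, p = cor_t_pvalue(r, length(x)),
                 n = length(x), method = method),
            class = "cor_result")
}

#' Two-tailed p-value of a correlation coefficient
#'
#' From the t statistic `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of
#' freedom; `|r| = 1` gives p = 0. Vectorized over `r`.
#'
#' @param r correlation coefficient(s).
#' @param n sample size behind the correlation (n >= 4).
#' @return two-tailed p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 4)) stopf("need n >= 4")
  cor_t_pvalue(r, n)
}

## two-tailed p from the t statistic on n-2 df; |r| = 1 gives p = 0
cor_t_pvalue <- function(r, n) {
  den <- pmax(1 - r^2, 0)
  p <- ifelse(den == 0, 0,
              2 * pt(-abs(r * sqrt(n - 2) / sqrt(den)), df = n - 2))
  pmin(p, 1)
}

#' Fisher z-transformation
#'
#' `z = atanh(r) = 0.5 * ln((1+r)/(1-r))`. Correlations with
#' `|r| >= 1 - 1e-12` are clamped to that bound with a warning so degenerate
#' inputs stay finite.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @return z-score(s).
#' @export
fisher_z <- function(r) {
  bound <- 1 - 1e-12
  if (any(abs(r) > bound)) {
    warning("correlation(s) with |r| >= 1 - 1e-12 clamped before atanh")
    r <- pmin(pmax(r, -bound), bound)
  }
  atanh(r)
}

#' Variance of a Fisher z-score
#'
#' `1/(n-3)` for Pearson and `1.06/(n-3)` for Spearman correlations.
#'
#' @param n sample size behind the correlation (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @export
correlation_variance <- function(n, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (any(n <= 3)) stopf("z-score variance needs n >= 4")
  (if (method == "spearman") 1.06 else 1) / (n - 3)
}

#' Standardized difference of two correlations
#'
#' `dz = (z_stress - z_control) / sqrt(var_control + var_stress)` with the
#' per-condition z-score variances pooled in the denominator, and the
#' two-tailed p-value `2 * (1 - Phi(|dz|))`. Vectorized over correlations.
#'
#' @param r_control,r_stress per-condition correlations.
#' @param n_control,n_stress per-condition sample sizes (>= 4).
#' @inheritParams correlation_variance
#' @return list with `dz` and `pValDiff`.
#' @export
dz_statistic <- function(r_control, n_control, r_stress, n_stress,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- correlation_variance(n_control, method) +
    correlation_variance(n_stress, method)
  dz <- (fisher_z(r_stress) - fisher_z(r_control)) / sqrt(v)
  list(dz = dz, pValDiff = 2 * pnorm(-abs(dz)))
}

#' Class label of a differentially correlated pair
#'
#' Per condition the sign is "0" if that condition's correlation p-value is
#' >= `sig_threshold`, otherwise the sign of r; the label is rendered
#' control/stress (e.g. `"0/+"`, `"+/-"`). Accepts `cor_result` objects or
#' raw `r`/`p` vectors (vectorized).
#'
#' @param control,stress `cor_result` objects, or numeric correlation(s)
#'   when `p_control`/`p_stress` are given.
#' @param p_control,p_stress per-condition correlation p-values (only when
#'   `control`/`stress` are numeric).
#' @param sig_threshold per-condition significance cutoff (default 0.05).
#' @return character label(s).
#' @export
classify_pair <- function(control, stress, p_control = NULL, p_stress = NULL,
                          sig_threshold = 0.05) {
  if (inherits(control, "cor_result")) {
    p_control <- control$p; control <- control$r
  }
  if (inherits(stress, "cor_result")) {
    p_stress <- stress$p; stress <- stress$r
  }
  sgn <- function(r, p) ifelse(p >= sig_threshold, "0",
                               ifelse(r > 0, "+", "-"))
  paste0(sgn(control, p_control), "/", sgn(stress, p_stress))
}

#' All-pairs differential correlation scan
#'
#' Computes, for every unordered pair within a gene set, the per-condition
#' correlations and p-values, the z-score difference `dz` and its two-tailed
#' p-value, and the class label — one row per pair, `m(m-1)/2` rows for m
#' genes.
#'
#' @param X gene x sample expression matrix (log2 normalized values by
#'   default in the pipeline).
#' @param design data.frame with `sample_id` and `condition` matching the
#'   columns of `X` (or a label vector).
#' @param genes optional character vector restricting (and ordering) the
#'   panel; default all rows of `X`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param sig_threshold per-condition significance cutoff for class signs.
#' @return data.frame with columns `gene1`, `gene2`, `control_cor`,
#'   `control_pVal`, `stress_cor`, `stress_pVal`, `zScoreDiff`, `pValDiff`,
#'   `Classes`.
#' @export
dgca_all_pairs <- function(X, design, genes = NULL,
                           method = c("pearson", "spearman"),
                           sig_threshold = 0.05) {
  method <- match.arg(method)
  X <- as.matrix(X)
  cond <- if (is.data.frame(design)) design$condition else as.character(design)
  if (length(cond) != ncol(X)) stopf("design does not match sample count")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing))
      stopf("genes absent from the matrix: %s", paste(missing, collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  m <- nrow(X)
  if (m < 2) stopf("need a gene set of size >= 2")
  nc <- sum(cond == "control"); ns <- sum(cond == "stress")
  if (nc < 4 || ns < 4) stopf("each condition needs >= 4 samples")

  Rc <- cor(t(X[, cond == "control", drop = FALSE]), method = method)
  Rs <- cor(t(X[, cond == "stress", drop = FALSE]), method = method)
  idx <- which(upper.tri(Rc), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  rc <- Rc[idx]; rs <- Rs[idx]
  if (anyNA(rc) || anyNA(rs))
    stopf("constant gene in a condition: correlation undefined")
  pc <- cor_t_pvalue(rc, nc)
  ps <- cor_t_pvalue(rs, ns)
  d <- dz_statistic(rc, nc, rs, ns, method)
  data.frame(gene1 = rownames(X)[idx[, "row"]],
             gene2 = rownames(X)[idx[, "col"]],
             control_cor = rc, control_pVal = pc,
             stress_cor = rs, stress_pVal = ps,
             zScoreDiff = d$dz, pValDiff = d$pValDiff,
             Classes = classify_pair(rc, rs, pc, ps, sig_threshold),
             stringsAsFactors = FALSE)
}

#' Top differentially correlated pairs
#'
#' Sorts pair records ascending by `pValDiff` (or descending by `|dz|`),
#' breaking ties by larger `|dz|` then lexicographic gene ids, and returns
#' the first `k` records or all records with `pValDiff < p_cutoff`.
#'
#' @param records data.frame from [dgca_all_pairs()].
#' @param by primary sort key: `"pValDiff"` (default) or `"dz"`.
#' @param k number of top pairs to keep (all, if larger than the record
#'   count).
#' @param p_cutoff alternatively, keep all pairs with `pValDiff` below this.
#' @return sorted subset of `records`.
#' @export
top_pairs <- function(records, by = c("pValDiff", "dz"), k = NULL,
                      p_cutoff = NULL) {
  by <- match.arg(by)
  if (!nrow(records)) stopf("no pair records")
  o <- if (by == "pValDiff")
    order(records$pValDiff, -abs(records$zScoreDiff),
          records$gene1, records$gene2)
  else
    order(-abs(records$zScoreDiff), records$pValDiff,
          records$gene1, records$gene2)
  out <- records[o, , drop = FALSE]
  if (!is.null(p_cutoff)) out <- out[out$pValDiff < p_cutoff, , drop = FALSE]
  if (!is.null(k)) out <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
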