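#' @name attribute-weighting
#' @title Attribute-weighting gene selectors
#'
#' @description Four filter-style selectors scoring every gene's ability to
#' discriminate control from stress samples, each returning weights min-max
#' normalized to \[0, 1\] so the top gene always scores exactly 1. Genes
#' with weight above a threshold (default 0.90) are selected with
#' [select_by_threshold()].
#'
#' @param X gene x sample expression matrix (typically
#'   `log2_normalized(normalize_counts(counts))`), rows named by gene.
#' @param y condition labels: a factor/character with values `control` and
#'   `stress` (or anything binary), or a design data.frame with a
#'   `condition` column, aligned with the columns of `X`.
#' @return a `weight_table`: data.frame with columns `gene_id`, `weight`
#'   (in \[0, 1\]), plus attributes `method` and `parameters`.
NULL

## label vector -> 0/1 numeric (stress/second level = 1)
encode_labels <- function(y, n) {
  if (is.data.frame(y)) y <- y$condition
  y <- as.character(y)
  if (length(y) != n) stopf("labels (%d) do not match sample count (%d)", length(y), n)
  lev <- sort(unique(y))
  if (length(lev) != 2)
    stopf("condition labels must be binary with both classes present (got: %s)",
          paste(lev, collapse = ", "))
  if (all(c("control", "stress") %in% lev)) lev <- c("control", "stress")
  as.numeric(y == lev[2])
}

minmax <- function(w) {
  w[!is.finite(w)] <- 0
  lo <- min(w); hi <- max(w)
  if (hi == lo) return(if (hi > 0) rep(1, length(w)) else rep(0, length(w)))
  (w - lo) / (hi - lo)
}

weight_table <- function(gene_ids, raw, method, parameters) {
  raw <- as.numeric(raw)
  raw[!is.finite(raw)] <- 0
  structure(data.frame(gene_id = gene_ids, weight = minmax(raw),
                       stringsAsFactors = FALSE),
            method = method, parameters = parameters, raw = setNames(raw, gene_ids),
            class = c("weight_table", "data.frame"))
}

#' @describeIn attribute-weighting absolute Pearson correlation between each
#'   gene's expression vector and the 0/1 condition label; constant genes
#'   get raw weight 0.
#' @export
weight_by_correlation <- function(X, y) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stopf("correlation weighting needs at least 3 samples")
  y01 <- encode_labels(y, ncol(X))
  r <- suppressWarnings(as.numeric(cor(t(X), y01)))
  r[is.na(r)] <- 0
  weight_table(rownames(X), abs(r), "correlation", list())
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @describeIn attribute-weighting symmetric uncertainty
#'   `2 I(G;Y) / (H(G) + H(Y))` after equal-frequency discretization of each
#'   gene into at most `bins` bins; degenerate discretizations (one bin)
#'   score 0.
#' @param bins number of equal-frequency bins for the uncertainty selector.
#' @export
weight_by_uncertainty <- function(X, y, bins = 5) {
  if (bins < 2) stopf("bins must be >= 2")
  X <- as.matrix(X)
  y01 <- encode_labels(y, ncol(X))
  hy <- entropy2(table(y01) / length(y01))
  raw <- apply(X, 1, function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 3) {  # <2 bins after dropping duplicate breaks
      g <- if (length(unique(x)) >= 2) as.integer(x > br[1]) else rep(0L, length(x))
      if (length(unique(g)) < 2) return(0)
    } else {
      g <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
    }
    joint <- table(g, y01) / length(x)
    hg <- entropy2(rowSums(joint))
    hj <- entropy2(as.numeric(joint))
    mi <- hg + hy - hj
    if (hg + hy == 0) 0 else 2 * mi / (hg + hy)
  })
  weight_table(rownames(X), raw, "uncertainty", list(bins = bins))
}

#' @describeIn attribute-weighting Relief: features are min-max scaled, a
#'   deterministic pass visits every instance (or the first `n_iterations`)
#'   in index order, finds the nearest same-class hit and other-class miss
#'   by Manhattan distance (ties to the lowest sample index; averaged over
#'   `n_neighbors` nearest of each), and accumulates
#'   `(diff to miss - diff to hit) / n_iterations` per feature.
#' @param n_neighbors nearest hits/misses averaged per visited instance;
#'   default `min(10, smallest class size - 1)`, the usual multi-neighbor
#'   (ReliefF) setting, which is much more stable than a single neighbor on
#'   noisy expression data.
#' @param n_iterations instances visited (default: all, once each).
#' @export
weight_by_relief <- function(X, y, n_neighbors = NULL, n_iterations = NULL) {
  X <- as.matrix(X)
  n <- ncol(X)
  y01 <- encode_labels(y, n)
  cls_min <- min(table(y01))
  if (is.null(n_neighbors)) n_neighbors <- max(1L, min(10L, cls_min - 1L))
  if (cls_min < n_neighbors + 1)
    stopf("each class needs at least n_neighbors + 1 samples for Relief")
  if (is.null(n_iterations) || n_iterations > n) n_iterations <- n
  ## scale features to [0,1]; constant features become all-zero
  rng <- apply(X, 1, range)
  span <- rng[2, ] - rng[1, ]
  Z <- (X - rng[1, ]) / ifelse(span == 0, 1, span)
  D <- as.matrix(dist(t(Z), method = "manhattan"))
  W <- numeric(nrow(X))
  for (i in seq_len(n_iterations)) {
    d <- D[i, ]
    d[i] <- Inf
    pick <- function(idx) idx[order(d[idx], idx)[seq_len(n_neighbors)]]
    hits <- pick(which(y01 == y01[i] & seq_len(n) != i))
    misses <- pick(which(y01 != y01[i]))
    dh <- rowMeans(abs(Z[, hits, drop = FALSE] - Z[, i]))
    dm <- rowMeans(abs(Z[, misses, drop = FALSE] - Z[, i]))
    W <- W + (dm - dh) / n_iterations
  }
  weight_table(rownames(X), W, "relief",
               list(n_neighbors = n_neighbors, n_iterations = n_iterations))
}

#' @describeIn attribute-weighting absolute coefficients of a linear
#'   soft-margin SVM hyperplane fitted on standardized features
#'   (zero mean, unit variance); larger |w| marks a gene with more influence
#'   on the decision boundary.
#' @param regularization SVM cost parameter C.
#' @export
weight_by_svm <- function(X, y, regularization = 1) {
  X <- as.matrix(X)
  y01 <- encode_labels(y, ncol(X))
  if (min(table(y01)) < 2) stopf("SVM weighting needs >= 2 samples per class")
  Z <- t(X)
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, sd)
  keep <- sdv > 0
  Zs <- sweep(sweep(Z[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
  fit <- e1071::svm(x = Zs, y = factor(y01), kernel = "linear",
                    cost = regularization, scale = FALSE)
  w <- numeric(nrow(X))
  w[keep] <- abs(as.numeric(crossprod(fit$coefs, fit$SV)))
  weight_table(rownames(X), w, "svm", list(cost = regularization))
}

#' Select genes above a weight threshold
#'
#' Returns genes with weight strictly above `tau`, plus any gene with
#' weight exactly 1 (each method's top-ranked gene always passes).
#'
#' @param weights a `weight_table` (or data.frame with `gene_id`, `weight`).
#' @param tau selection threshold in (0, 1]; default 0.90.
#' @return sorted character vector of selected gene ids.
#' @export
select_by_threshold <- function(weights, tau = 0.90) {
  if (!is.numeric(tau) || tau <= 0 || tau > 1)
    stopf("threshold tau must lie in (0, 1]")
  sort(weights$gene_id[weights$weight > tau | weights$weight == 1])
}
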