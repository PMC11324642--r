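#' L1-penalized logistic gene selection
#'
#' The penalized-selection stage: an L1-regularized logistic regression of
#' condition on standardized per-gene expression shrinks the coefficients
#' of uninformative genes exactly to zero; the penalty is chosen by
#' stratified k-fold cross-validation and the one-standard-error rule
#' (`lambda.1se`), giving a sparse panel. Fitting is delegated to
#' \pkg{glmnet}, whose objective is `NLL/n + lambda * ||beta||_1` with an
#' unpenalized intercept, so all coefficients are zero at
#' `lambda_max = max_g |sum_j x_gj (y_j - ybar)| / n`.
#'
#' @name lasso-selection
NULL

## standardize samples x genes; constant genes stay at 0
standardize_features <- function(Z) {
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(Z, 2, mu), 2, sdv, `/`)
}

#' @describeIn lasso-selection analytic smallest penalty with an all-zero
#'   solution, computed on standardized features.
#' @export
lambda_max <- function(X, y) {
  Z <- standardize_features(t(as.matrix(X)))
  y01 <- encode_labels(y, nrow(Z))
  max(abs(crossprod(Z, y01 - mean(y01)))) / nrow(Z)
}

default_lambda_grid <- function(lmax, nlambda = 100, min_ratio = 1e-4) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' @describeIn lasso-selection fit the coefficient path over a descending
#'   penalty grid (default: 100 log-spaced values from `lambda_max` down to
#'   `1e-4 * lambda_max`).
#' @param X gene x sample expression matrix (standardized internally).
#' @param y binary condition labels (see [weight_by_correlation()]).
#' @param lambda optional descending penalty grid.
#' @return `fit_lasso_path`: list with `lambda`, `beta` (gene x lambda
#'   matrix), `a0`, `gene_ids` and the glmnet fit.
#' @export
fit_lasso_path <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  Z <- standardize_features(t(X))
  y01 <- encode_labels(y, nrow(Z))
  if (is.null(lambda)) lambda <- default_lambda_grid(lambda_max(X, y))
  if (is.unsorted(rev(lambda))) stopf("lambda grid must be descending")
  fit <- glmnet::glmnet(Z, y01, family = "binomial", lambda = lambda,
                        standardize = FALSE, thresh = 1e-10)
  beta <- as.matrix(fit$beta)
  rownames(beta) <- rownames(X)
  list(lambda = fit$lambda, beta = beta, a0 = fit$a0,
       gene_ids = rownames(X), fit = fit)
}

stratified_folds <- function(y01, folds, seed) {
  if (folds < 2) stopf("folds must be >= 2")
  if (min(table(y01)) < folds)
    stopf("cannot build %d stratified folds with both classes in every fold: smallest class has %d samples; reduce folds or change the fold seed",
          folds, min(table(y01)))
  set.seed(seed)
  foldid <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    foldid[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  }
  foldid
}

#' @describeIn lasso-selection choose the penalty by stratified k-fold
#'   cross-validation of the held-out binomial deviance; `lambda_min`
#'   minimizes the CV curve and `lambda_1se` is the largest penalty within
#'   one standard error of that minimum.
#' @param folds number of CV folds (default 10).
#' @param seed seed fixing the fold assignment.
#' @return `cross_validate_lambda`: object of class `lasso_cv` with
#'   `lambda`, `cv_mean`, `cv_se`, `n_nonzero`, `lambda_min`, `lambda_1se`,
#'   `gene_ids` and the underlying `cv.glmnet` fit.
#' @export
cross_validate_lambda <- function(X, y, folds = 10, seed = 1, lambda = NULL) {
  X <- as.matrix(X)
  Z <- standardize_features(t(X))
  y01 <- encode_labels(y, nrow(Z))
  if (is.null(lambda)) lambda <- default_lambda_grid(lambda_max(X, y))
  foldid <- stratified_folds(y01, folds, seed)
  cvfit <- glmnet::cv.glmnet(Z, y01, family = "binomial", lambda = lambda,
                             foldid = foldid, standardize = FALSE,
                             type.measure = "deviance", thresh = 1e-10)
  structure(list(lambda = cvfit$lambda, cv_mean = cvfit$cvm,
                 cv_se = cvfit$cvsd, n_nonzero = cvfit$nzero,
                 lambda_min = cvfit$lambda.min, lambda_1se = cvfit$lambda.1se,
                 gene_ids = rownames(X), folds = folds, seed = seed,
                 fit = cvfit),
            class = "lasso_cv")
}

#' @describeIn lasso-selection gene ids with nonzero coefficient at the
#'   chosen penalty.
#' @param result a `lasso_cv` from [cross_validate_lambda()].
#' @param which `"1se"` (default, the sparser one-standard-error choice) or
#'   `"min"`.
#' @export
selected_genes <- function(result, which = c("1se", "min")) {
  which <- match.arg(which)
  s <- if (which == "1se") result$lambda_1se else result$lambda_min
  b <- as.numeric(coef(result$fit, s = s))[-1]  # drop intercept
  sort(result$gene_ids[b != 0])
}
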