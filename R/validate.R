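#' @name panel-validation
#' @title Validation of a selected gene panel
#'
#' @description A selected panel is validated by (i) a 100-tree random
#' forest with its out-of-bag misclassification error, accuracy and AUC,
#' (ii) additive per-sample per-gene Shapley attributions whose sum
#' reconstructs each sample's predicted score exactly, and (iii) a
#' shadow-feature confirmation loop: each run adds column-shuffled copies
#' of the undecided genes, refits a forest with permutation importance, and
#' scores a "hit" for every gene beating the best shadow; hit counts are
#' tested against a fair coin (Bonferroni-corrected binomial tests) until
#' genes are Confirmed or Rejected, with a rough fix adjudicating leftovers
#' by median importance.
NULL

rf_labels <- function(y, n) {
  if (is.data.frame(y)) y <- y$condition
  y <- as.character(y)
  if (length(y) != n) stopf("labels do not match sample count")
  lev <- sort(unique(y))
  if (length(lev) != 2) stopf("need exactly two classes, both present")
  if (all(c("control", "stress") %in% lev)) lev <- c("control", "stress")
  factor(y, levels = lev)
}

#' Train a random-forest classifier on a gene panel
#'
#' A probability forest (default 100 trees, bootstrap per tree, sqrt(p)
#' candidate features per split) via \pkg{ranger}; the out-of-bag error is
#' the misclassification rate of the out-of-bag probability votes at the
#' 0.5 threshold.
#'
#' @param X gene x sample expression matrix restricted to the panel.
#' @param y binary condition labels.
#' @param n_trees trees in the ensemble (default 100).
#' @param seed seed for the forest (fixed seed, identical refit).
#' @return list of class `rf_validation`: `model`, `oob_error`,
#'   `oob_scores` (OOB probability of the positive/stress class),
#'   `classes`, `gene_ids`, `n_trees`, `seed`.
#' @export
train_random_forest <- function(X, y, n_trees = 100, seed = 1) {
  X <- as.matrix(X)
  yf <- rf_labels(y, ncol(X))
  if (min(table(yf)) < 2) stopf("need >= 2 samples per class")
  Z <- t(X)
  fit <- ranger::ranger(x = Z, y = yf, num.trees = n_trees,
                        probability = TRUE, seed = seed,
                        mtry = floor(sqrt(nrow(X))))
  pos <- levels(yf)[2]
  scores <- fit$predictions[, pos]
  pred <- ifelse(scores > 0.5, levels(yf)[2], levels(yf)[1])
  structure(list(model = fit, oob_error = mean(pred != as.character(yf)),
                 oob_scores = scores, classes = levels(yf),
                 gene_ids = rownames(X), n_trees = n_trees, seed = seed),
            class = "rf_validation")
}

rank_auc <- function(scores, y01) {
  r <- rank(scores)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a panel classifier
#'
#' `"oob"` scores the training forest's out-of-bag probability votes;
#' `"kfold"` refits the forest per stratified fold and pools the held-out
#' scores. Accuracy uses the 0.5 threshold; AUC is the Mann-Whitney rank
#' statistic over the scores, with ROC points from \pkg{pROC}.
#'
#' @param model an `rf_validation` from [train_random_forest()].
#' @param X,y the panel matrix and labels (needed for refitting under
#'   `"kfold"`, and for the labels under both protocols).
#' @param protocol `"oob"` (default) or `"kfold"`.
#' @param folds folds for the `"kfold"` protocol.
#' @return list: `accuracy`, `auc`, `roc_points` (data.frame fpr/tpr),
#'   `protocol`, `scores`.
#' @export
evaluate_model <- function(model, X, y, protocol = c("oob", "kfold"),
                           folds = 5) {
  protocol <- match.arg(protocol)
  X <- as.matrix(X)
  yf <- rf_labels(y, ncol(X))
  if (length(unique(yf)) < 2) stopf("evaluation labels contain one class")
  y01 <- as.numeric(yf == levels(yf)[2])
  if (protocol == "oob") {
    scores <- model$oob_scores
  } else {
    foldid <- stratified_folds(y01, folds, model$seed)
    scores <- numeric(length(y01))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- ranger::ranger(x = t(X[, tr, drop = FALSE]),
                            y = yf[tr], num.trees = model$n_trees,
                            probability = TRUE, seed = model$seed + f,
                            mtry = floor(sqrt(nrow(X))))
      scores[!tr] <- predict(fit, data = t(X[, !tr, drop = FALSE]))$predictions[, levels(yf)[2]]
    }
  }
  acc <- mean((scores > 0.5) == (y01 == 1))
  roc <- pROC::roc(response = y01, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  list(accuracy = acc, auc = rank_auc(scores, y01),
       roc_points = data.frame(fpr = rev(1 - roc$specificities),
                               tpr = rev(roc$sensitivities)),
       protocol = protocol, scores = scores)
}

#' Additive Shapley attributions for a forest on a gene panel
#'
#' Interventional permutation-sampling Shapley values against a background
#' dataset: for each sampled feature ordering, features are switched from
#' background to the explained sample one at a time and the change in mean
#' predicted score is credited to the switched feature. Every ordering's
#' credits telescope to `f(x) - base_value` exactly, so additivity
#' `base_value + sum_g phi_g = f(x)` holds exactly for every sample at any
#' number of sampled orderings.
#'
#' @param model an `rf_validation`.
#' @param X gene x sample panel matrix to explain.
#' @param background background matrix (default `X`).
#' @param n_perm sampled feature orderings (default 20).
#' @param seed seed for the orderings.
#' @return list: `phi` (sample x gene attribution matrix), `base_value`
#'   (mean predicted score of the background), `prediction` (per-sample
#'   model score), `ranking` (data.frame of genes by mean |phi|,
#'   descending, ties by gene id).
#' @export
shap_attributions <- function(model, X, background = NULL, n_perm = 20,
                              seed = 1) {
  X <- as.matrix(X)
  if (!identical(rownames(X), model$gene_ids))
    stopf("panel genes do not match the fitted model")
  Z <- t(X)                      # samples x genes
  B <- if (is.null(background)) Z else t(as.matrix(background))
  p <- ncol(Z); n <- nrow(Z); nb <- nrow(B)
  pos <- model$classes[2]
  f <- function(M) {
    colnames(M) <- colnames(Z)
    predict(model$model, data = M)$predictions[, pos]
  }
  base_value <- mean(f(B))
  prediction <- f(Z)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
  phi <- matrix(0, n, p, dimnames = list(rownames(Z), colnames(Z)))
  ## big matrix: for each explained sample, a copy of the background
  big <- B[rep(seq_len(nb), times = n), , drop = FALSE]
  samp_of_row <- rep(seq_len(n), each = nb)
  for (perm in perms) {
    cur <- big
    prev <- rep(base_value, n)
    for (j in perm) {
      cur[, j] <- Z[samp_of_row, j]
      m <- as.numeric(tapply(f(cur), samp_of_row, mean))
      phi[, j] <- phi[, j] + (m - prev) / n_perm
      prev <- m
    }
  }
  mean_abs <- colMeans(abs(phi))
  ranking <- data.frame(gene_id = colnames(Z), mean_abs_phi = mean_abs,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi, ranking$gene_id), ]
  rownames(ranking) <- NULL
  list(phi = phi, base_value = base_value, prediction = prediction,
       ranking = ranking)
}

## two-sided exact binomial p-value for h hits in r fair-coin runs
binom_two_sided <- function(h, r) {
  pmin(1, 2 * pmin(pbinom(h, r, 0.5), 1 - pbinom(h - 1, r, 0.5)))
}

#' Shadow-feature (Boruta-style) all-relevant gene selection
#'
#' Each run appends column-shuffled shadow copies of every still-undecided
#' gene (padded to at least 5 shadows), fits a random forest with
#' permutation importance, and records a hit for each undecided gene whose
#' importance exceeds the maximum shadow importance. After every run a
#' two-sided binomial test against a fair coin (Bonferroni-corrected across
#' the initial genes at `alpha`) Confirms genes with significantly many
#' hits and Rejects those with significantly few; Rejected genes are
#' dropped from subsequent forests. Genes still undecided after `max_runs`
#' remain Tentative.
#'
#' @param X gene x sample expression matrix.
#' @param y binary condition labels.
#' @param max_runs maximum runs (default 100).
#' @param alpha familywise significance level of the hit tests.
#' @param n_trees trees per forest.
#' @param seed master seed for shuffles and forests.
#' @return list of class `boruta_result`: `decision` (named:
#'   Confirmed/Tentative/Rejected), `hits`, `runs` (runs each gene was
#'   present in), `max_runs`, `alpha`, `importance_history` (run x gene,
#'   NA when absent), `shadow_max` (per-run maximum shadow importance).
#' @export
boruta <- function(X, y, max_runs = 100, alpha = 0.01, n_trees = 100,
                   seed = 1) {
  X <- as.matrix(X)
  yf <- rf_labels(y, ncol(X))
  p <- nrow(X)
  genes <- rownames(X)
  if (is.null(genes)) genes <- paste0("f", seq_len(p))
  Z <- t(X)
  decision <- setNames(rep("Tentative", p), genes)
  hits <- setNames(integer(p), genes)
  runs <- setNames(integer(p), genes)
  imp_hist <- matrix(NA_real_, max_runs, p, dimnames = list(NULL, genes))
  shadow_max <- rep(NA_real_, max_runs)
  set.seed(seed)
  n_runs <- 0L
  for (run in seq_len(max_runs)) {
    und <- which(decision == "Tentative")
    if (!length(und)) break
    n_runs <- run
    keep <- which(decision != "Rejected")
    sh_src <- rep_len(und, max(5L, length(und)))    # pad shadows to >= 5
    shadows <- apply(Z[, sh_src, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0("shadow_", seq_along(sh_src))
    D <- cbind(Z[, keep, drop = FALSE], shadows)
    fit <- ranger::ranger(x = D, y = yf, num.trees = n_trees,
                          importance = "permutation", seed = seed + run,
                          mtry = floor(sqrt(ncol(D))))
    imp <- fit$variable.importance
    smax <- max(imp[grepl("^shadow_", names(imp))])
    shadow_max[run] <- smax
    gi <- imp[genes[keep]]
    imp_hist[run, keep] <- gi
    hit <- genes[und][imp[genes[und]] > smax]
    hits[hit] <- hits[hit] + 1L
    runs[und] <- runs[und] + 1L
    pv <- binom_two_sided(hits[und], runs[und])
    sig <- pv < alpha / p
    decision[und][sig & hits[und] > runs[und] / 2] <- "Confirmed"
    decision[und][sig & hits[und] < runs[und] / 2] <- "Rejected"
  }
  structure(list(decision = decision, hits = hits, runs = runs,
                 max_runs = max_runs, alpha = alpha,
                 importance_history = imp_hist[seq_len(max(n_runs, 1L)), ,
                                               drop = FALSE],
                 shadow_max = shadow_max[seq_len(max(n_runs, 1L))],
                 seed = seed),
            class = "boruta_result")
}

#' Adjudicate Tentative shadow-selection genes
#'
#' Each Tentative gene becomes Confirmed if its median importance across
#' the runs it took part in exceeds the median of the per-run maximum
#' shadow importances, otherwise Rejected; Confirmed and Rejected genes are
#' unchanged.
#'
#' @param result a `boruta_result`.
#' @return the result with a `final_decision` element added.
#' @export
tentative_rough_fix <- function(result) {
  final <- result$decision
  tent <- names(final)[final == "Tentative"]
  if (length(tent)) {
    med_shadow <- median(result$shadow_max, na.rm = TRUE)
    med_imp <- apply(result$importance_history[, tent, drop = FALSE], 2,
                     median, na.rm = TRUE)
    final[tent] <- ifelse(med_imp > med_shadow, "Confirmed", "Rejected")
  }
  result$final_decision <- final
  result
}
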