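#' Union of per-method and penalized-selection gene sets
#'
#' The consensus panel fed to the differential-correlation stage: the
#' deduplicated, sorted union of the four attribute-weighting selections
#' and the L1-logistic selection.
#'
#' @param method_sets list (or single character vector) of per-method gene
#'   id sets.
#' @param lasso_set gene ids selected at `lambda.1se`.
#' @return sorted character vector.
#' @export
union_selected <- function(method_sets, lasso_set = character(0)) {
  if (!is.list(method_sets)) method_sets <- list(method_sets)
  sort(unique(c(unlist(method_sets, use.names = FALSE), lasso_set)))
}

#' Intersection of two gene sets with its cardinality
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `genes` (sorted) and `n`.
#' @export
intersect_sets <- function(set_a, set_b) {
  g <- sort(intersect(unique(set_a), unique(set_b)))
  list(genes = g, n = length(g))
}

#' Distinct genes appearing in a set of top pairs
#'
#' @param records data.frame of pair records with `gene1`/`gene2` columns.
#' @return sorted character vector of the distinct gene ids.
#' @export
genes_in_top_pairs <- function(records) {
  if (!nrow(records)) stopf("no pair records")
  sort(unique(c(records$gene1, records$gene2)))
}

#' Pipeline configuration
#'
#' Every tunable of the multi-method selection pipeline, defaulting to the
#' study's settings: weight threshold `tau = 0.90`, 10 CV folds with the
#' one-standard-error rule, Pearson differential correlation with
#' per-condition significance 0.05 and pair cutoff `pValDiff < 0.01`, the
#' top 10 pairs defining the validation panel, 100-tree forests, and a
#' 100-run shadow-feature loop at `alpha = 0.01`.
#'
#' @param tau attribute-weight selection threshold in (0, 1].
#' @param bins equal-frequency bins for the uncertainty selector.
#' @param relief_neighbors nearest hits/misses per Relief instance
#'   (NULL: the selector's auto default, min(10, class size - 1)).
#' @param svm_cost linear-SVM cost.
#' @param folds CV folds for the penalized selection.
#' @param lasso_rule `"1se"` or `"min"`.
#' @param dgca_method `"pearson"` or `"spearman"`.
#' @param sig_threshold per-condition correlation significance for class
#'   signs.
#' @param p_diff_cutoff `pValDiff` cutoff counting significantly changed
#'   pairs.
#' @param top_k top pairs whose genes form the validation panel.
#' @param n_trees forest size.
#' @param boruta_runs,boruta_alpha shadow-feature loop settings.
#' @param boruta_on `"all"` (shadow selection on the full matrix, the
#'   default) or `"panel"` (on the consensus union only).
#' @param log_transform work on `log2(normalized + 1)` (default) rather
#'   than raw normalized values.
#' @param shap_perm sampled orderings for the Shapley attributions.
#' @param seed master seed (folds, forests, shuffles).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(tau = 0.90, bins = 5, relief_neighbors = NULL,
                            svm_cost = 1, folds = 10,
                            lasso_rule = c("1se", "min"),
                            dgca_method = c("pearson", "spearman"),
                            sig_threshold = 0.05, p_diff_cutoff = 0.01,
                            top_k = 10, n_trees = 100, boruta_runs = 100,
                            boruta_alpha = 0.01,
                            boruta_on = c("all", "panel"),
                            log_transform = TRUE, shap_perm = 20, seed = 1) {
  cfg <- list(tau = tau, bins = bins, relief_neighbors = relief_neighbors,
              svm_cost = svm_cost, folds = folds,
              lasso_rule = match.arg(lasso_rule),
              dgca_method = match.arg(dgca_method),
              sig_threshold = sig_threshold, p_diff_cutoff = p_diff_cutoff,
              top_k = top_k, n_trees = n_trees, boruta_runs = boruta_runs,
              boruta_alpha = boruta_alpha, boruta_on = match.arg(boruta_on),
              log_transform = log_transform, shap_perm = shap_perm,
              seed = seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$tau) || cfg$tau <= 0 || cfg$tau > 1)
    stopf("invalid config: tau must lie in (0, 1]")
  if (cfg$sig_threshold <= 0 || cfg$sig_threshold > 1)
    stopf("invalid config: sig_threshold must lie in (0, 1]")
  if (cfg$p_diff_cutoff <= 0 || cfg$p_diff_cutoff > 1)
    stopf("invalid config: p_diff_cutoff must lie in (0, 1]")
  if (cfg$folds < 2) stopf("invalid config: folds must be >= 2")
  if (cfg$top_k < 1) stopf("invalid config: top_k must be >= 1")
  if (cfg$n_trees < 1 || cfg$boruta_runs < 1)
    stopf("invalid config: n_trees and boruta_runs must be >= 1")
  invisible(cfg)
}

#' Run the full multi-method selection pipeline
#'
#' Normalization, the four attribute-weighting selections at `tau`, the
#' cross-validated L1-logistic selection, the consensus union, the
#' all-pairs differential correlation scan on the union with top-pair gene
#' extraction, and validation of the top-pair panel (random forest with
#' OOB metrics, Shapley attributions, and the shadow-feature loop with
#' rough fix). A rerun with the same inputs and config reproduces the
#' identical report.
#'
#' @param counts gene x sample count matrix (or latent expression; set
#'   `normalize = FALSE` for already-normalized input).
#' @param design data.frame with `sample_id` and `condition` (see
#'   [read_metadata_tsv()]).
#' @param config a [pipeline_config()].
#' @param normalize apply median-of-ratios normalization first (default
#'   TRUE; use FALSE for gaussian-mode latent matrices).
#' @param verbose print one progress line per stage.
#' @return list of class `selection_report`: `sets` (per-method, lasso,
#'   union, dgca_top, boruta_confirmed), `cardinalities`, `intersections`,
#'   `weights` (the four weight tables), `cv` (the CV fit), `pairs` (all
#'   pair records), `top_pairs`, `n_significant_pairs`, `validation`
#'   (oob_error, accuracy, auc, protocol), `attributions`, `boruta`,
#'   `provenance`.
#' @export
run_pipeline <- function(counts, design, config = pipeline_config(),
                         normalize = TRUE, verbose = FALSE) {
  validate_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- as.matrix(counts)
  if (is.data.frame(design) && !is.null(design$sample_id) &&
      !is.null(colnames(counts))) {
    if (!setequal(design$sample_id, colnames(counts)))
      stopf("metadata sample ids do not match the count matrix")
    design <- design[match(colnames(counts), design$sample_id), ]
  }
  y <- if (is.data.frame(design)) design$condition else design

  stage <- "normalize"
  res <- tryCatch({
    if (normalize) {
      say("normalize: median-of-ratios size factors")
      norm <- normalize_counts(counts)
      X <- if (config$log_transform) log2_normalized(norm) else unclass(norm)
    } else {
      norm <- counts
      X <- counts
    }

    stage <- "weights"
    say("weights: uncertainty / relief / correlation / svm at tau = %.2f",
        config$tau)
    wt <- list(
      uncertainty = weight_by_uncertainty(X, y, bins = config$bins),
      relief = weight_by_relief(X, y, n_neighbors = config$relief_neighbors),
      correlation = weight_by_correlation(X, y),
      svm = weight_by_svm(X, y, regularization = config$svm_cost))
    method_sets <- lapply(wt, select_by_threshold, tau = config$tau)

    stage <- "lasso"
    say("lasso: %d-fold CV, %s rule", config$folds, config$lasso_rule)
    cv <- cross_validate_lambda(X, y, folds = config$folds,
                                seed = config$seed)
    lasso_set <- selected_genes(cv, which = config$lasso_rule)

    stage <- "union"
    U <- union_selected(method_sets, lasso_set)
    say("union: %d genes", length(U))
    if (length(U) < 2)
      stopf("consensus union has fewer than 2 genes; nothing to correlate")

    stage <- "dgca"
    pairs <- dgca_all_pairs(X, design, genes = U,
                            method = config$dgca_method,
                            sig_threshold = config$sig_threshold)
    n_sig <- sum(pairs$pValDiff < config$p_diff_cutoff)
    tp <- top_pairs(pairs, k = config$top_k)
    D <- genes_in_top_pairs(tp)
    say("dgca: %d pairs, %d below p < %g, %d genes in the top %d pairs",
        nrow(pairs), n_sig, config$p_diff_cutoff, length(D), config$top_k)

    stage <- "validate"
    rf <- train_random_forest(X[D, , drop = FALSE], y,
                              n_trees = config$n_trees, seed = config$seed)
    ev <- evaluate_model(rf, X[D, , drop = FALSE], y, protocol = "oob")
    shap <- shap_attributions(rf, X[D, , drop = FALSE],
                              n_perm = config$shap_perm, seed = config$seed)
    say("validate: oob error %.4f, accuracy %.3f, auc %.3f",
        rf$oob_error, ev$accuracy, ev$auc)

    stage <- "boruta"
    Xb <- if (config$boruta_on == "all") X else X[U, , drop = FALSE]
    bo <- tentative_rough_fix(
      boruta(Xb, y, max_runs = config$boruta_runs,
             alpha = config$boruta_alpha, n_trees = config$n_trees,
             seed = config$seed))
    B <- sort(names(bo$final_decision)[bo$final_decision == "Confirmed"])
    say("boruta: %d confirmed of %d features", length(B), nrow(Xb))

    sets <- c(method_sets,
              list(lasso = lasso_set, union = U, dgca_top = D,
                   boruta_confirmed = B))
    report <- list(
      sets = sets,
      cardinalities = vapply(sets, length, 0L),
      intersections = list(
        boruta_union = intersect_sets(B, U),
        boruta_dgca_top = intersect_sets(B, D)),
      weights = wt, cv = cv, pairs = pairs, top_pairs = tp,
      n_significant_pairs = n_sig,
      validation = list(oob_error = rf$oob_error, accuracy = ev$accuracy,
                        auc = ev$auc, protocol = ev$protocol,
                        n_trees = config$n_trees),
      attributions = shap,
      boruta = bo,
      provenance = list(config = unclass(config),
                        n_genes = nrow(counts), n_samples = ncol(counts)))
    class(report) <- "selection_report"
    report
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  res
}

#' Check a selection report's internal consistency
#'
#' Verifies that every reported cardinality equals its set's size, that the
#' union equals the union of its five upstream sets, and that the top-pair
#' genes are contained in the union.
#'
#' @param report a `selection_report`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  s <- report$sets
  if (!all(report$cardinalities == vapply(s, length, 0L)))
    stopf("report cardinalities do not match set sizes")
  if (!setequal(s$union,
                union_selected(s[c("uncertainty", "relief", "correlation",
                                   "svm")], s$lasso)))
    stopf("union set is not the union of the upstream sets")
  if (!all(s$dgca_top %in% s$union))
    stopf("top-pair genes are not contained in the consensus union")
  invisible(TRUE)
}

#' Write a selection report as JSON
#'
#' Sets are serialized sorted, so identical analyses give byte-identical
#' files.
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    sets = lapply(report$sets, sort),
    cardinalities = as.list(report$cardinalities),
    intersections = report$intersections,
    n_significant_pairs = report$n_significant_pairs,
    validation = report$validation,
    top_pairs = report$top_pairs,
    importance_ranking = report$attributions$ranking,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
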