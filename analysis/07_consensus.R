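#!/usr/bin/env Rscript
# Stage 7: consensus bookkeeping.
#
# The set algebra over all stages: per-method panels, the penalized
# selection, their union, the differential-correlation panel, the
# shadow-confirmed genes, and the pairwise overlaps, scored against the
# planted ground truth.

suppressMessages(library(floodgene))

truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
sets <- list(
  uncertainty = select_by_threshold(read.delim("results/weights_uncertainty.tsv")),
  relief = select_by_threshold(read.delim("results/weights_relief.tsv")),
  correlation = select_by_threshold(read.delim("results/weights_correlation.tsv")),
  svm = select_by_threshold(read.delim("results/weights_svm.tsv")),
  lasso = read_gene_list("results/lasso_genes.txt"),
  union = read_gene_list("results/union_genes.txt"),
  dgca_top = read_gene_list("results/dgca_panel_genes.txt"))
bo <- read.delim("results/boruta_decisions.tsv")
sets$boruta_confirmed <- sort(bo$gene_id[bo$final_decision == "Confirmed"])

overlaps <- list(
  boruta_vs_union = intersect_sets(sets$boruta_confirmed, sets$union),
  boruta_vs_dgca_top = intersect_sets(sets$boruta_confirmed, sets$dgca_top))

de <- truth$de_genes$gene_id
dc <- unique(c(truth$dc_pairs$gene1, truth$dc_pairs$gene2))
scoring <- list(
  planted_de_in_union = intersect_sets(de, sets$union)$n,
  planted_de_total = length(de),
  planted_dc_in_panel = intersect_sets(dc, sets$dgca_top)$n,
  planted_dc_total = length(dc))

jsonlite::write_json(list(sets = sets,
                          cardinalities = lapply(sets, length),
                          overlaps = overlaps, ground_truth_score = scoring),
                     "results/consensus_report.json",
                     auto_unbox = TRUE, digits = NA)

cat("Panel sizes:\n")
print(vapply(sets, length, 0L))
cat(sprintf("Shadow-confirmed ∩ union: %d | ∩ top-pair panel: %d\n",
            overlaps$boruta_vs_union$n, overlaps$boruta_vs_dgca_top$n))
cat(sprintf("Planted DE captured by the union: %d/%d; planted DC genes in the panel: %d/%d\n",
            scoring$planted_de_in_union, scoring$planted_de_total,
            scoring$planted_dc_in_panel, scoring$planted_dc_total))
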