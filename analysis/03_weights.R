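#!/usr/bin/env Rscript
# Stage 3: attribute weighting.
#
# The four selectors (symmetric uncertainty, Relief, correlation,
# linear-SVM weights) score every gene's ability to separate control from
# stress on log2 normalized values; genes above the 0.90 threshold form
# each method's panel.

suppressMessages(library(floodgene))

X <- log2_normalized(read_counts_tsv("results/normalized.tsv"))
md <- read_metadata_tsv("results/data/metadata.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

wts <- list(uncertainty = weight_by_uncertainty(X, md),
            relief = weight_by_relief(X, md),
            correlation = weight_by_correlation(X, md),
            svm = weight_by_svm(X, md))

for (m in names(wts)) {
  w <- wts[[m]]
  w$selected <- w$weight > 0.90 | w$weight == 1
  write.table(w[order(-w$weight), ],
              file.path("results", paste0("weights_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- select_by_threshold(w, 0.90)
  cat(sprintf("%-12s %3d genes above 0.90 (%d of them planted DE)\n",
              m, length(sel), sum(sel %in% truth$de_genes$gene_id)))
}
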