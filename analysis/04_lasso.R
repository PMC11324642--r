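#!/usr/bin/env Rscript
# Stage 4: L1-penalized logistic selection.
#
# 10-fold stratified cross-validation of the binomial deviance over the
# penalty path; the one-standard-error rule picks a sparse panel of genes
# with nonzero coefficients.

suppressMessages(library(floodgene))

X <- log2_normalized(read_counts_tsv("results/normalized.tsv"))
md <- read_metadata_tsv("results/data/metadata.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

cv <- cross_validate_lambda(X, md, folds = 10, seed = 2024)
curve <- data.frame(lambda = cv$lambda, cv_mean = cv$cv_mean,
                    cv_se = cv$cv_se, n_nonzero = as.integer(cv$n_nonzero))
write.table(curve, "results/lasso_cv_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- selected_genes(cv, "1se")
writeLines(sel, "results/lasso_genes.txt")

cat(sprintf("lambda.min = %.5f, lambda.1se = %.5f\n",
            cv$lambda_min, cv$lambda_1se))
cat(sprintf("%d genes selected at lambda.1se (%d planted DE among them)\n",
            length(sel), sum(sel %in% truth$de_genes$gene_id)))
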