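#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.
#
# Emulates the merged two-condition design the pipeline was built for:
# 18 control + 18 stress samples pooled from 3 studies, negative-binomial
# counts with per-sample size factors and per-study batch shifts, 1% of
# genes with a planted 2^±2 fold change, and two correlation blocks whose
# gene-gene correlation differs between conditions (a 0 -> +0.98 block and
# a +0.8 -> -0.8 block; the correlated latent term carries SD 1.5 on the
# log2 scale so the realized count-level correlations stay around 0.9,
# the regime in which stress-induced co-expression is actually published).
# 5,000 genes keep the run light; the generator scales to the full
# ~20k-gene defaults unchanged. Ground truth is written next to the data
# so later stages can score themselves.

suppressMessages(library(floodgene))

cfg <- sim_config(
  n_genes = 5000, n_control = 18, n_stress = 18, n_studies = 3, seed = 2024,
  de_fraction = 0.01, lfc_sd = 2, dispersion = 0.1,
  size_factor_range = c(0.5, 2), study_shift_sd = 0.3,
  baseline_log2_mean = 7, baseline_log2_sd = 1.5, dc_de = TRUE,
  dc_noise_sd = 1.5,
  dc_blocks = list(list(size = 3, rho_control = 0, rho_stress = 0.98),
                   list(size = 2, rho_control = 0.8, rho_stress = -0.8)))

ds <- generate_dataset(cfg)
paths <- write_dataset(ds, "results/data")

cat("Simulated", nrow(ds$matrix), "genes x", ncol(ds$matrix), "samples\n")
cat("Planted DE genes:", nrow(ds$truth$de_genes),
    "| planted differential-correlation pairs:", nrow(ds$truth$dc_pairs), "\n")
cat("Files:", paste(paths, collapse = ", "), "\n")
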