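#' Simulation configuration for two-condition expression data
#'
#' Describes a synthetic gene x sample experiment with planted differential
#' expression and planted condition-specific correlation blocks. Defaults
#' emulate the merged cucumber waterlogging design the pipeline was built
#' for: ~20,144 genes and 18 control + 18 stress samples pooled from three
#' studies, negative-binomial counts with per-sample size factors and
#' per-study batch shifts.
#'
#' @param n_genes number of genes.
#' @param n_control,n_stress samples per condition (each must be >= 4; the
#'   Fisher z variance 1/(n-3) needs n > 3).
#' @param n_studies number of batches the samples are split over.
#' @param seed master seed; all draws flow from one seeded generator so a
#'   rerun is bit-identical.
#' @param de_fraction fraction of genes given a planted log2 fold change.
#' @param lfc_sd magnitude of every planted log2 fold change (sign is drawn
#'   at random per gene). In the stress condition a DE gene's mean is
#'   multiplied by `2^lfc`.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha*mu^2); a scalar, or a length-2 range sampled per gene.
#'   0 gives (near-)Poisson counts.
#' @param size_factor_range length-2 interval for per-sample scale factors
#'   (log-uniform), or a single value used for every sample.
#' @param study_shift_sd SD of per-gene, per-study log2 batch shifts
#'   (counts mode only).
#' @param dc_blocks list of correlation blocks, each a list/vector with
#'   elements `size` (>= 2), `rho_control` and `rho_stress` (each in
#'   (-1, 1)). Within a block the latent values share a per-sample factor so
#'   that the latent pairwise correlation equals the planted rho (sign
#'   applied per gene).
#' @param output_mode `"counts"` for negative-binomial counts;
#'   `"gaussian"` for the latent log2 expression itself (no NB noise, no
#'   size factors, no batch shifts) -- exact correlations for sharp
#'   numerical tests.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 mean expression.
#' @param dc_noise_sd log2-scale SD given to the correlated latent term in
#'   counts mode (in gaussian mode the latent term has unit SD).
#' @param detect_floor |rho| below which a planted correlation is labelled
#'   "0" in the ground-truth class (detectability floor).
#' @param dc_de when TRUE, every correlation-block gene also receives a
#'   planted fold change (counted toward `de_fraction`), emulating panels
#'   where the differentially correlated genes are themselves
#'   stress-responsive.
#'
#' @return an object of class `sim_config`.
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_genes = 20144, n_control = 18, n_stress = 18,
                       n_studies = 3, seed = 1,
                       de_fraction = 0.05, lfc_sd = 2,
                       dispersion = 0.1, size_factor_range = c(0.5, 2),
                       study_shift_sd = 0.3, dc_blocks = list(),
                       output_mode = c("counts", "gaussian"),
                       baseline_log2_mean = 5, baseline_log2_sd = 2,
                       dc_noise_sd = 0.5, detect_floor = 0.3,
                       dc_de = FALSE) {
  output_mode <- match.arg(output_mode)
  cfg <- list(n_genes = n_genes, n_control = n_control, n_stress = n_stress,
              n_studies = n_studies, seed = seed, de_fraction = de_fraction,
              lfc_sd = lfc_sd, dispersion = dispersion,
              size_factor_range = size_factor_range,
              study_shift_sd = study_shift_sd, dc_blocks = dc_blocks,
              output_mode = output_mode,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              dc_noise_sd = dc_noise_sd, detect_floor = detect_floor,
              dc_de = dc_de)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stopf("invalid sim_config: n_genes must be >= 1")
  if (cfg$n_control < 4 || cfg$n_stress < 4)
    stopf("invalid sim_config: n_control and n_stress must each be >= 4 (z-score variance needs n > 3)")
  if (cfg$n_studies < 1) stopf("invalid sim_config: n_studies must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stopf("invalid sim_config: de_fraction must lie in [0, 1]")
  if (any(cfg$dispersion < 0) || length(cfg$dispersion) > 2)
    stopf("invalid sim_config: dispersion must be a non-negative scalar or range")
  if (any(cfg$size_factor_range <= 0) || length(cfg$size_factor_range) > 2)
    stopf("invalid sim_config: size_factor_range must be positive (scalar or interval)")
  blk <- cfg$dc_blocks
  if (length(blk)) {
    sizes <- vapply(blk, function(b) as.numeric(b[["size"]]), 0)
    rhos <- c(vapply(blk, function(b) as.numeric(b[["rho_control"]]), 0),
              vapply(blk, function(b) as.numeric(b[["rho_stress"]]), 0))
    if (any(sizes < 2)) stopf("invalid sim_config: dc_block sizes must be >= 2")
    if (sum(sizes) > cfg$n_genes)
      stopf("invalid sim_config: sum of dc_block sizes exceeds n_genes")
    if (any(abs(rhos) >= 1))
      stopf("invalid sim_config: every planted rho must lie in (-1, 1)")
  }
  invisible(cfg)
}

# per-gene sign flags realising a (possibly negative) planted rho:
# gene 1 carries +1; the rest carry sign(rho), so pairs with gene 1 have
# correlation rho and pairs among the rest have +|rho|.
block_signs <- function(size, rho) {
  s <- rep(if (rho < 0) -1 else 1, size)
  s[1] <- 1
  s
}

planted_class <- function(rho_c, rho_s, floor) {
  sgn <- function(r) ifelse(abs(r) < floor, "0", ifelse(r > 0, "+", "-"))
  paste0(sgn(rho_c), "/", sgn(rho_s))
}

#' Generate a synthetic two-condition expression dataset
#'
#' Draws a gene x sample matrix under the configuration's planted
#' differential expression and correlation structure, together with
#' machine-readable ground truth. In `"gaussian"` mode the returned matrix
#' is the latent log2 expression (unit-variance noise; planted within-block
#' latent correlations are exact). In `"counts"` mode latent means are
#' scaled by per-sample size factors and per-study batch shifts and counts
#' are drawn negative-binomially.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `matrix` (gene x
#'   sample), `design` (data.frame: sample_id, condition, study), `truth`
#'   (list: de_genes, dc_pairs, size_factors, block_genes) and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  ng <- config$n_genes
  nc <- config$n_control
  ns <- config$n_stress
  n <- nc + ns
  gaussian <- config$output_mode == "gaussian"

  gene_ids <- sprintf("gene%05d", seq_len(ng))
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(nc)),
                  sprintf("strs_%02d", seq_len(ns)))
  condition <- rep(c("control", "stress"), c(nc, ns))
  study_idx <- c(rep_len(seq_len(config$n_studies), nc),
                 rep_len(seq_len(config$n_studies), ns))
  design <- data.frame(sample_id = sample_ids, condition = condition,
                       study = sprintf("study%d", study_idx),
                       stringsAsFactors = FALSE)

  ## fixed draw order (baselines, DE, batch, size factors, blocks, noise)
  ## so that one seed fixes the whole dataset
  m <- rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)

  ## dc blocks occupy the first genes, deterministically
  block_sizes <- vapply(config$dc_blocks,
                        function(b) as.integer(b[["size"]]), 0L)
  block_idx_all <- seq_len(sum(block_sizes))

  n_de <- round(config$de_fraction * ng)
  if (isTRUE(config$dc_de)) {
    extra <- setdiff(seq_len(ng), block_idx_all)
    n_extra <- max(0L, n_de - length(block_idx_all))
    de_idx <- sort(c(block_idx_all,
                     if (n_extra > 0) sample(extra, n_extra) else integer(0)))
  } else {
    de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  }
  lfc <- numeric(ng)
  if (length(de_idx))
    lfc[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
      config$lfc_sd

  B <- matrix(rnorm(ng * config$n_studies, 0, config$study_shift_sd),
              ng, config$n_studies)

  sfr <- config$size_factor_range
  s <- if (length(sfr) == 1 || sfr[1] == sfr[2]) rep(sfr[1], n)
       else exp(runif(n, log(sfr[1]), log(sfr[2])))
  names(s) <- sample_ids

  ## correlated latent term: within block k, gene i, sample j
  ##   e_ij = sign_i * sqrt(|rho|) * f_kj + sqrt(1 - |rho|) * eps_ij
  ## with f, eps iid N(0,1), so cor(e_i, e_j) = sign_i*sign_j*|rho| exactly
  E <- matrix(0, ng, n)
  is_ctrl <- condition == "control"
  blocks <- config$dc_blocks
  block_gene_idx <- list()
  dc_pairs <- NULL
  ptr <- 0L
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    size <- as.integer(b[["size"]])
    g <- ptr + seq_len(size)
    ptr <- ptr + size
    block_gene_idx[[k]] <- g
    f <- rnorm(n)
    eps <- matrix(rnorm(size * n), size, n)
    for (cond in c("control", "stress")) {
      cols <- if (cond == "control") which(is_ctrl) else which(!is_ctrl)
      rho <- as.numeric(b[[if (cond == "control") "rho_control" else "rho_stress"]])
      sg <- block_signs(size, rho)
      a <- abs(rho)
      E[g, cols] <- sg * sqrt(a) * rep(f[cols], each = size) +
        sqrt(1 - a) * eps[, cols, drop = FALSE]
    }
    prs <- combn(seq_len(size), 2)
    sc <- block_signs(size, as.numeric(b[["rho_control"]]))
    ss <- block_signs(size, as.numeric(b[["rho_stress"]]))
    rc <- sc[prs[1, ]] * sc[prs[2, ]] * abs(as.numeric(b[["rho_control"]]))
    rs <- ss[prs[1, ]] * ss[prs[2, ]] * abs(as.numeric(b[["rho_stress"]]))
    dc_pairs <- rbind(dc_pairs, data.frame(
      gene1 = gene_ids[g[prs[1, ]]], gene2 = gene_ids[g[prs[2, ]]],
      rho_control = rc, rho_stress = rs, block = k,
      class = planted_class(rc, rs, config$detect_floor),
      stringsAsFactors = FALSE))
  }
  if (is.null(dc_pairs))
    dc_pairs <- data.frame(gene1 = character(0), gene2 = character(0),
                           rho_control = numeric(0), rho_stress = numeric(0),
                           block = integer(0), class = character(0),
                           stringsAsFactors = FALSE)

  in_block <- seq_len(ng) %in% unlist(block_gene_idx)

  stress_ind <- as.numeric(!is_ctrl)
  if (gaussian) {
    ## latent log2 expression: unit-variance noise everywhere; batch shifts
    ## and size factors are count-level artefacts and are omitted so that
    ## planted correlations are exact
    if (any(!in_block))
      E[!in_block, ] <- matrix(rnorm(sum(!in_block) * n), sum(!in_block), n)
    M <- m + outer(lfc, stress_ind) + E
  } else {
    log2mu <- m + B[, study_idx, drop = FALSE] + outer(lfc, stress_ind) +
      config$dc_noise_sd * E
    mu <- sweep(2^log2mu, 2, s, `*`)
    alpha <- if (length(config$dispersion) == 2)
      runif(ng, config$dispersion[1], config$dispersion[2])
    else rep(config$dispersion, ng)
    size_nb <- ifelse(alpha <= 0, 1e8, 1 / alpha)
    M <- matrix(rnbinom(ng * n, mu = as.vector(mu),
                        size = rep(size_nb, times = n)), ng, n)
  }
  dimnames(M) <- list(gene_ids, sample_ids)

  truth <- list(
    de_genes = data.frame(gene_id = gene_ids[de_idx], lfc = lfc[de_idx],
                          stringsAsFactors = FALSE),
    dc_pairs = dc_pairs,
    size_factors = s,
    block_genes = lapply(block_gene_idx, function(i) gene_ids[i]))

  structure(list(matrix = M, design = design, truth = truth, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the counts (or latent-expression) TSV with genes as rows, the
#' sample metadata TSV (sample_id, condition, study), and the ground truth
#' as JSON. The TSVs round-trip losslessly through [read_counts_tsv()] and
#' [read_metadata_tsv()].
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param directory output directory (created if missing).
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "sim_dataset")) stopf("not a sim_dataset")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", directory)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             truth = file.path(directory, "ground_truth.json"))
  write_counts_tsv(dataset$matrix, paths[["counts"]])
  write.table(dataset$design, paths[["metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$size_factors <- as.list(truth$size_factors)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
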