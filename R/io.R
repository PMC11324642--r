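#' Read a gene x sample counts TSV
#'
#' Expects a header row `gene_id<TAB>sample1...` and one gene per row.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene x sample matrix as TSV
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("failed to write %s", path)
  invisible(path)
}

#' Read a sample metadata TSV (sample_id, condition, study)
#'
#' @param path file path.
#' @return data.frame with at least `sample_id` and `condition` columns.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  df
}

#' Read a gene list (one id per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Curated reference results from the cucumber waterlogging meta-analysis
#'
#' The published selection results this pipeline is organized around: a
#' three-study cucumber (Cucumis sativus) waterlogging RNA-seq
#' meta-analysis with 18 control and 18 stress samples. Shipped as
#' plain-text files under `inst/extdata/` and used by the set-algebra and
#' dz-reproduction checks.
#'
#' @return list with elements:
#'   \describe{
#'     \item{weights}{data.frame (method, gene_id, weight): the genes each
#'       attribute-weighting method scored above 0.90.}
#'     \item{lasso_genes}{the 13 genes with nonzero coefficient at
#'       `lambda.1se`.}
#'     \item{top_pairs}{data.frame of the top ten differentially correlated
#'       pairs: per-condition Pearson r and p (n = 18 each), z-score
#'       difference, its p-value, and the class label.}
#'   }
#' @export
cucumber_reference <- function() {
  d <- system.file("extdata", package = "floodgene")
  list(weights = read.delim(file.path(d, "cucumber_weight_panels.tsv"),
                            stringsAsFactors = FALSE),
       lasso_genes = read_gene_list(file.path(d, "cucumber_lasso_genes.txt")),
       top_pairs = read.delim(file.path(d, "cucumber_top_pairs.tsv"),
                              stringsAsFactors = FALSE))
}
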