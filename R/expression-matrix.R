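#' Construct an expression matrix with sample metadata
#'
#' Bundles a non-negative genes-by-samples FPKM matrix with per-sample
#' metadata (species, tissue, replicate).  All screen operations take
#' this container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, in
#'   FPKM units.  Row and column names are required and become the gene
#'   and sample identifiers.
#' @param sample_meta Data frame with columns `sample_id`, `species`,
#'   `tissue`, `replicate`, covering every column of `values` exactly
#'   once.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_meta`.
#' @examples
#' m <- matrix(c(5, 1, 6, 1.2), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), species = "human",
#'                    tissue = c("heart", "liver"), replicate = 1L)
#' expression_matrix(m, meta)
#' @export
expression_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  if (any(values < 0) || any(!is.finite(values)))
    stop("FPKM values must be finite and non-negative", call. = FALSE)
  need <- c("sample_id", "species", "tissue", "replicate")
  if (!all(need %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicated sample_id in sample_meta", call. = FALSE)
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta must cover every sample exactly once", call. = FALSE)
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 sample_meta = sample_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              paste(unique(x$sample_meta$species), collapse = ", ")))
  tab <- table(x$sample_meta$tissue)
  cat("  tissues:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has `gene_id` in the first column and one column per
#' sample; the metadata file has columns `sample_id`, `species`,
#' `tissue`, `replicate`.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, meta_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs gene_id + >=1 sample column")
  genes <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata to TSV
#'
#' @param expr An [expression_matrix()].
#' @param path,meta_path Output paths for the value matrix and the
#'   sample metadata.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path, meta_path) {
  out <- data.frame(gene_id = expr$gene_ids, expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
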