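## Tabular I/O. All tables are UTF-8 TSV/CSV with "." decimals; "NA" and ""
## parse as missing. Delimiter is auto-detected from the extension
## (.tsv -> tab, .csv -> comma) and can be overridden.

delim_for <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  switch(tolower(tools::file_ext(path)), csv = ",", "\t")
}

read_table_raw <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path, delimiter),
                    quote = "\"", na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

#' Read a gene x sample count matrix from TSV/CSV
#'
#' First column holds gene IDs, the header row holds sample IDs, cells are
#' non-negative integers.
#'
#' @param path file path.
#' @param delimiter field separator; default inferred from the extension.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, delimiter = NULL) {
  df <- read_table_raw(path, delimiter)
  if (ncol(df) < 3L) stop("expected gene ID column plus >=2 sample columns")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- genes
  count_matrix(m)
}

#' Write a count matrix to TSV/CSV
#'
#' @param cm a [count_matrix()].
#' @param path output path; delimiter from extension.
#' @param delimiter optional override.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, delimiter = NULL) {
  df <- data.frame(gene = rownames(cm), unclass(cm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path, delimiter),
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path file path.
#' @param id_column name of the sample ID column.
#' @param delimiter field separator; default inferred from the extension.
#' @return A [sample_metadata()].
#' @export
read_metadata <- function(path, id_column = "sample_id", delimiter = NULL) {
  sample_metadata(read_table_raw(path, delimiter), id_column = id_column)
}

#' Default header dialect for contrast tables
#'
#' Maps the canonical column roles to the synonyms common DE engines emit.
#' @return named list of character vectors, one per role.
#' @export
contrast_dialect <- function() {
  list(gene      = c("gene", "gene_id", "id", "row", "feature"),
       mean_expr = c("mean_expr", "baseMean", "base_mean", "AveExpr", "logCPM",
                     "mean"),
       log2fc    = c("log2fc", "log2FoldChange", "logFC", "lfc"),
       pvalue    = c("pvalue", "p_value", "PValue", "P.Value", "pval"),
       padj      = c("padj", "p_adj", "FDR", "adj.P.Val", "qvalue"))
}

#' Read a per-contrast DE result table
#'
#' Column names are matched against a dialect of synonyms
#' ([contrast_dialect()]) so tables from different DE engines load without
#' renaming. A file where the gene role is unmatched falls back to the first
#' column. A table with no adjusted-p column at all loads with every `padj`
#' missing (and the `all_padj_missing` attribute set).
#'
#' @param path file path.
#' @param dialect named list of header synonyms per role; merged over
#'   [contrast_dialect()].
#' @param contrast_label label for the contrast; defaults to the file stem.
#' @param delimiter field separator; default inferred from the extension.
#' @return A [contrast_result()].
#' @export
read_contrast_table <- function(path, dialect = NULL, contrast_label = NULL,
                                delimiter = NULL) {
  df <- read_table_raw(path, delimiter)
  dia <- contrast_dialect()
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  pick <- function(role, required = TRUE) {
    hit <- intersect(dia[[role]], names(df))
    if (length(hit)) return(hit[1L])
    if (required)
      stop(sprintf("no column for '%s'; expected one of: %s (found: %s)",
                   role, paste(dia[[role]], collapse = ", "),
                   paste(names(df), collapse = ", ")))
    NA_character_
  }
  gene_col <- intersect(dia$gene, names(df))
  gene <- if (length(gene_col)) df[[gene_col[1L]]] else df[[1L]]
  padj_col <- pick("padj", required = FALSE)
  out <- data.frame(
    gene = gene,
    mean_expr = df[[pick("mean_expr")]],
    log2fc = df[[pick("log2fc")]],
    pvalue = df[[pick("pvalue")]],
    padj = if (is.na(padj_col)) NA_real_ else df[[padj_col]],
    stringsAsFactors = FALSE)
  if (is.null(contrast_label))
    contrast_label <- tools::file_path_sans_ext(basename(path))
  contrast_result(out, contrast_label = contrast_label)
}

#' Write a contrast result table
#'
#' Emits the canonical five-column schema (`gene`, `mean_expr`, `log2fc`,
#' `pvalue`, `padj`).
#'
#' @param cr a [contrast_result()].
#' @param path output path; delimiter from extension.
#' @param delimiter optional override.
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(cr, path, delimiter = NULL) {
  utils::write.table(as.data.frame(cr), path, sep = delim_for(path, delimiter),
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-check a count matrix against a metadata table
#'
#' Report-only: lists sample IDs present in only one of the two inputs.
#'
#' @param cm a [count_matrix()].
#' @param md a [sample_metadata()].
#' @return list with `counts_only`, `metadata_only` and logical `ok` (TRUE iff
#'   the two ID sets coincide).
#' @export
validate_pair <- function(cm, md) {
  a <- colnames(cm); b <- md$sample_id
  out <- list(counts_only = setdiff(a, b), metadata_only = setdiff(b, a))
  out$ok <- !length(out$counts_only) && !length(out$metadata_only)
  out
}
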