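#' aggDE: aggregation and visualization of multi-contrast differential
#' expression results
#'
#' aggDE merges the per-gene statistics of many pairwise contrasts (fold
#' changes, p-values) into one master gene-by-contrast result set by union or
#' intersection of their significant genes, and computes the numeric tables
#' behind sixteen standard visualizations of such data, from sample-distance
#' heat maps and MDS embeddings to volcano plots and co-expression series.
#' A standardized project workspace with toggled auto-export keeps every
#' figure next to the exact numbers it was drawn from.
#'
#' @section Core objects:
#' \describe{
#'   \item{[count_matrix()]}{raw integer gene x sample counts.}
#'   \item{[sample_metadata()]}{per-sample factor annotations.}
#'   \item{[contrast_result()]}{one contrast's per-gene DE statistics.}
#'   \item{[aggregate_contrasts()]}{the master result set: aligned lfc / padj /
#'     significance matrices across contrasts.}
#'   \item{[compute_plot_data()]}{the numeric tables behind each of the 16
#'     registered plot types.}
#'   \item{[init_project()]}{the standardized output workspace.}
#' }
#'
#' @keywords internal
#' @importFrom stats as.hclust
"_PACKAGE"

## ---- count_matrix -----------------------------------------------------

#' Construct a validated count matrix
#'
#' A count matrix is the root input of every analysis: genes in rows, samples
#' in columns, cells are raw non-negative integer read counts.
#'
#' @param counts numeric matrix of non-negative integers with unique rownames
#'   (gene IDs) and unique colnames (sample IDs).
#' @return An integer matrix of class `count_matrix`.
#' @examples
#' cm <- count_matrix(matrix(0:5, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' dim(cm)
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("count matrix needs at least 1 gene and 2 samples")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 counts[bad[1L, , drop = FALSE]]))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  y <- unclass(x)
  print(utils::head(y[, seq_len(min(6L, ncol(y))), drop = FALSE]))
  invisible(x)
}

## ---- sample_metadata --------------------------------------------------

#' Construct sample metadata
#'
#' @param df data.frame with one row per sample.
#' @param id_column name of the column holding sample IDs.
#' @return A data.frame of class `sample_metadata`: a `sample_id` character
#'   column followed by factor columns.
#' @export
sample_metadata <- function(df, id_column = "sample_id") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!id_column %in% names(df))
    stop(sprintf("id column '%s' not found; available: %s",
                 id_column, paste(names(df), collapse = ", ")))
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fac <- df[setdiff(names(df), id_column)]
  for (nm in names(fac)) {
    col <- fac[[nm]]
    miss <- is.na(col) | (is.character(col) & !nzchar(trimws(as.character(col))))
    if (any(miss))
      stop(sprintf("missing value in factor '%s' for sample '%s'",
                   nm, ids[which(miss)[1L]]))
    fac[[nm]] <- factor(col)
  }
  out <- data.frame(sample_id = ids, fac, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- ids
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Names of the factor columns of a metadata table
#' @param md a `sample_metadata`.
#' @return character vector.
#' @export
metadata_factors <- function(md) setdiff(names(md), "sample_id")

## ---- contrast_result --------------------------------------------------

#' Construct a per-contrast differential expression result table
#'
#' The interchange format for external DE engines: one row per gene with the
#' normalized mean expression, log2 fold change, raw and adjusted p-value.
#' Missing `padj` is routine (engines drop low-information genes from
#' adjustment); a missing `pvalue` indicates a corrupt table and is rejected.
#'
#' @param df data.frame with columns `gene`, `mean_expr`, `log2fc`, `pvalue`,
#'   `padj`.
#' @param contrast_label length-3 character: factor name, numerator level,
#'   denominator level (or any single descriptive string).
#' @return data.frame of class `contrast_result` with attribute
#'   `contrast_label` and logical attribute `all_padj_missing`.
#' @export
contrast_result <- function(df, contrast_label = "contrast") {
  need <- c("gene", "mean_expr", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene))
    stop("duplicate gene IDs: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  for (nm in c("mean_expr", "log2fc", "pvalue", "padj"))
    df[[nm]] <- as.numeric(df[[nm]])
  if (anyNA(df$pvalue))
    stop("missing pvalue for gene '", df$gene[which(is.na(df$pvalue))[1L]],
         "' (missing padj is allowed, missing pvalue is not)")
  bad <- df$pvalue < 0 | df$pvalue > 1
  if (any(bad))
    stop("pvalue outside [0,1] for gene '", df$gene[which(bad)[1L]], "'")
  bad <- !is.na(df$padj) & (df$padj < 0 | df$padj > 1)
  if (any(bad))
    stop("padj outside [0,1] for gene '", df$gene[which(bad)[1L]], "'")
  rownames(df) <- df$gene
  attr(df, "contrast_label") <- as.character(contrast_label)
  attr(df, "all_padj_missing") <- all(is.na(df$padj))
  class(df) <- c("contrast_result", "data.frame")
  df
}

#' Label of a contrast result
#' @param cr a `contrast_result`.
#' @return single string (factor:numerator_vs_denominator for 3-part labels).
#' @export
contrast_name <- function(cr) {
  lab <- attr(cr, "contrast_label")
  if (length(lab) == 3L)
    sprintf("%s:%s_vs_%s", lab[1L], lab[2L], lab[3L])
  else paste(lab, collapse = "_")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result '%s': %d genes\n", contrast_name(x), nrow(x)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

## ---- gene_map ---------------------------------------------------------

#' Construct a gene ID to display-name map
#'
#' @param ids character vector of gene IDs (unique).
#' @param names character vector of display names, same length.
#' @param policy behaviour for IDs absent from the map: keep the original ID,
#'   drop the entry, or raise an error.
#' @return list of class `gene_map`.
#' @export
gene_map <- function(ids, names, policy = c("keep", "drop", "error")) {
  policy <- match.arg(policy)
  ids <- as.character(ids); names <- as.character(names)
  if (length(ids) != length(names))
    stop("ids and names differ in length")
  if (anyDuplicated(ids))
    stop("duplicate map keys: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(mapping = stats::setNames(names, ids), policy = policy),
            class = "gene_map")
}
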