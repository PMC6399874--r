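## The core feature: merging many contrasts' significant genes into one
## master gene x contrast result set (union or intersection), with values
## re-extracted for every retained gene, then filtering / sorting /
## subsetting the aggregate.

new_master_result <- function(genes, contrasts, lfc, padj, sig, mode,
                              p_cut, lfc_cut, filters = list()) {
  structure(list(genes = genes, contrasts = contrasts,
                 lfc = lfc, padj = padj, sig = sig,
                 mode = mode, p_cut = p_cut, lfc_cut = lfc_cut,
                 filters = filters),
            class = "master_result")
}

#' Aggregate contrasts into a master result set
#'
#' The retained gene set is the union (or intersection) of each contrast's
#' significant genes at the given thresholds ([call_significance()]). For
#' every retained gene, `lfc` and `padj` values are re-extracted from every
#' contrast — including contrasts where the gene did not reach significance —
#' because cross-contrast heat maps and profiles need the full matrix; the
#' `sig` matrix keeps the distinction. Genes absent from some contrast's
#' table are retained with missing values in that column under union mode and
#' excluded under intersection mode (intersection demands evidence in every
#' contrast).
#'
#' @param contrasts list of [contrast_result()] objects (>= 1), with distinct
#'   labels.
#' @param mode `"union"` or `"intersection"`.
#' @param p_cut,lfc_cut significance thresholds, recorded in the result.
#' @return A `master_result`: `genes`, `contrasts` (labels), aligned numeric
#'   matrices `lfc` and `padj`, logical matrix `sig`, plus `mode` and the
#'   thresholds.
#' @export
aggregate_contrasts <- function(contrasts, mode = c("union", "intersection"),
                                p_cut = 0.05, lfc_cut = 0) {
  mode <- match.arg(mode)
  if (!length(contrasts)) stop("need at least one contrast")
  if (inherits(contrasts, "contrast_result")) contrasts <- list(contrasts)
  labels <- vapply(contrasts, contrast_name, character(1))
  if (anyDuplicated(labels))
    stop("duplicate contrast labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sig_sets <- lapply(contrasts, call_significance,
                     p_cut = p_cut, lfc_cut = lfc_cut)
  genes <- Reduce(if (mode == "union") union else intersect,
                  lapply(sig_sets, as.character))
  if (mode == "intersection" && length(genes)) {
    present <- Reduce(intersect, lapply(contrasts, function(cr) cr$gene))
    genes <- intersect(genes, present)
  }
  genes <- sort(unique(genes))
  if (!length(genes))
    warning("empty master result (no gene passes in ",
            if (mode == "union") "any" else "every", " contrast)")
  k <- length(contrasts)
  lfc <- padj <- matrix(NA_real_, length(genes), k,
                        dimnames = list(genes, labels))
  sig <- matrix(FALSE, length(genes), k, dimnames = list(genes, labels))
  for (j in seq_len(k)) {
    cr <- contrasts[[j]]
    hit <- genes %in% cr$gene
    idx <- match(genes[hit], cr$gene)
    lfc[hit, j] <- cr$log2fc[idx]
    padj[hit, j] <- cr$padj[idx]
    sig[hit, j] <- genes[hit] %in% as.character(sig_sets[[j]])
  }
  new_master_result(genes, labels, lfc, padj, sig, mode, p_cut, lfc_cut)
}

#' @export
print.master_result <- function(x, ...) {
  cat(sprintf("master_result (%s): %d genes x %d contrasts (padj < %g, |lfc| >= %g)\n",
              x$mode, length(x$genes), length(x$contrasts),
              x$p_cut, x$lfc_cut))
  if (length(x$filters))
    cat("  filters applied:", length(x$filters), "\n")
  invisible(x)
}

#' Per-gene count of contrasts in which each master gene is significant
#' @param mr a `master_result`.
#' @return named integer vector over the master genes.
#' @export
overlap_counts <- function(mr) {
  stats::setNames(as.integer(rowSums(mr$sig)), mr$genes)
}

#' Agreement densities of the master gene set across contrasts
#'
#' For each contrast, the Gaussian kernel density (Silverman bandwidth) of
#' `padj` or `log2fc` restricted to the master genes, all evaluated on one
#' shared grid, plus the per-gene overlap counts. Used to judge whether
#' merging the contrasts was sensible: similar curves mean the contrasts
#' agree on the aggregated genes.
#'
#' @param mr a `master_result` with >= 2 genes.
#' @param on `"padj"` or `"lfc"`.
#' @return list of class `agreement_density`: `on`, `grid`, `curves` (named
#'   list of density vectors per contrast), `bandwidths`, `overlap`.
#' @export
agreement_density <- function(mr, on = c("padj", "lfc")) {
  on <- match.arg(on)
  if (length(mr$genes) < 2L)
    stop("density undefined for fewer than 2 master genes")
  vals <- if (on == "padj") mr$padj else mr$lfc
  per <- lapply(seq_along(mr$contrasts), function(j) {
    v <- vals[, j]; v[!is.na(v)]
  })
  bws <- vapply(per, silverman_bw, numeric(1))
  lo <- min(vapply(per, min, numeric(1))) - 3 * max(bws)
  hi <- max(vapply(per, max, numeric(1))) + 3 * max(bws)
  grid <- seq(lo, hi, length.out = 512L)
  curves <- lapply(seq_along(per), function(j)
    kde_1d(per[[j]], bandwidth = bws[j], grid = grid)$density)
  names(curves) <- mr$contrasts
  structure(list(on = on, grid = grid, curves = curves,
                 bandwidths = stats::setNames(bws, mr$contrasts),
                 overlap = overlap_counts(mr)),
            class = "agreement_density")
}

#' Filter a master result by thresholds
#'
#' Keeps genes meeting `padj < p_cut` and `|lfc| >= lfc_cut` in at least one
#' contrast (`scope = "any"`) or in all contrasts (`scope = "all"`); missing
#' cells never satisfy the cuts. The applied filter is appended to the
#' result's provenance. Idempotent at fixed parameters.
#'
#' @param mr a `master_result`.
#' @param p_cut,lfc_cut thresholds.
#' @param scope `"any"` or `"all"`.
#' @return Filtered `master_result`.
#' @export
filter_master <- function(mr, p_cut = mr$p_cut, lfc_cut = mr$lfc_cut,
                          scope = c("any", "all")) {
  scope <- match.arg(scope)
  pass <- !is.na(mr$padj) & mr$padj < p_cut &
          !is.na(mr$lfc) & abs(mr$lfc) >= lfc_cut
  keep <- if (scope == "any") rowSums(pass) >= 1L
          else rowSums(pass) == ncol(pass)
  if (!length(mr$genes)) keep <- logical(0)
  out <- new_master_result(mr$genes[keep], mr$contrasts,
                           mr$lfc[keep, , drop = FALSE],
                           mr$padj[keep, , drop = FALSE],
                           mr$sig[keep, , drop = FALSE],
                           mr$mode, mr$p_cut, mr$lfc_cut,
                           filters = c(mr$filters,
                                       list(list(p_cut = p_cut,
                                                 lfc_cut = lfc_cut,
                                                 scope = scope))))
  out
}

#' Subset samples by a metadata predicate
#'
#' Restricts the columns of a count matrix (and rows of its metadata) to the
#' samples satisfying every clause of a `factor = value` conjunction. Gene
#' rows are untouched. An empty predicate is the identity.
#'
#' @param cm a [count_matrix()].
#' @param md matching [sample_metadata()].
#' @param ... clauses as named arguments, e.g. `time = "1d", treatment = "ebov"`.
#' @return list with subset `counts` and `metadata`.
#' @export
subset_samples <- function(cm, md, ...) {
  clauses <- list(...)
  keep <- rep(TRUE, nrow(md))
  for (nm in names(clauses)) {
    if (!nm %in% metadata_factors(md))
      stop("factor '", nm, "' not in metadata")
    keep <- keep & as.character(md[[nm]]) %in% as.character(clauses[[nm]])
  }
  if (!any(keep)) stop("predicate matches no samples")
  ids <- md$sample_id[keep]
  y <- unclass(as.matrix(cm))[, ids, drop = FALSE]
  md2 <- as.data.frame(md)[keep, , drop = FALSE]
  list(counts = count_matrix(y), metadata = sample_metadata(md2))
}

#' Derive a composite metadata factor
#'
#' Appends a new factor whose values are the given factors' values joined by
#' `sep` (e.g. `treatment` and `time` become `"ebov_1d"`).
#'
#' @param md a [sample_metadata()].
#' @param fields factor names to combine.
#' @param name name of the new factor; default the fields joined by `sep`.
#' @param sep separator string.
#' @return The metadata with the composite factor appended.
#' @export
derive_metadata_field <- function(md, fields, name = NULL, sep = "_") {
  miss <- setdiff(fields, metadata_factors(md))
  if (length(miss)) stop("unknown factor(s): ", paste(miss, collapse = ", "))
  if (is.null(name)) name <- paste(fields, collapse = sep)
  if (name %in% names(md)) stop("factor '", name, "' already exists")
  vals <- do.call(paste, c(lapply(fields, function(f) as.character(md[[f]])),
                           sep = sep))
  out <- as.data.frame(md)
  out[[name]] <- vals
  sample_metadata(out)
}

#' Order master genes by a summary of their fold-change profile
#'
#' Per-gene summary of the lfc row across contrasts (missing cells ignored),
#' stable sort, ties broken by gene ID lexicographic order. `variance` and
#' `sd` use the sample (n-1) denominator.
#'
#' @param mr a non-empty `master_result`.
#' @param stat `"max"`, `"min"`, `"mean"`, `"variance"` or `"sd"`.
#' @param descending sort direction; default TRUE.
#' @return character vector of the master genes in order.
#' @export
sort_genes <- function(mr, stat = c("max", "min", "mean", "variance", "sd"),
                       descending = TRUE) {
  stat <- match.arg(stat)
  if (!length(mr$genes)) stop("empty master result")
  fn <- switch(stat,
               max = function(v) max(v), min = function(v) min(v),
               mean = function(v) mean(v),
               variance = function(v) if (length(v) > 1) stats::var(v) else 0,
               sd = function(v) if (length(v) > 1) stats::sd(v) else 0)
  s <- apply(mr$lfc, 1, function(row) fn(row[!is.na(row)]))
  o <- order(if (descending) -s else s, mr$genes, method = "radix")
  mr$genes[o]
}

#' Export a master result as aligned TSVs plus a provenance sidecar
#'
#' Writes `<stem>.lfc.tsv`, `<stem>.padj.tsv`, `<stem>.sig.tsv` (gene rows,
#' contrast columns) and `<stem>.provenance.txt` (flat `key = value` lines:
#' mode, thresholds, contrast labels, applied filters).
#'
#' @param mr a `master_result`.
#' @param stem output path stem (no extension).
#' @return character vector of the written paths, invisibly.
#' @export
write_master_result <- function(mr, stem) {
  write_mat <- function(m, path) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    path
  }
  lfc_m <- mr$lfc; padj_m <- mr$padj; sig_m <- mr$sig
  rownames(lfc_m) <- rownames(padj_m) <- rownames(sig_m) <- mr$genes
  paths <- c(write_mat(lfc_m, paste0(stem, ".lfc.tsv")),
             write_mat(padj_m, paste0(stem, ".padj.tsv")),
             write_mat(sig_m, paste0(stem, ".sig.tsv")))
  prov <- c(sprintf("mode = %s", mr$mode),
            sprintf("p_cut = %.17g", mr$p_cut),
            sprintf("lfc_cut = %.17g", mr$lfc_cut),
            sprintf("contrasts = %s", paste(mr$contrasts, collapse = ";")),
            vapply(seq_along(mr$filters), function(i)
              sprintf("filter_%d = p_cut %.17g, lfc_cut %.17g, scope %s", i,
                      mr$filters[[i]]$p_cut, mr$filters[[i]]$lfc_cut,
                      mr$filters[[i]]$scope), character(1)))
  prov_path <- paste0(stem, ".provenance.txt")
  writeLines(prov, prov_path)
  invisible(c(paths, prov_path))
}
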