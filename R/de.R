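## Significance calling and a minimal negative-binomial reference test.
## The reference test exists so the pipeline is exercisable end-to-end without
## an external DE engine; production contrasts are expected to come from a
## dedicated engine through read_contrast_table().

#' Call significant genes in a contrast
#'
#' A gene is significant when `padj < p_cut` (strict) AND
#' `|log2fc| >= lfc_cut` (non-strict). Genes with missing `padj` are never
#' significant.
#'
#' @param cr a [contrast_result()].
#' @param p_cut adjusted-p threshold in (0, 1].
#' @param lfc_cut non-negative absolute log2-fold-change threshold.
#' @return Character vector of significant gene IDs, class `significance_set`,
#'   with attributes `p_cut`, `lfc_cut` and `contrast_label`.
#' @export
call_significance <- function(cr, p_cut = 0.05, lfc_cut = 0) {
  if (!(p_cut > 0 && p_cut <= 1)) stop("p_cut must lie in (0, 1]")
  if (lfc_cut < 0) stop("lfc_cut must be non-negative")
  hit <- !is.na(cr$padj) & cr$padj < p_cut & abs(cr$log2fc) >= lfc_cut
  structure(cr$gene[hit], p_cut = p_cut, lfc_cut = lfc_cut,
            contrast_label = attr(cr, "contrast_label"),
            class = "significance_set")
}

#' Minimal negative-binomial Wald test between two groups
#'
#' A deliberately simple reference test: per gene, group means on the
#' counts-per-million scale; `log2fc = log2((m_a + 0.5)/(m_b + 0.5))`;
#' gene-wise dispersion by method of moments (`alpha = (var - mu)/mu^2` on
#' size-factor-normalized counts) pooled across the two groups and floored at
#' 1e-8; a two-sided Wald p-value from the delta-method standard error of the
#' log2 fold change; `padj` by [bh_adjust()]. No shrinkage, no independent
#' filtering — fixture generation and pipeline testing, not publication-grade
#' inference.
#'
#' @param cm a [count_matrix()].
#' @param md matching [sample_metadata()].
#' @param factor_name metadata factor defining the groups.
#' @param level_a numerator level (>= 2 samples).
#' @param level_b denominator level (>= 2 samples).
#' @param nf optional [tmm_factors()]; computed from the two groups' samples
#'   when `NULL`.
#' @return A [contrast_result()] labelled `(factor_name, level_a, level_b)`.
#' @export
nb_reference_test <- function(cm, md, factor_name, level_a, level_b,
                              nf = NULL) {
  if (!factor_name %in% metadata_factors(md))
    stop("factor '", factor_name, "' not in metadata")
  g <- as.character(md[[factor_name]])
  sa <- md$sample_id[g == level_a]
  sb <- md$sample_id[g == level_b]
  if (length(sa) < 2L) stop("level '", level_a, "' has fewer than 2 samples")
  if (length(sb) < 2L) stop("level '", level_b, "' has fewer than 2 samples")
  y <- unclass(as.matrix(cm))[, c(sa, sb), drop = FALSE]
  if (is.null(nf)) nf <- tmm_factors(count_matrix(y))
  f <- as.numeric(nf[colnames(y)])
  N <- colSums(y)
  cpm <- sweep(y, 2, 1e6 / (N * f), "*")
  ## size-factor-normalized counts for dispersion estimation: effective
  ## library sizes rescaled to geometric mean 1 keep the counts on their
  ## native scale
  sf <- (N * f) / exp(mean(log(N * f)))
  q <- sweep(y, 2, sf, "/")
  ia <- seq_along(sa); ib <- length(sa) + seq_along(sb)
  na <- length(sa); nb <- length(sb)
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])
  v_a <- apply(q[, ia, drop = FALSE], 1, stats::var)
  v_b <- apply(q[, ib, drop = FALSE], 1, stats::var)
  mom <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  alpha <- pmax(1e-8, ((na - 1) * mom(v_a, mu_a) + (nb - 1) * mom(v_b, mu_b)) /
                        (na + nb - 2))
  m_a <- rowMeans(cpm[, ia, drop = FALSE])
  m_b <- rowMeans(cpm[, ib, drop = FALSE])
  lfc <- log2((m_a + 0.5) / (m_b + 0.5))
  ## delta method on log2(mean + 0.5): Var(mean q) = (mu + alpha mu^2)/n,
  ## carried to the cpm scale by the (common within contrast) cpm/q ratio
  scale_cpm <- 1e6 / exp(mean(log(N * f)))
  var_ma <- scale_cpm^2 * (mu_a + alpha * mu_a^2) / na
  var_mb <- scale_cpm^2 * (mu_b + alpha * mu_b^2) / nb
  se2 <- (var_ma / (m_a + 0.5)^2 + var_mb / (m_b + 0.5)^2) / log(2)^2
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  contrast_result(
    data.frame(gene = rownames(y),
               mean_expr = (m_a + m_b) / 2,
               log2fc = lfc, pvalue = p, padj = bh_adjust(p),
               stringsAsFactors = FALSE),
    contrast_label = c(factor_name, level_a, level_b))
}
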