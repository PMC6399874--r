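## The visualization registry: 16 plot types, each split into a pure
## data-computation step (compute_plot_data -> plot_data, serializable to
## TSV) and a rendering step (render_plot). The numeric tables behind every
## figure are first-class and exportable.

PLOT_TYPES <- c(
  "sample_distance_heatmap", "group_dendrogram", "mds_confidence",
  "mds_hull", "boxplot_prenorm", "boxplot_postnorm", "foldchange_boxplot",
  "divergence_plot", "updown_summary", "volcano", "gene_heatmap",
  "profile_plot", "gene_boxplot_wilcoxon", "coexpression_series",
  "aggregation_density_p", "aggregation_density_lfc")

#' The registered plot types
#'
#' @return Character vector of the 16 plot type tags, in registry order.
#' @export
list_plot_types <- function() PLOT_TYPES

THEMES <- list(
  standard = list(palette = c("#1b6ca8", "#d1495b", "#66a182", "#edae49",
                              "#8d96a3", "#2e4057", "#a786c9", "#c97b63"),
                  fill_low = "#2166ac", fill_mid = "#f7f7f7",
                  fill_high = "#b2182b",
                  font_scale = 1, legend_position = "right", dark = FALSE),
  slate    = list(palette = c("#8ecae6", "#ffb703", "#fb8500", "#90be6d",
                              "#f94144", "#b5838d", "#cdb4db", "#a7c957"),
                  fill_low = "#48cae4", fill_mid = "#22333b",
                  fill_high = "#ffb703",
                  font_scale = 1, legend_position = "right", dark = TRUE),
  minimal  = list(palette = c("#444444", "#999999", "#1b6ca8", "#d1495b",
                              "#66a182", "#edae49", "#8d96a3", "#a786c9"),
                  fill_low = "#666666", fill_mid = "#ffffff",
                  fill_high = "#111111",
                  font_scale = 0.9, legend_position = "bottom", dark = FALSE),
  vibrant  = list(palette = c("#e6194b", "#3cb44b", "#4363d8", "#f58231",
                              "#911eb4", "#46f0f0", "#f032e6", "#bcf60c"),
                  fill_low = "#4363d8", fill_mid = "#ffffff",
                  fill_high = "#e6194b",
                  font_scale = 1.05, legend_position = "right", dark = FALSE),
  pastel   = list(palette = c("#a1c9f4", "#ffb482", "#8de5a1", "#ff9f9b",
                              "#d0bbff", "#debb9b", "#fab0e4", "#cfcfcf"),
                  fill_low = "#a1c9f4", fill_mid = "#ffffff",
                  fill_high = "#ff9f9b",
                  font_scale = 1, legend_position = "right", dark = FALSE),
  ocean    = list(palette = c("#03045e", "#0077b6", "#00b4d8", "#90e0ef",
                              "#014f86", "#2a6f97", "#61a5c2", "#89c2d9"),
                  fill_low = "#03045e", fill_mid = "#caf0f8",
                  fill_high = "#ff6b35",
                  font_scale = 1, legend_position = "right", dark = FALSE))

#' The built-in themes
#'
#' Six layout/color schemes; every plot type renders under every theme.
#'
#' @return Named list of theme definitions (palette, diverging fill anchors,
#'   font scale, legend placement).
#' @export
list_themes <- function() {
  lapply(stats::setNames(names(THEMES), names(THEMES)), get_theme)
}

get_theme <- function(theme) {
  if (inherits(theme, "de_theme")) return(theme)
  if (!theme %in% names(THEMES))
    stop("unknown theme '", theme, "'; available: ",
         paste(names(THEMES), collapse = ", "))
  structure(c(list(name = theme), THEMES[[theme]]), class = "de_theme")
}

new_plot_data <- function(plot_type, tables, params = list(),
                          provenance = character()) {
  stopifnot(plot_type %in% PLOT_TYPES)
  tables <- lapply(tables, function(df) { rownames(df) <- NULL; df })
  if (!length(params)) params <- structure(list(), names = character())
  structure(list(plot_type = plot_type, tables = tables, params = params,
                 provenance = provenance),
            class = "plot_data")
}

#' @export
print.plot_data <- function(x, ...) {
  cat(sprintf("plot_data '%s': tables [%s]\n", x$plot_type,
              paste(sprintf("%s %dx%d", names(x$tables),
                            vapply(x$tables, nrow, 1L),
                            vapply(x$tables, ncol, 1L)), collapse = ", ")))
  invisible(x)
}

## Tukey box summary per group of a long (group, value) table
box_summary <- function(group, value) {
  groups <- unique(group)
  stats_df <- do.call(rbind, lapply(groups, function(g) {
    v <- value[group == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- min(v[v >= q[1L] - 1.5 * iqr])
    hi <- max(v[v <= q[3L] + 1.5 * iqr])
    data.frame(group = g, lo = lo, q1 = q[1L], median = q[2L], q3 = q[3L],
               hi = hi, stringsAsFactors = FALSE)
  }))
  out_df <- do.call(rbind, lapply(groups, function(g) {
    v <- value[group == g]
    s <- stats_df[stats_df$group == g, ]
    o <- v[v < s$lo | v > s$hi]
    if (!length(o)) return(NULL)
    data.frame(group = g, value = o, stringsAsFactors = FALSE)
  }))
  if (is.null(out_df))
    out_df <- data.frame(group = character(), value = numeric(),
                         stringsAsFactors = FALSE)
  list(stats = stats_df, outliers = out_df)
}

dendrogram_segments <- function(dend) {
  n <- length(dend$labels)
  xpos <- numeric(n)
  xpos[dend$order] <- seq_len(n)
  node_x <- numeric(nrow(dend$merge))
  node_y <- dend$height
  seg <- NULL
  pos_of <- function(v) if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
  for (i in seq_len(nrow(dend$merge))) {
    a <- pos_of(dend$merge[i, 1L]); b <- pos_of(dend$merge[i, 2L])
    node_x[i] <- (a[1L] + b[1L]) / 2
    seg <- rbind(seg,
      data.frame(x = a[1L], y = a[2L], xend = a[1L], yend = node_y[i]),
      data.frame(x = b[1L], y = b[2L], xend = b[1L], yend = node_y[i]),
      data.frame(x = a[1L], y = node_y[i], xend = b[1L], yend = node_y[i]))
  }
  seg
}

group_of <- function(md, factor_name, ids) {
  as.character(md[[factor_name]])[match(ids, md$sample_id)]
}

#' Compute the numeric tables behind a plot
#'
#' The pure half of every visualization: given the domain objects a plot
#' type consumes, returns the exact tables the rendered figure is drawn
#' from, serializable to TSV ([write_plot_data()]) and reloadable
#' ([read_plot_data()]). Inputs are passed in a named list; which entries a
#' type needs is part of its contract:
#'
#' \describe{
#'   \item{sample_distance_heatmap}{`counts` (or `norm`); params `metric`,
#'     `linkage`.}
#'   \item{group_dendrogram}{`counts`/`norm` + `metadata`; params
#'     `factor_name`, `metric`, `linkage`.}
#'   \item{mds_confidence / mds_hull}{`counts`/`norm` + `metadata`; params
#'     `factor_name`, `metric`, `level`.}
#'   \item{boxplot_prenorm / boxplot_postnorm}{`counts` (+ `nf` for post);
#'     per-sample Tukey box summaries of log2 expression before/after scale
#'     normalization.}
#'   \item{foldchange_boxplot}{`master`; per-contrast lfc distributions over
#'     the master genes.}
#'   \item{divergence_plot}{`master`; per contrast, mean lfc of the
#'     significant up- and down-sets as signed bars.}
#'   \item{updown_summary}{`master`; per contrast, counts of significant
#'     up/down genes.}
#'   \item{volcano}{`contrast`; params `p_cut`, `lfc_cut`; per gene
#'     `(log2fc, -log10 padj, class)` with class one of `ns`, `p_only`,
#'     `lfc_only`, `both` (zero padj clamped to the table's smallest positive
#'     value).}
#'   \item{gene_heatmap}{`master`; params `top_n`, `stat`, `descending`,
#'     `cluster_rows`; top-N genes by [sort_genes()], lfc matrix, row/column
#'     display orders.}
#'   \item{profile_plot}{`master`; params `genes` or `top_n` + `stat`; lfc
#'     trajectories across contrasts.}
#'   \item{gene_boxplot_wilcoxon}{`counts` + `metadata`; params `gene`,
#'     `factor_name`; normalized expression split by the factor plus all
#'     pairwise Wilcoxon rank-sum results.}
#'   \item{coexpression_series}{`master`; params `k`; [cluster_profiles()]
#'     assignments, z-scored series and cluster mean profiles.}
#'   \item{aggregation_density_p / aggregation_density_lfc}{`master`;
#'     [agreement_density()] curves and overlap counts.}
#' }
#'
#' @param plot_type one of [list_plot_types()].
#' @param inputs named list of domain objects (see above).
#' @param params named list of per-type options.
#' @return A `plot_data` object.
#' @export
compute_plot_data <- function(plot_type, inputs = list(), params = list()) {
  if (!plot_type %in% PLOT_TYPES)
    stop("unknown plot type '", plot_type, "'; see list_plot_types()")
  need <- function(nm) {
    if (is.null(inputs[[nm]]))
      stop(sprintf("plot type '%s' needs input '%s'", plot_type, nm))
    inputs[[nm]]
  }
  par_or <- function(nm, default) if (is.null(params[[nm]])) default else params[[nm]]
  prov <- sprintf("plot=%s", plot_type)

  if (plot_type %in% c("sample_distance_heatmap", "group_dendrogram",
                       "mds_confidence", "mds_hull")) {
    dat <- if (!is.null(inputs$norm)) inputs$norm else need("counts")
    metric <- par_or("metric",
                     if (inherits(dat, "count_matrix")) "poisson" else "euclidean")
    dm <- distance_matrix(dat, metric = metric, axis = "samples")
    if (plot_type == "sample_distance_heatmap") {
      linkage <- par_or("linkage", "complete")
      dend <- hcluster(dm, linkage = linkage)
      ord <- dend$labels[dend$order]
      long <- data.frame(row = rep(rownames(dm), ncol(dm)),
                         col = rep(colnames(dm), each = nrow(dm)),
                         distance = as.vector(unclass(dm)),
                         stringsAsFactors = FALSE)
      return(new_plot_data(plot_type,
        list(distance = long,
             order = data.frame(position = seq_along(ord), sample = ord,
                                stringsAsFactors = FALSE)),
        params = list(metric = metric, linkage = linkage), provenance = prov))
    }
    if (plot_type == "group_dendrogram") {
      md <- need("metadata")
      factor_name <- par_or("factor_name", metadata_factors(md)[1L])
      linkage <- par_or("linkage", "complete")
      dend <- hcluster(dm, linkage = linkage)
      leaves <- data.frame(position = seq_along(dend$order),
                           sample = dend$labels[dend$order],
                           stringsAsFactors = FALSE)
      leaves$group <- group_of(md, factor_name, leaves$sample)
      return(new_plot_data(plot_type,
        list(segments = dendrogram_segments(dend), leaves = leaves),
        params = list(metric = metric, linkage = linkage,
                      factor_name = factor_name), provenance = prov))
    }
    ## MDS variants
    md <- need("metadata")
    factor_name <- par_or("factor_name", metadata_factors(md)[1L])
    level <- par_or("level", 0.95)
    emb <- classical_mds(dm, k = 2L)
    style <- if (plot_type == "mds_confidence") "ellipse" else "hull"
    ov <- group_overlay(emb, md, factor_name, style = style, level = level)
    pts <- data.frame(sample = rownames(emb$points),
                      dim1 = emb$points[, 1L], dim2 = emb$points[, 2L],
                      stringsAsFactors = FALSE)
    pts$group <- group_of(md, factor_name, pts$sample)
    shp <- do.call(rbind, lapply(names(ov$groups), function(g) {
      xy <- if (style == "ellipse") ellipse_path(ov$groups[[g]])
            else ov$groups[[g]]$vertices
      data.frame(group = g, order = seq_len(nrow(xy)),
                 x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
    }))
    if (is.null(shp))
      shp <- data.frame(group = character(), order = integer(),
                        x = numeric(), y = numeric(), stringsAsFactors = FALSE)
    return(new_plot_data(plot_type,
      list(points = pts, overlay = shp),
      params = list(metric = metric, factor_name = factor_name,
                    level = level, style = style,
                    var_explained = round(emb$var_explained, 6),
                    skipped_groups = ov$skipped), provenance = prov))
  }

  if (plot_type %in% c("boxplot_prenorm", "boxplot_postnorm")) {
    cm <- need("counts")
    if (plot_type == "boxplot_prenorm") {
      nm <- log2(unclass(as.matrix(cm)) + 1)
      lab <- "log2(count + 1)"
    } else {
      nf <- if (!is.null(inputs$nf)) inputs$nf else tmm_factors(cm)
      nm <- unclass(normalize_counts(cm, nf, method = "log2cpm"))
      lab <- "log2 CPM (TMM)"
    }
    long_group <- rep(colnames(nm), each = nrow(nm))
    bs <- box_summary(long_group, as.vector(nm))
    names(bs$stats)[1L] <- "sample"; names(bs$outliers)[1L] <- "sample"
    return(new_plot_data(plot_type, bs,
                         params = list(value_label = lab), provenance = prov))
  }

  if (plot_type == "foldchange_boxplot") {
    mr <- need("master")
    long <- data.frame(contrast = rep(mr$contrasts, each = length(mr$genes)),
                       lfc = as.vector(mr$lfc), stringsAsFactors = FALSE)
    long <- long[!is.na(long$lfc), ]
    bs <- box_summary(long$contrast, long$lfc)
    names(bs$stats)[1L] <- "contrast"; names(bs$outliers)[1L] <- "contrast"
    return(new_plot_data(plot_type, bs,
                         params = list(n_genes = length(mr$genes)),
                         provenance = prov))
  }

  if (plot_type == "divergence_plot") {
    mr <- need("master")
    rows <- do.call(rbind, lapply(seq_along(mr$contrasts), function(j) {
      up <- mr$sig[, j] & !is.na(mr$lfc[, j]) & mr$lfc[, j] > 0
      dn <- mr$sig[, j] & !is.na(mr$lfc[, j]) & mr$lfc[, j] < 0
      data.frame(contrast = mr$contrasts[j],
                 direction = c("up", "down"),
                 mean_lfc = c(if (any(up)) mean(mr$lfc[up, j]) else 0,
                              if (any(dn)) mean(mr$lfc[dn, j]) else 0),
                 n = c(sum(up), sum(dn)), stringsAsFactors = FALSE)
    }))
    return(new_plot_data(plot_type, list(divergence = rows),
                         provenance = prov))
  }

  if (plot_type == "updown_summary") {
    mr <- need("master")
    rows <- do.call(rbind, lapply(seq_along(mr$contrasts), function(j) {
      data.frame(contrast = mr$contrasts[j],
                 direction = c("up", "down"),
                 count = c(sum(mr$sig[, j] & !is.na(mr$lfc[, j]) & mr$lfc[, j] > 0),
                           sum(mr$sig[, j] & !is.na(mr$lfc[, j]) & mr$lfc[, j] < 0)),
                 stringsAsFactors = FALSE)
    }))
    return(new_plot_data(plot_type, list(counts = rows), provenance = prov))
  }

  if (plot_type == "volcano") {
    cr <- need("contrast")
    p_cut <- par_or("p_cut", 0.05); lfc_cut <- par_or("lfc_cut", 1)
    padj <- cr$padj
    minpos <- suppressWarnings(min(padj[!is.na(padj) & padj > 0]))
    padj[!is.na(padj) & padj == 0] <- if (is.finite(minpos)) minpos
                                      else .Machine$double.xmin
    p_pass <- !is.na(padj) & padj < p_cut
    l_pass <- abs(cr$log2fc) >= lfc_cut
    cls <- ifelse(p_pass & l_pass, "both",
           ifelse(p_pass, "p_only", ifelse(l_pass, "lfc_only", "ns")))
    pts <- data.frame(gene = cr$gene, log2fc = cr$log2fc,
                      neglog10_padj = -log10(padj), class = cls,
                      stringsAsFactors = FALSE)
    return(new_plot_data(plot_type, list(points = pts),
                         params = list(p_cut = p_cut, lfc_cut = lfc_cut,
                                       contrast = contrast_name(cr)),
                         provenance = prov))
  }

  if (plot_type == "gene_heatmap") {
    mr <- need("master")
    stat <- par_or("stat", "max"); descending <- par_or("descending", TRUE)
    top_n <- par_or("top_n", 30L)
    if (top_n > length(mr$genes)) {
      warning("top_n exceeds available genes; clamped to ", length(mr$genes))
      top_n <- length(mr$genes)
    }
    sel <- sort_genes(mr, stat = stat, descending = descending)[seq_len(top_n)]
    m <- mr$lfc[match(sel, mr$genes), , drop = FALSE]
    rownames(m) <- sel
    cluster_rows <- par_or("cluster_rows", TRUE)
    row_ord <- if (cluster_rows && length(sel) > 1L) {
      m0 <- m; m0[is.na(m0)] <- 0
      dend <- hcluster(distance_matrix(t(m0), "euclidean", axis = "samples"),
                       linkage = "complete")
      dend$labels[dend$order]
    } else sel
    vals <- data.frame(gene = rep(rownames(m), ncol(m)),
                       contrast = rep(colnames(m), each = nrow(m)),
                       lfc = as.vector(m), stringsAsFactors = FALSE)
    return(new_plot_data(plot_type,
      list(values = vals,
           selection = data.frame(rank = seq_along(sel), gene = sel,
                                  stringsAsFactors = FALSE),
           row_order = data.frame(position = seq_along(row_ord),
                                  gene = row_ord, stringsAsFactors = FALSE),
           col_order = data.frame(position = seq_along(mr$contrasts),
                                  contrast = mr$contrasts,
                                  stringsAsFactors = FALSE)),
      params = list(top_n = top_n, stat = stat, descending = descending,
                    cluster_rows = cluster_rows), provenance = prov))
  }

  if (plot_type == "profile_plot") {
    mr <- need("master")
    genes <- params$genes
    if (is.null(genes)) {
      top_n <- min(par_or("top_n", 10L), length(mr$genes))
      genes <- sort_genes(mr, stat = par_or("stat", "sd"))[seq_len(top_n)]
    }
    miss <- setdiff(genes, mr$genes)
    if (length(miss)) stop("genes not in master result: ",
                           paste(miss, collapse = ", "))
    idx <- match(genes, mr$genes)
    traj <- data.frame(gene = rep(genes, length(mr$contrasts)),
                       contrast = rep(mr$contrasts, each = length(genes)),
                       contrast_index = rep(seq_along(mr$contrasts),
                                            each = length(genes)),
                       lfc = as.vector(mr$lfc[idx, , drop = FALSE]),
                       stringsAsFactors = FALSE)
    return(new_plot_data(plot_type, list(trajectories = traj),
                         params = list(genes = genes), provenance = prov))
  }

  if (plot_type == "gene_boxplot_wilcoxon") {
    cm <- need("counts"); md <- need("metadata")
    gene <- params$gene
    if (is.null(gene)) stop("plot type 'gene_boxplot_wilcoxon' needs params$gene")
    factor_name <- par_or("factor_name", metadata_factors(md)[1L])
    if (!gene %in% rownames(cm)) stop("gene '", gene, "' not in count matrix")
    nf <- if (!is.null(inputs$nf)) inputs$nf else tmm_factors(cm)
    nm <- unclass(normalize_counts(cm, nf, method = "log2cpm"))
    expr <- nm[gene, md$sample_id]
    grp <- as.character(md[[factor_name]])
    values <- data.frame(sample = md$sample_id, group = grp, expr = expr,
                         stringsAsFactors = FALSE)
    levs <- unique(grp)
    tests <- NULL
    if (length(levs) > 1L) {
      pairs <- utils::combn(levs, 2L)
      tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        a <- pairs[1L, i]; b <- pairs[2L, i]
        tr <- wilcoxon_rank_sum(expr[grp == a], expr[grp == b])
        data.frame(group1 = a, group2 = b, statistic = tr$statistic,
                   p_value = tr$p_value, method = tr$method,
                   stringsAsFactors = FALSE)
      }))
    } else {
      tests <- data.frame(group1 = character(), group2 = character(),
                          statistic = numeric(), p_value = numeric(),
                          method = character(), stringsAsFactors = FALSE)
    }
    return(new_plot_data(plot_type, list(values = values, tests = tests),
                         params = list(gene = gene, factor_name = factor_name),
                         provenance = prov))
  }

  if (plot_type == "coexpression_series") {
    mr <- need("master")
    k <- par_or("k", min(4L, max(2L, length(mr$genes) - 1L)))
    pc <- cluster_profiles(mr, k = k)
    genes <- names(pc$labels)
    idx <- match(genes, mr$genes)
    m <- mr$lfc[idx, , drop = FALSE]
    mu <- rowMeans(m); s <- apply(m, 1, stats::sd)
    z <- (m - mu) / ifelse(s > 0, s, 1); z[s == 0, ] <- 0
    series <- data.frame(gene = rep(genes, length(mr$contrasts)),
                         cluster = rep(unname(pc$labels), length(mr$contrasts)),
                         contrast = rep(mr$contrasts, each = length(genes)),
                         contrast_index = rep(seq_along(mr$contrasts),
                                              each = length(genes)),
                         z = as.vector(z), stringsAsFactors = FALSE)
    centers <- data.frame(cluster = rep(seq_len(k), length(mr$contrasts)),
                          contrast = rep(mr$contrasts, each = k),
                          contrast_index = rep(seq_along(mr$contrasts),
                                               each = k),
                          mean_z = as.vector(pc$centers),
                          stringsAsFactors = FALSE)
    return(new_plot_data(plot_type,
      list(assignments = data.frame(gene = genes,
                                    cluster = unname(pc$labels),
                                    stringsAsFactors = FALSE),
           series = series, centers = centers),
      params = list(k = k, excluded = pc$excluded), provenance = prov))
  }

  ## aggregation_density_p / aggregation_density_lfc
  mr <- need("master")
  on <- if (plot_type == "aggregation_density_p") "padj" else "lfc"
  ad <- agreement_density(mr, on = on)
  curves <- do.call(rbind, lapply(names(ad$curves), function(nm)
    data.frame(contrast = nm, x = ad$grid, density = ad$curves[[nm]],
               stringsAsFactors = FALSE)))
  overlap <- data.frame(gene = names(ad$overlap),
                        n_significant = unname(ad$overlap),
                        stringsAsFactors = FALSE)
  new_plot_data(plot_type, list(curves = curves, overlap = overlap),
                params = list(on = on,
                              bandwidths = round(unname(ad$bandwidths), 10)),
                provenance = prov)
}
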