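## Serialization of plot_data to TSV sidecars and ggplot2 rendering.

#' Serialize plot data to TSV sidecar files
#'
#' Writes one `<stem>.<table>.tsv` per table (numerics at full precision)
#' plus `<stem>.meta.tsv` holding the plot type, parameters and provenance
#' as parseable key-value pairs. [read_plot_data()] reproduces the object
#' exactly.
#'
#' @param pd a `plot_data`.
#' @param stem output path stem (no extension).
#' @return character vector of written paths, invisibly.
#' @export
write_plot_data <- function(pd, stem) {
  paths <- character()
  for (nm in names(pd$tables)) {
    df <- pd$tables[[nm]]
    out <- df
    for (cl in names(out))
      if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
        out[[cl]] <- sprintf("%.17g", out[[cl]])
    p <- sprintf("%s.%s.tsv", stem, nm)
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  meta <- c(sprintf("plot_type\t%s", pd$plot_type),
            sprintf("tables\t%s", paste(names(pd$tables), collapse = ",")),
            sprintf("column_types\t%s", paste(vapply(names(pd$tables),
              function(nm) paste(vapply(pd$tables[[nm]], function(col)
                class(col)[1L], character(1)), collapse = ","), character(1)),
              collapse = ";")),
            sprintf("provenance\t%s", paste(pd$provenance, collapse = ";")),
            vapply(names(pd$params), function(nm)
              sprintf("param:%s\t%s", nm,
                      paste(deparse(pd$params[[nm]]), collapse = "")),
              character(1)))
  mp <- sprintf("%s.meta.tsv", stem)
  writeLines(meta, mp)
  invisible(c(paths, mp))
}

#' Reload serialized plot data
#'
#' @param stem the path stem given to [write_plot_data()].
#' @return The reconstructed `plot_data`.
#' @export
read_plot_data <- function(stem) {
  mp <- sprintf("%s.meta.tsv", stem)
  if (!file.exists(mp)) stop("no plot-data metadata at ", mp)
  meta <- strsplit(readLines(mp), "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, function(x)
    if (length(x) > 1L) x[2L] else "", character(1)),
    vapply(meta, `[`, character(1), 1L))
  tbl_names <- strsplit(kv[["tables"]], ",", fixed = TRUE)[[1]]
  col_types <- strsplit(strsplit(kv[["column_types"]], ";", fixed = TRUE)[[1]],
                        ",", fixed = TRUE)
  tables <- lapply(seq_along(tbl_names), function(i) {
    df <- utils::read.table(sprintf("%s.%s.tsv", stem, tbl_names[i]),
                            header = TRUE, sep = "\t", quote = "",
                            na.strings = "NA", colClasses = col_types[[i]],
                            check.names = FALSE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    df
  })
  names(tables) <- tbl_names
  pk <- grep("^param:", names(kv), value = TRUE)
  params <- structure(lapply(kv[pk], function(s) eval(parse(text = s))),
                      names = sub("^param:", "", pk))
  new_plot_data(kv[["plot_type"]], tables, params = params,
                provenance = strsplit(kv[["provenance"]], ";",
                                      fixed = TRUE)[[1]])
}

apply_theme <- function(p, th, discrete_aes = character()) {
  base <- if (th$dark)
    ggplot2::theme_dark(base_size = 11 * th$font_scale)
  else
    ggplot2::theme_bw(base_size = 11 * th$font_scale)
  p <- p + base + ggplot2::theme(legend.position = th$legend_position)
  if ("colour" %in% discrete_aes)
    p <- p + ggplot2::scale_colour_manual(
      values = rep_len(th$palette, 50), drop = TRUE)
  if ("fill" %in% discrete_aes)
    p <- p + ggplot2::scale_fill_manual(
      values = rep_len(th$palette, 50), drop = TRUE)
  p
}

build_plot <- function(pd, th) {
  t1 <- pd$tables[[1L]]
  switch(pd$plot_type,
    sample_distance_heatmap = {
      ord <- pd$tables$order$sample
      df <- pd$tables$distance
      df$row <- factor(df$row, levels = ord)
      df$col <- factor(df$col, levels = ord)
      p <- ggplot2::ggplot(df, ggplot2::aes(col, row, fill = distance)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient(low = th$fill_mid, high = th$fill_low) +
        ggplot2::labs(x = NULL, y = NULL, title = "Sample distances") +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           hjust = 1))
      apply_theme(p, th) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           hjust = 1))
    },
    group_dendrogram = {
      p <- ggplot2::ggplot() +
        ggplot2::geom_segment(data = pd$tables$segments,
          ggplot2::aes(x = x, y = y, xend = xend, yend = yend)) +
        ggplot2::geom_point(data = pd$tables$leaves,
          ggplot2::aes(x = position, y = 0, colour = group), size = 2) +
        ggplot2::geom_text(data = pd$tables$leaves,
          ggplot2::aes(x = position, y = 0, label = sample),
          angle = 90, hjust = 1.1, size = 2.5 * th$font_scale) +
        ggplot2::labs(x = NULL, y = "height", title = "Sample dendrogram")
      apply_theme(p, th, "colour")
    },
    mds_confidence = ,
    mds_hull = {
      p <- ggplot2::ggplot(pd$tables$points,
                           ggplot2::aes(dim1, dim2, colour = group)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(title = sprintf("MDS (%s)", pd$params$style))
      if (nrow(pd$tables$overlay))
        p <- p + ggplot2::geom_polygon(data = pd$tables$overlay,
          ggplot2::aes(x, y, colour = group, fill = group), alpha = 0.15,
          inherit.aes = FALSE)
      apply_theme(p, th, c("colour", "fill"))
    },
    boxplot_prenorm = ,
    boxplot_postnorm = {
      st <- pd$tables$stats
      p <- ggplot2::ggplot(st, ggplot2::aes(x = sample, fill = sample)) +
        ggplot2::geom_boxplot(ggplot2::aes(ymin = lo, lower = q1,
          middle = median, upper = q3, ymax = hi), stat = "identity") +
        ggplot2::labs(y = pd$params$value_label, x = NULL,
                      title = if (pd$plot_type == "boxplot_prenorm")
                        "Expression before normalization"
                      else "Expression after normalization") +
        ggplot2::guides(fill = "none")
      if (nrow(pd$tables$outliers))
        p <- p + ggplot2::geom_point(data = pd$tables$outliers,
          ggplot2::aes(sample, value), inherit.aes = FALSE, size = 0.6)
      apply_theme(p, th, "fill") +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           hjust = 1))
    },
    foldchange_boxplot = {
      st <- pd$tables$stats
      p <- ggplot2::ggplot(st, ggplot2::aes(x = contrast, fill = contrast)) +
        ggplot2::geom_boxplot(ggplot2::aes(ymin = lo, lower = q1,
          middle = median, upper = q3, ymax = hi), stat = "identity") +
        ggplot2::labs(y = "log2 fold change", x = NULL,
                      title = "Fold-change distribution per contrast") +
        ggplot2::guides(fill = "none")
      if (nrow(pd$tables$outliers))
        p <- p + ggplot2::geom_point(data = pd$tables$outliers,
          ggplot2::aes(contrast, value), inherit.aes = FALSE, size = 0.6)
      apply_theme(p, th, "fill")
    },
    divergence_plot = {
      p <- ggplot2::ggplot(pd$tables$divergence,
        ggplot2::aes(contrast, mean_lfc, fill = direction)) +
        ggplot2::geom_col(position = "identity") +
        ggplot2::geom_hline(yintercept = 0) +
        ggplot2::labs(y = "mean log2 fold change of significant set",
                      title = "Group-wise fold-change divergence")
      apply_theme(p, th, "fill")
    },
    updown_summary = {
      df <- pd$tables$counts
      df$signed <- ifelse(df$direction == "up", df$count, -df$count)
      p <- ggplot2::ggplot(df,
        ggplot2::aes(contrast, signed, fill = direction)) +
        ggplot2::geom_col() + ggplot2::geom_hline(yintercept = 0) +
        ggplot2::labs(y = "significant genes (down / up)",
                      title = "Up/down regulation summary")
      apply_theme(p, th, "fill")
    },
    volcano = {
      df <- pd$tables$points
      p <- ggplot2::ggplot(df[!is.na(df$neglog10_padj), ],
        ggplot2::aes(log2fc, neglog10_padj, colour = class)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::geom_vline(xintercept = c(-1, 1) * pd$params$lfc_cut,
                            linetype = 2) +
        ggplot2::geom_hline(yintercept = -log10(pd$params$p_cut),
                            linetype = 2) +
        ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                      title = paste("Volcano:", pd$params$contrast))
      apply_theme(p, th, "colour")
    },
    gene_heatmap = {
      df <- pd$tables$values
      df$gene <- factor(df$gene, levels = rev(pd$tables$row_order$gene))
      df$contrast <- factor(df$contrast, levels = pd$tables$col_order$contrast)
      p <- ggplot2::ggplot(df, ggplot2::aes(contrast, gene, fill = lfc)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient2(low = th$fill_low, mid = th$fill_mid,
                                      high = th$fill_high, midpoint = 0) +
        ggplot2::labs(x = NULL, y = NULL, title = "Gene heat map (log2 FC)")
      apply_theme(p, th) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    },
    profile_plot = {
      df <- pd$tables$trajectories
      p <- ggplot2::ggplot(df,
        ggplot2::aes(contrast_index, lfc, colour = gene, group = gene)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::scale_x_continuous(
          breaks = unique(df$contrast_index),
          labels = df$contrast[!duplicated(df$contrast_index)]) +
        ggplot2::labs(x = NULL, y = "log2 fold change",
                      title = "Expression profiles across contrasts")
      apply_theme(p, th, "colour")
    },
    gene_boxplot_wilcoxon = {
      df <- pd$tables$values
      bs <- box_summary(df$group, df$expr)
      tst <- pd$tables$tests
      sub <- if (nrow(tst))
        paste(sprintf("%s vs %s: p=%.3g", tst$group1, tst$group2,
                      tst$p_value), collapse = "; ")
      else NULL
      p <- ggplot2::ggplot(bs$stats, ggplot2::aes(group, fill = group)) +
        ggplot2::geom_boxplot(ggplot2::aes(ymin = lo, lower = q1,
          middle = median, upper = q3, ymax = hi), stat = "identity") +
        ggplot2::geom_point(data = df, ggplot2::aes(group, expr),
                            inherit.aes = FALSE, size = 1) +
        ggplot2::labs(y = "log2 CPM", x = pd$params$factor_name,
                      title = sprintf("%s by %s (Wilcoxon)", pd$params$gene,
                                      pd$params$factor_name),
                      subtitle = sub) +
        ggplot2::guides(fill = "none")
      apply_theme(p, th, "fill")
    },
    coexpression_series = {
      df <- pd$tables$series
      ctr <- pd$tables$centers
      p <- ggplot2::ggplot(df,
        ggplot2::aes(contrast_index, z, group = gene)) +
        ggplot2::geom_line(alpha = 0.3, colour = th$palette[1L]) +
        ggplot2::geom_line(data = ctr,
          ggplot2::aes(contrast_index, mean_z, group = cluster),
          colour = th$palette[2L], linewidth = 1) +
        ggplot2::facet_wrap(~cluster) +
        ggplot2::labs(x = "contrast", y = "z-scored log2 FC",
                      title = "Co-expression series")
      apply_theme(p, th)
    },
    aggregation_density_p = ,
    aggregation_density_lfc = {
      df <- pd$tables$curves
      p <- ggplot2::ggplot(df,
        ggplot2::aes(x, density, colour = contrast)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = if (pd$params$on == "padj") "adjusted p-value"
                      else "log2 fold change",
                      title = "Aggregation agreement density")
      apply_theme(p, th, "colour")
    },
    stop("no renderer for plot type '", pd$plot_type, "'"))
}

#' Render plot data to a figure file
#'
#' The figure is a pure function of the plot data, the theme and the size
#' ([figure_size()]). With a project whose autosave toggles are on
#' ([init_project()], [set_autosave()]), the figure is written in both pdf
#' and png into the project scaffold together with its plot-data sidecars,
#' and each file is logged; otherwise an explicit `path` is required.
#'
#' @param pd a `plot_data` from [compute_plot_data()].
#' @param theme theme name or object ([list_themes()]).
#' @param path explicit output file (`.pdf` or `.png`); ignored when saving
#'   into a project.
#' @param fmt output format; default from the path extension.
#' @param dpi raster resolution for png.
#' @param base base width/height in inches before auto-rescaling.
#' @param project optional `project_layout`.
#' @param name file stem used inside the project scaffold; default the plot
#'   type.
#' @return character vector of written file paths, invisibly.
#' @export
render_plot <- function(pd, theme = "standard", path = NULL, fmt = NULL,
                        dpi = 300, base = c(7, 7), project = NULL,
                        name = NULL) {
  th <- get_theme(theme)
  size <- figure_size(pd, base = base)
  p <- build_plot(pd, th)
  write_one <- function(file, fmt) {
    if (!fmt %in% c("pdf", "png")) stop("unknown format '", fmt, "'")
    dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
    if (fmt == "pdf")
      grDevices::pdf(file, width = size[1L], height = size[2L],
                     onefile = FALSE)
    else
      grDevices::png(file, width = size[1L], height = size[2L],
                     units = "in", res = dpi, type = "cairo")
    ok <- FALSE
    tryCatch({ print(p); ok <- TRUE }, finally = grDevices::dev.off())
    if (!ok) stop("rendering failed for ", pd$plot_type)
    file
  }
  if (!is.null(project)) {
    if (is.null(name)) name <- pd$plot_type
    name <- sanitize_name(name)
    written <- character()
    if (isTRUE(project$autosave_figures)) {
      for (f in c("pdf", "png")) {
        file <- versioned_path(file.path(project$paths[[paste0("figures_", f)]],
                                         paste0(name, ".", f)))
        written <- c(written, write_one(file, f))
        project_log(project, "render", file)
      }
    }
    if (isTRUE(project$autosave_data)) {
      stem <- versioned_stem(file.path(project$paths$figures_data, name),
                             ".meta.tsv")
      side <- write_plot_data(pd, stem)
      for (f in side) project_log(project, "plot_data", f)
      written <- c(written, side)
    }
    return(invisible(written))
  }
  if (is.null(path)) stop("supply a path or a project with autosave enabled")
  if (is.null(fmt)) fmt <- tolower(tools::file_ext(path))
  invisible(write_one(path, fmt))
}
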