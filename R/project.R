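## Standardized project workspace: a fixed directory scaffold created at
## initialization, a flat key-value config snapshot, toggled auto-export of
## figures and data, collision-safe (versioned) writes, and an append-only
## log so every file in the scaffold is accounted for.

PROJECT_SUBDIRS <- c(
  de_lists     = "results/de_lists",
  master       = "results/master",
  figures_pdf  = "figures/pdf",
  figures_png  = "figures/png",
  figures_data = "figures/data",
  logs         = "logs",
  config       = "config")

#' Initialize a project workspace
#'
#' Creates the standardized scaffold under `root`:
#' `results/de_lists`, `results/master`, `figures/pdf`, `figures/png`,
#' `figures/data`, `logs`, `config`, and writes a config snapshot. With
#' `overwrite_policy = "merge"` re-initialization is lossless and idempotent;
#' with `"refuse"` a non-empty existing root is an error and nothing is
#' touched.
#'
#' @param root project root directory (created if absent).
#' @param overwrite_policy `"refuse"` or `"merge"`.
#' @param autosave_data,autosave_figures initial auto-export toggles.
#' @param fmt default figure format; `dpi` default raster resolution.
#' @param dpi default raster resolution.
#' @return list of class `project_layout`: `root`, named `paths`, toggles and
#'   figure defaults.
#' @export
init_project <- function(root, overwrite_policy = c("merge", "refuse"),
                         autosave_data = TRUE, autosave_figures = TRUE,
                         fmt = "pdf", dpi = 300) {
  overwrite_policy <- match.arg(overwrite_policy)
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) &&
      overwrite_policy == "refuse")
    stop("root '", root, "' exists and is non-empty (policy: refuse)")
  existing <- if (file.exists(file.path(root, "config", "config.txt")))
    read_config(file.path(root, "config", "config.txt")) else list()
  pl <- structure(list(
    root = normalizePath(root, mustWork = FALSE),
    paths = NULL,
    autosave_data = if (!is.null(existing$autosave_data))
      existing$autosave_data else autosave_data,
    autosave_figures = if (!is.null(existing$autosave_figures))
      existing$autosave_figures else autosave_figures,
    fmt = if (!is.null(existing$fmt)) existing$fmt else fmt,
    dpi = if (!is.null(existing$dpi)) existing$dpi else dpi),
    class = "project_layout")
  for (d in PROJECT_SUBDIRS)
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  pl$root <- normalizePath(root)
  pl$paths <- lapply(PROJECT_SUBDIRS, function(d) file.path(pl$root, d))
  write_config(pl)
  pl
}

config_path <- function(pl) file.path(pl$paths$config, "config.txt")

write_config <- function(pl) {
  lines <- c(sprintf("autosave_data = %s", tolower(pl$autosave_data)),
             sprintf("autosave_figures = %s", tolower(pl$autosave_figures)),
             sprintf("fmt = %s", pl$fmt),
             sprintf("dpi = %d", as.integer(pl$dpi)))
  writeLines(lines, config_path(pl))
  invisible(pl)
}

read_config <- function(path) {
  kv <- strsplit(readLines(path), " = ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2L),
                          vapply(kv, `[`, character(1), 1L))
  list(autosave_data = identical(vals$autosave_data, "true"),
       autosave_figures = identical(vals$autosave_figures, "true"),
       fmt = vals$fmt,
       dpi = as.integer(vals$dpi))
}

#' Reload an existing project from its root
#'
#' @param root project root containing a config snapshot.
#' @return The `project_layout` recorded on disk.
#' @export
load_project <- function(root) {
  if (!file.exists(file.path(root, "config", "config.txt")))
    stop("no project config under '", root, "'")
  init_project(root, overwrite_policy = "merge")
}

#' Toggle automatic export of data and figures
#'
#' @param pl a `project_layout`.
#' @param data autosave plot-data sidecars and result exports.
#' @param figures autosave rendered figures (pdf + png).
#' @return The updated layout (persisted to the config snapshot).
#' @export
set_autosave <- function(pl, data = pl$autosave_data,
                         figures = pl$autosave_figures) {
  pl$autosave_data <- isTRUE(data)
  pl$autosave_figures <- isTRUE(figures)
  write_config(pl)
  pl
}

#' @export
print.project_layout <- function(x, ...) {
  cat("project:", x$root, "\n",
      sprintf("  autosave: data=%s figures=%s (fmt=%s, dpi=%d)\n",
              x$autosave_data, x$autosave_figures, x$fmt, x$dpi))
  invisible(x)
}

sanitize_name <- function(name) {
  out <- gsub("[^A-Za-z0-9._-]+", "_", name)
  out <- gsub("^_+|_+$", "", out)
  if (!nzchar(out)) stop("name '", name, "' empty after sanitization")
  out
}

## next free path: base, then _v2, _v3, ... — never overwrite silently
versioned_path <- function(path) {
  if (!file.exists(path)) return(path)
  ext <- tools::file_ext(path)
  stem <- tools::file_path_sans_ext(path)
  v <- 2L
  repeat {
    cand <- sprintf("%s_v%d.%s", stem, v, ext)
    if (!file.exists(cand)) return(cand)
    v <- v + 1L
  }
}

## versioning for multi-file stems, probed by a marker suffix
versioned_stem <- function(stem, probe) {
  if (!file.exists(paste0(stem, probe))) return(stem)
  v <- 2L
  repeat {
    cand <- sprintf("%s_v%d", stem, v)
    if (!file.exists(paste0(cand, probe))) return(cand)
    v <- v + 1L
  }
}

project_log <- function(pl, action, file, params = "") {
  rel <- file
  pref <- paste0(pl$root, "/")
  if (startsWith(rel, pref)) rel <- substring(rel, nchar(pref) + 1L)
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), action, rel,
                  params)
  cat(line, "\n", sep = "", file = file.path(pl$paths$logs, "project.log"),
      append = TRUE)
  invisible(line)
}

#' Read the project log
#' @param pl a `project_layout`.
#' @return data.frame with `timestamp`, `action`, `file`, `params`.
#' @export
project_log_table <- function(pl) {
  lf <- file.path(pl$paths$logs, "project.log")
  if (!file.exists(lf))
    return(data.frame(timestamp = character(), action = character(),
                      file = character(), params = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(readLines(lf), "\t", fixed = TRUE)
  data.frame(timestamp = vapply(parts, `[`, character(1), 1L),
             action = vapply(parts, `[`, character(1), 2L),
             file = vapply(parts, `[`, character(1), 3L),
             params = vapply(parts, function(x)
               if (length(x) >= 4L) x[4L] else "", character(1)),
             stringsAsFactors = FALSE)
}

#' Figure size after automatic rescaling
#'
#' Row-indexed plots (gene heat maps, profile plots, co-expression series)
#' grow in height by 0.15 inch per row beyond 20, clamped to four times the
#' base height. Sample- or contrast-indexed widths grow by 0.3 inch per item
#' beyond 12, clamped to four times the base width. Non-indexed plots
#' (volcano, densities, MDS) return the base size.
#'
#' @param pd a `plot_data`.
#' @param base numeric length-2, width and height in inches.
#' @return numeric length-2 `(width, height)`.
#' @export
figure_size <- function(pd, base = c(7, 7)) {
  w <- base[1L]; h <- base[2L]
  n_rows <- switch(pd$plot_type,
    gene_heatmap = nrow(pd$tables$selection),
    profile_plot = length(unique(pd$tables$trajectories$gene)),
    coexpression_series = nrow(pd$tables$assignments),
    NULL)
  n_items <- switch(pd$plot_type,
    sample_distance_heatmap = nrow(pd$tables$order),
    group_dendrogram = nrow(pd$tables$leaves),
    boxplot_prenorm = ,
    boxplot_postnorm = nrow(pd$tables$stats),
    foldchange_boxplot = nrow(pd$tables$stats),
    gene_heatmap = nrow(pd$tables$col_order),
    NULL)
  if (!is.null(n_rows))
    h <- min(h + 0.15 * max(0, n_rows - 20), 4 * h)
  if (!is.null(n_items))
    w <- min(w + 0.3 * max(0, n_items - 12), 4 * w)
  c(w, h)
}

#' Export a result object into the project scaffold
#'
#' Master results go to `results/master` (three aligned TSVs plus a
#' provenance sidecar), contrast results and significance sets to
#' `results/de_lists`. Name collisions get a versioned suffix; every written
#' file is logged.
#'
#' @param pl a `project_layout`.
#' @param obj a `master_result`, `contrast_result` or `significance_set`.
#' @param name file stem (sanitized to filesystem-safe characters).
#' @return character vector of written paths, invisibly.
#' @export
export_result <- function(pl, obj, name) {
  name <- sanitize_name(name)
  if (inherits(obj, "master_result")) {
    stem <- versioned_stem(file.path(pl$paths$master, name), ".lfc.tsv")
    paths <- write_master_result(obj, stem)
  } else if (inherits(obj, "contrast_result")) {
    p <- versioned_path(file.path(pl$paths$de_lists, paste0(name, ".tsv")))
    write_contrast_table(obj, p)
    paths <- p
  } else if (inherits(obj, "significance_set")) {
    p <- versioned_path(file.path(pl$paths$de_lists, paste0(name, ".txt")))
    writeLines(c(sprintf("# p_cut = %g, lfc_cut = %g",
                         attr(obj, "p_cut"), attr(obj, "lfc_cut")),
                 as.character(obj)), p)
    paths <- p
  } else stop("cannot export object of class ", class(obj)[1L])
  for (p in paths) project_log(pl, "export", p)
  invisible(paths)
}
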