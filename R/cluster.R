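## Distances, agglomerative clustering with a deterministic tie-break,
## classical MDS, group overlays (confidence ellipses / convex hulls) and
## cross-contrast profile clustering.

#' Pairwise distances between samples or genes
#'
#' `euclidean` is the root-sum-of-squared differences over the non-chosen
#' axis and accepts any real matrix. `poisson` is a size-factor-adjusted
#' Poisson deviance divergence on raw counts: with size factors
#' `s_i = N_i / geomean(N)` and scaled counts `x' = x/s`, for items i, j and
#' per-gene pooled mean `mu_g = (x'_gi + x'_gj)/2`, the divergence is
#' `sum_g x'_gi log(x'_gi/mu_g) + x'_gj log(x'_gj/mu_g)` (with
#' `0 log(0/.) = 0`) and the distance its square root — zero iff the scaled
#' profiles are equal, so pure sequencing-depth differences vanish.
#'
#' @param data matrix: a [count_matrix()] (required for `poisson`) or a
#'   [normalize_counts()] output.
#' @param metric `"euclidean"` or `"poisson"`.
#' @param axis `"samples"` (distances between columns) or `"genes"` (rows).
#' @return Symmetric matrix of class `dist_matrix` with zero diagonal and
#'   attribute `metric`.
#' @export
distance_matrix <- function(data, metric = c("euclidean", "poisson"),
                            axis = c("samples", "genes")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  m <- unclass(as.matrix(data))
  if (axis == "samples") m <- t(m)  # items in rows from here on
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    if (any(m < 0) || any(m != round(m)))
      stop("poisson distance requires raw non-negative integer counts")
    N <- rowSums(m)
    if (any(N <= 0)) stop("poisson distance: item with zero total count")
    s <- N / exp(mean(log(N)))
    x <- m / s
    n <- nrow(x)
    out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    xlx <- function(v, mu) ifelse(v > 0, v * log(v / mu), 0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      mu <- (x[i, ] + x[j, ]) / 2
      ok <- mu > 0
      div <- sum(xlx(x[i, ok], mu[ok]) + xlx(x[j, ok], mu[ok]))
      out[i, j] <- out[j, i] <- sqrt(max(0, div))
    }
    out
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d <- (d + t(d)) / 2  # exact symmetry
  structure(d, metric = metric, class = c("dist_matrix", class(d)))
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard agglomeration under complete, average (UPGMA, size-weighted) or
#' single linkage. When several pairs are at the minimal distance, the pair
#' whose (sorted) cluster IDs — each cluster named by its lexicographically
#' smallest member — is smallest merges first, so results are reproducible
#' regardless of input order.
#'
#' @param dm a [distance_matrix()] (or any symmetric matrix with dimnames).
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return list of class `agg_dendrogram` with hclust-compatible fields
#'   `merge`, `height`, `labels`, `order`, plus `linkage`; coercible with
#'   [as.hclust()].
#' @export
hcluster <- function(dm, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  d <- unclass(as.matrix(dm))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)               # current cluster slots
  id <- labels                       # lexicographic cluster IDs
  size <- rep(1L, n)
  node <- -seq_len(n)                # hclust coding: negative = leaf
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D <- d
  for (step in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best_d <- min(sub)
    cand <- which(sub <= best_d + 1e-12, arr.ind = TRUE)
    pick <- 1L
    if (nrow(cand) > 1L) {  # tie: smallest sorted ID pair wins
      keys <- apply(cand, 1, function(rc) {
        pr <- sort(c(id[active[rc[1L]]], id[active[rc[2L]]]))
        paste(pr, collapse = "\r")
      })
      pick <- which.min(rank(keys, ties.method = "first"))
    }
    i <- active[cand[pick, 1L]]; j <- active[cand[pick, 2L]]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- D[i, j]
    ## Lance-Williams update into slot i
    for (o in setdiff(active, c(i, j))) {
      D[i, o] <- D[o, i] <- switch(linkage,
        complete = max(D[i, o], D[j, o]),
        single   = min(D[i, o], D[j, o]),
        average  = (size[i] * D[i, o] + size[j] * D[j, o]) /
                   (size[i] + size[j]))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    id[i] <- min(id[i], id[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  ord <- integer(0)
  walk <- function(v) {
    if (v < 0) return(-v)
    c(walk(merge[v, 1L]), walk(merge[v, 2L]))
  }
  ord <- walk(n - 1L)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, linkage = linkage,
                 method = linkage, call = match.call(),
                 dist.method = attr(dm, "metric")),
            class = "agg_dendrogram")
}

#' @export
as.hclust.agg_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 call = x$call, dist.method = x$dist.method),
            class = "hclust")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences: a leaf's branch is the height of
#' the merge it joins, an internal node's branch is its parent's height minus
#' its own.
#'
#' @param dend an `agg_dendrogram`.
#' @param path optional file to write to.
#' @return Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  fmt <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%.10g", dend$labels[-node], parent_h))
    h <- dend$height[node]
    sprintf("(%s,%s):%.10g", fmt(dend$merge[node, 1L], h),
            fmt(dend$merge[node, 2L], h), parent_h - h)
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  nwk <- sprintf("(%s,%s);", fmt(dend$merge[root, 1L], h),
                 fmt(dend$merge[root, 2L], h))
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers `-0.5 * J D^2 J`, eigendecomposes, and scales the top-k
#' eigenvectors by the square roots of their (non-negative) eigenvalues;
#' negative eigenvalues are truncated to unused (zero coordinates).
#'
#' @param dm a [distance_matrix()].
#' @param k number of output dimensions (default 2), `1 <= k < n`.
#' @return list of class `mds_embedding`: `points` (n x k, centered, ordered
#'   by descending eigenvalue), `eig` (all eigenvalues), `var_explained`
#'   (per returned dimension, over the positive eigenvalues).
#' @export
classical_mds <- function(dm, k = 2L) {
  D <- unclass(as.matrix(dm))
  n <- nrow(D)
  if (k < 1L || k >= n) stop("need 1 <= k < number of items")
  if (all(D == 0)) {
    warning("all items coincide; embedding is all-zero")
    pts <- matrix(0, n, k, dimnames = list(rownames(D), paste0("dim", 1:k)))
    return(structure(list(points = pts, eig = rep(0, n),
                          var_explained = rep(0, k)),
                     class = "mds_embedding"))
  }
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values[seq_len(k)]
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pmax(ev, 0)), k)
  pts <- sweep(pts, 2, colMeans(pts))  # enforce exact centering
  dimnames(pts) <- list(rownames(D), paste0("dim", seq_len(k)))
  pos <- sum(pmax(e$values, 0))
  structure(list(points = pts, eig = e$values,
                 var_explained = pmax(ev, 0) / pos),
            class = "mds_embedding")
}

## counter-clockwise convex hull vertex indices
hull_ccw <- function(xy) {
  idx <- grDevices::chull(xy[, 1L], xy[, 2L])
  v <- xy[idx, , drop = FALSE]
  area2 <- sum(v[, 1L] * v[c(2:nrow(v), 1L), 2L] -
               v[c(2:nrow(v), 1L), 1L] * v[, 2L])
  if (area2 < 0) idx <- rev(idx)
  idx
}

#' Group overlays for an MDS embedding
#'
#' Per level of a metadata factor, either a normal-theory confidence ellipse
#' (2-D sample covariance scaled by the chi-square quantile at `level`, 2 df)
#' or the convex hull of the group's points (vertices in counter-clockwise
#' order). Groups with too few points (fewer than 3) are reported and
#' skipped.
#'
#' @param emb a [classical_mds()] embedding (first two dimensions used).
#' @param md matching [sample_metadata()].
#' @param factor_name grouping factor.
#' @param style `"ellipse"` or `"hull"`.
#' @param level ellipse confidence level (default 0.95).
#' @return list of class `group_overlay`: `style`, `level`, `groups` (per
#'   group: ellipse `center`, `axes`, `angle`, or hull `vertices` matrix) and
#'   `skipped` (group names with too few points).
#' @export
group_overlay <- function(emb, md, factor_name,
                          style = c("ellipse", "hull"), level = 0.95) {
  style <- match.arg(style)
  if (!factor_name %in% metadata_factors(md))
    stop("factor '", factor_name, "' not in metadata")
  pts <- emb$points[, 1:2, drop = FALSE]
  ids <- rownames(pts)
  g <- as.character(md[[factor_name]])[match(ids, md$sample_id)]
  groups <- list(); skipped <- character()
  for (lv in unique(g)) {
    xy <- pts[g == lv, , drop = FALSE]
    if (nrow(xy) < 3L) { skipped <- c(skipped, lv); next }
    if (style == "ellipse") {
      ctr <- colMeans(xy)
      S <- stats::cov(xy)
      e <- eigen(S, symmetric = TRUE)
      scale2 <- stats::qchisq(level, df = 2)
      axes <- sqrt(pmax(e$values, 0) * scale2)
      if (any(axes <= 0)) { skipped <- c(skipped, lv); next }
      groups[[lv]] <- list(center = ctr, axes = axes,
                           angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                           level = level, n = nrow(xy))
    } else {
      if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2L) {
        skipped <- c(skipped, lv); next  # collinear points: no polygon
      }
      groups[[lv]] <- list(vertices = xy[hull_ccw(xy), , drop = FALSE],
                           n = nrow(xy))
    }
  }
  structure(list(style = style, level = level, groups = groups,
                 skipped = skipped),
            class = "group_overlay")
}

## points of an ellipse outline (for rendering and containment checks)
ellipse_path <- function(ell, n = 100L) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ell$axes[1L] * cos(t), ell$axes[2L] * sin(t))
  R <- matrix(c(cos(ell$angle), sin(ell$angle),
                -sin(ell$angle), cos(ell$angle)), 2L, 2L)
  sweep(t(R %*% u), 2, ell$center, "+")
}

#' Cluster genes by the shape of their cross-contrast fold-change profile
#'
#' Each master gene's lfc row is z-scored (zero-variance rows become all-zero
#' profiles), genes with any missing lfc are excluded and reported, rows are
#' hierarchically clustered (euclidean, complete linkage) and the tree cut
#' into `k` groups.
#'
#' @param mr a `master_result` with >= 2 contrasts and >= k genes.
#' @param k number of clusters, `2 <= k <=` number of usable genes (`k` equal
#'   to the gene count yields singletons).
#' @return list of class `profile_clusters`: `labels` (named integer vector),
#'   `centers` (k x contrasts mean z-profiles), `excluded` (genes dropped for
#'   missing values), `dendrogram`.
#' @export
cluster_profiles <- function(mr, k) {
  if (length(mr$contrasts) < 2L) stop("need at least 2 contrasts")
  ok <- rowSums(is.na(mr$lfc)) == 0L
  excluded <- mr$genes[!ok]
  m <- mr$lfc[ok, , drop = FALSE]
  rownames(m) <- mr$genes[ok]
  if (k < 2L || k > nrow(m)) stop("need 2 <= k <= number of usable genes")
  mu <- rowMeans(m); s <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  dend <- hcluster(distance_matrix(t(z), "euclidean", axis = "samples"),
                   linkage = "complete")
  labels <- stats::cutree(as.hclust(dend), k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(z[labels == cl, , drop = FALSE])))
  dimnames(centers) <- list(paste0("cluster", seq_len(k)), mr$contrasts)
  structure(list(labels = labels, centers = centers, k = k,
                 excluded = excluded, dendrogram = dend),
            class = "profile_clusters")
}
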