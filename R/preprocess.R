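## Normalization and preprocessing: TMM scale factors, CPM-family
## transformations, replicate merging, gene ID transposition.

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scale factors robust to asymmetric differential expression.
#' Library sizes are column sums. The reference sample is the one whose
#' 75th-percentile CPM is closest to the mean 75th-percentile CPM (ties go to
#' the earlier column). For each sample k against the reference r, over genes
#' with positive counts in both, M-values `M_g = log2((y_gk/N_k)/(y_gr/N_r))`
#' and average abundances `A_g = 0.5*log2((y_gk/N_k)*(y_gr/N_r))` are formed;
#' `floor(n*trim_m)` genes are dropped from each extreme of M and
#' `floor(n*trim_a)` from each extreme of A (keeping the intersection, ranks
#' with ties broken by position), and the factor is `2^` the mean of the kept
#' M-values weighted by inverse asymptotic (delta-method binomial) variances
#' `w_g = (N_k-y_gk)/(N_k*y_gk) + (N_r-y_gr)/(N_r*y_gr)` inverted. Factors
#' are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()] (or integer matrix with dimnames).
#' @param trim_m fraction trimmed from each tail of the M-values (default 0.3).
#' @param trim_a fraction trimmed from each tail of the A-values (default 0.05).
#' @return Named numeric vector of class `norm_factors`, one positive factor
#'   per sample, with attribute `reference_sample`.
#' @examples
#' cm <- count_matrix(matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("a", "b"))))
#' tmm_factors(cm)  # pure depth difference: both factors 1
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  y <- unclass(as.matrix(cm))
  if (ncol(y) < 2L) stop("TMM needs at least 2 samples")
  N <- colSums(y)
  if (any(N <= 0))
    stop("all-zero sample: ", colnames(y)[which(N <= 0)[1L]])
  uq <- vapply(seq_len(ncol(y)),
               function(j) stats::quantile(1e6 * y[, j] / N[j], 0.75,
                                           names = FALSE),
               numeric(1))
  ref <- which.min(abs(uq - mean(uq)))  # which.min takes the earlier tie
  f <- vapply(seq_len(ncol(y)), function(k) {
    keep0 <- y[, k] > 0 & y[, ref] > 0
    yk <- y[keep0, k]; yr <- y[keep0, ref]
    if (!length(yk)) return(1)
    M <- log2((yk / N[k]) / (yr / N[ref]))
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1L; hiM <- n - floor(n * trim_m)
    loA <- floor(n * trim_a) + 1L; hiA <- n - floor(n * trim_a)
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, colnames(y)),
            reference_sample = colnames(y)[ref], class = "norm_factors")
}

#' Normalize a count matrix
#'
#' Three related transformations on the counts-per-million scale:
#' \describe{
#'   \item{cpm}{`1e6 * count / (library size * factor)`.}
#'   \item{log2cpm}{`log2(cpm + prior)`.}
#'   \item{reglog}{a shrunken (regularized) log,
#'     `log2(1e6 * (count + prior) / (library size * factor))`, which tames
#'     the variance of low counts for visualization; default prior 4.}
#' }
#'
#' @param cm a [count_matrix()].
#' @param nf [tmm_factors()] output aligned to the samples of `cm`; `NULL`
#'   for unit factors (pure library-size scaling).
#' @param method one of `"cpm"`, `"log2cpm"`, `"reglog"`.
#' @param prior pseudocount; default 1 for `log2cpm`, 4 for `reglog`.
#' @return Numeric matrix of class `normalized_matrix` with attributes
#'   `method`, `prior` and `factors`.
#' @export
normalize_counts <- function(cm, nf = NULL, method = c("log2cpm", "cpm", "reglog"),
                             prior = NULL) {
  method <- match.arg(method)
  y <- unclass(as.matrix(cm))
  N <- colSums(y)
  if (is.null(nf)) nf <- stats::setNames(rep(1, ncol(y)), colnames(y))
  if (!all(colnames(y) %in% names(nf)))
    stop("normalization factors do not cover all samples")
  f <- as.numeric(nf[colnames(y)])
  eff <- N * f
  if (is.null(prior)) prior <- switch(method, reglog = 4, 1)
  out <- switch(method,
    cpm     = sweep(y, 2, 1e6 / eff, "*"),
    log2cpm = log2(sweep(y, 2, 1e6 / eff, "*") + prior),
    reglog  = log2(sweep(y + prior, 2, 1e6 / eff, "*")))
  structure(out, method = method, prior = prior,
            factors = stats::setNames(f, colnames(y)),
            class = c("normalized_matrix", class(out)))
}

#' Merge replicate samples by a metadata factor
#'
#' Sums counts within each level of `key`. Merged metadata keeps factors that
#' are constant within every level and drops (reporting) those that vary.
#'
#' @param cm a [count_matrix()].
#' @param md matching [sample_metadata()].
#' @param key factor name defining the merge groups; the merged sample IDs
#'   are the key levels.
#' @return list with merged `counts` ([count_matrix()]), `metadata`
#'   ([sample_metadata()]) and `dropped_factors` (character).
#' @export
merge_replicates <- function(cm, md, key) {
  if (!key %in% metadata_factors(md))
    stop(sprintf("factor '%s' not in metadata (available: %s)",
                 key, paste(metadata_factors(md), collapse = ", ")))
  y <- unclass(as.matrix(cm))[, md$sample_id, drop = FALSE]
  g <- md[[key]]
  lev <- levels(g)
  merged <- vapply(lev, function(l) rowSums(y[, g == l, drop = FALSE]),
                   numeric(nrow(y)))
  merged <- matrix(as.integer(merged), nrow(y), length(lev),
                   dimnames = list(rownames(y), lev))
  keep <- character(); drop <- character()
  fac <- list()
  for (nm in setdiff(metadata_factors(md), key)) {
    vals <- vapply(lev, function(l) {
      u <- unique(as.character(md[[nm]][g == l]))
      if (length(u) == 1L) u else NA_character_
    }, character(1))
    if (anyNA(vals)) drop <- c(drop, nm)
    else { keep <- c(keep, nm); fac[[nm]] <- vals }
  }
  mmd <- data.frame(sample_id = lev, stringsAsFactors = FALSE)
  for (nm in keep) mmd[[nm]] <- fac[[nm]]
  list(counts = count_matrix(merged),
       metadata = sample_metadata(mmd),
       dropped_factors = drop)
}

#' Transpose gene IDs to display names
#'
#' @param ids character vector of gene IDs.
#' @param gm a [gene_map()]. Unmapped IDs are handled per the map's policy
#'   (kept, dropped, or an error). Two IDs mapping to the same display name
#'   are disambiguated by suffixing the original ID as `"name|id"`.
#' @return character vector of display names.
#' @export
transpose_ids <- function(ids, gm) {
  ids <- as.character(ids)
  hit <- ids %in% names(gm$mapping)
  if (gm$policy == "error" && any(!hit))
    stop("unmapped gene ID: ", ids[which(!hit)[1L]])
  out <- ids
  out[hit] <- unname(gm$mapping[ids[hit]])
  if (gm$policy == "drop") { out <- out[hit]; ids <- ids[hit] }
  dup_names <- unique(out[duplicated(out)])
  clash <- out %in% dup_names
  out[clash] <- paste0(out[clash], "|", ids[clash])
  out
}
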