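## Self-contained statistical primitives: Wilcoxon rank-sum testing (exact by
## enumeration for small tie-free samples, tie-corrected normal approximation
## otherwise), Benjamini-Hochberg adjustment, Gaussian kernel density.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the rank sum `W` of the first group in the pooled ranking.
#' When `n1 + n2 <= 12` and the pooled data are tie-free, the p-value is exact
#' by full enumeration of all `choose(n1+n2, n1)` rank assignments; the
#' two-sided exact p doubles the smaller tail probability and is capped at 1.
#' Otherwise a normal approximation with tie-corrected variance and a
#' continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return list of class `rank_sum_test`: `statistic` (rank sum of `x`),
#'   `p_value`, `method` (`"exact"` or `"normal-approx"`), `n1`, `n2`,
#'   `alternative`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1, exact
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (anyNA(c(x, y))) stop("missing values not allowed")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  if (n <= 12L && !ties) {
    ## exact: distribution of the rank sum over all C(n, n1) splits
    splits <- utils::combn(n, n1)
    sums <- colSums(matrix(seq_len(n)[splits], nrow = n1))
    lower <- mean(sums <= W); upper <- mean(sums >= W)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(lower, upper)),
                greater   = upper,
                less      = lower)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    v <- n1 * n2 * (n + 1) / 12 -
      n1 * n2 * sum(tie_tab^3 - tie_tab) / (12 * n * (n - 1))
    if (v <= 0) return(structure(
      list(statistic = W, p_value = 1, method = "normal-approx",
           n1 = n1, n2 = n2, alternative = alternative),
      class = "rank_sum_test"))
    s <- sqrt(v)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-max(0, abs(W - mu) - 0.5) / s),
      greater   = stats::pnorm((W - mu - 0.5) / s, lower.tail = FALSE),
      less      = stats::pnorm((W - mu + 0.5) / s))
    p <- min(1, p)
    method <- "normal-approx"
  }
  structure(list(statistic = W, p_value = p, method = method,
                 n1 = n1, n2 = n2, alternative = alternative),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2, x$alternative))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-missing entries (`m` = number of
#' non-missing p-values); missing entries stay missing. Adjusted values are
#' monotone (cumulative minimum from the largest rank) and capped at 1.
#'
#' @param pvals numeric vector in `[0, 1]`, possibly with `NA`.
#' @return numeric vector of the same length.
#' @export
bh_adjust <- function(pvals) {
  p <- as.numeric(pvals)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m) {
    pp <- p[ok]
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
  }
  out
}

silverman_bw <- function(x) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  lo <- min(s, iqr / 1.34)
  if (lo == 0) lo <- s  # degenerate IQR: fall back to sd
  if (lo == 0)
    stop("zero variance and zero IQR: supply an explicit bandwidth")
  0.9 * lo * length(x)^(-1 / 5)
}

#' One-dimensional Gaussian kernel density estimate
#'
#' Automatic bandwidth is Silverman's rule,
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`. The default grid spans the data plus
#' 3 bandwidths on each side at 512 points; a caller-supplied grid lets
#' several densities share one evaluation grid.
#'
#' @param values numeric vector, length >= 2.
#' @param bandwidth positive bandwidth, or `"auto"`.
#' @param grid optional numeric vector of evaluation points.
#' @return list of class `density_curve`: `grid`, `density`, `bandwidth`, `n`.
#' @export
kde_1d <- function(values, bandwidth = "auto", grid = NULL) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 values for a density")
  bw <- if (identical(bandwidth, "auto")) silverman_bw(x) else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
    bw
  }
  if (is.null(grid))
    grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = 512L)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = bw, n = length(x)),
            class = "density_curve")
}

## trapezoid integral of a density curve (used by invariants and tests)
trapezoid <- function(grid, values) {
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
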