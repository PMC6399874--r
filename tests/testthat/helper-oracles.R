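# Independent reference implementations used as oracles. These deliberately
# share no code with the package: sort-based trimming instead of ranks,
# explicit loops instead of vectorized forms.

# brute-force trimmed weighted mean of M-values
oracle_tmm <- function(y, trim_m = 0.30, trim_a = 0.05) {
  N <- colSums(y)
  uq <- sapply(seq_len(ncol(y)), function(j)
    unname(quantile(1e6 * y[, j] / N[j], 0.75)))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(y))
  for (k in seq_len(ncol(y))) {
    keep <- which(y[, k] > 0 & y[, ref] > 0)
    yk <- y[keep, k]; yr <- y[keep, ref]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    cut_m <- floor(n * trim_m); cut_a <- floor(n * trim_a)
    keep_m <- order(M)[(cut_m + 1):(n - cut_m)]
    keep_a <- order(A)[(cut_a + 1):(n - cut_a)]
    sel <- intersect(keep_m, keep_a)
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    f[k] <- 2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }
  f / exp(mean(log(f)))
}

# exact Wilcoxon two-sided p by enumerating every rank split
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[1:n1])
  splits <- combn(seq_len(n), n1)
  sums <- apply(splits, 2, sum)
  min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs)))
}

# cophenetic distances of an agg_dendrogram via its merge table
oracle_cophenetic <- function(dend) {
  n <- length(dend$labels)
  D <- matrix(0, n, n, dimnames = list(dend$labels, dend$labels))
  nodes <- list()
  for (s in seq_len(nrow(dend$merge))) {
    leaves_of <- function(v) if (v < 0) -v else nodes[[v]]
    a <- leaves_of(dend$merge[s, 1]); b <- leaves_of(dend$merge[s, 2])
    D[a, b] <- dend$height[s]
    D[b, a] <- dend$height[s]
    nodes[[s]] <- c(a, b)
  }
  D
}

# random count matrix with gene rownames / sample colnames
rand_counts <- function(ng, ns, lambda = 80) {
  m <- matrix(rpois(ng * ns, lambda) + 1L, ng, ns,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  count_matrix(m)
}

# max |embedded pairwise distance - input distance|
dist_residual <- function(emb, dm) {
  max(abs(as.matrix(dist(emb$points)) - unclass(as.matrix(dm))))
}

# is point p inside (or on) the polygon given by vertex matrix v?
point_in_polygon <- function(p, v, tol = 1e-9) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (cross < -tol) return(FALSE)  # CCW polygon: inside is left of edges
  }
  TRUE
}
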