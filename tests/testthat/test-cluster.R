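test_that("euclidean and poisson distances meet their definitions", {
  m <- matrix(c(0, 3, 4, 0, 0, 3), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  d <- distance_matrix(m, "euclidean", "samples")
  expect_equal(d["a", "b"], 5)          # 3-4-5 triangle
  expect_equal(d["a", "c"], 0)          # identical columns
  expect_identical(attr(d, "metric"), "euclidean")

  y <- unclass(as.matrix(rand_counts(30, 3)))
  y[, 2] <- 2L * y[, 1]                 # scaled copy of column 1
  dp <- distance_matrix(count_matrix(y), "poisson", "samples")
  expect_lt(dp["s01", "s02"], 1e-8)     # size factors absorb depth
  expect_gt(dp["s01", "s03"], 0)
  expect_error(distance_matrix(y / 3, "poisson"), "integer")
})

test_that("distance matrices satisfy their invariants exactly", {
  set.seed(17)
  for (metric in c("euclidean", "poisson")) {
    d <- distance_matrix(rand_counts(25, 5), metric, "samples")
    m <- unclass(as.matrix(d))
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
  dg <- distance_matrix(rand_counts(6, 4), "euclidean", "genes")
  expect_identical(dim(unclass(as.matrix(dg))), c(6L, 6L))
})

test_that("hcluster reproduces hand agglomeration and handles 2 items", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  h <- hcluster(d, "complete")
  expect_equal(h$height, c(1, 10))
  expect_identical(h$merge[1, ], c(-2L, -1L))  # x1,x2 merge first
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  h2 <- hcluster(d2)
  expect_equal(h2$height, 4)
})

test_that("hcluster agrees with stats::hclust on tie-free random instances", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(2 * n), n,
                  dimnames = list(sprintf("i%d", 1:n), NULL))
    dm <- distance_matrix(t(pts), "euclidean", "samples")
    for (lk in c("complete", "average", "single")) {
      ours <- oracle_cophenetic(hcluster(dm, lk))
      ref <- as.matrix(cophenetic(hclust(as.dist(unclass(dm)), method = lk)))
      expect_equal(ours[rownames(ref), colnames(ref)], ref,
                   tolerance = 1e-10)
    }
    ## linkage bounds: complete >= input, single <= input (off-diagonal)
    co <- oracle_cophenetic(hcluster(dm, "complete"))
    si <- oracle_cophenetic(hcluster(dm, "single"))
    off <- upper.tri(co)
    expect_true(all(co[off] >= unclass(dm)[off] - 1e-12))
    expect_true(all(si[off] <= unclass(dm)[off] + 1e-12))
  }
})

test_that("hcluster breaks exact ties toward the smallest ID pair", {
  ## four equidistant items: every pair ties at 1
  d <- matrix(1, 4, 4, dimnames = list(c("b", "d", "a", "c"),
                                       c("b", "d", "a", "c")))
  diag(d) <- 0
  h <- hcluster(d, "complete")
  first <- sort(h$labels[-h$merge[1, ]])
  expect_identical(first, c("a", "b"))  # lexicographically smallest pair
})

test_that("dendrogram exports to Newick readable by ape with matching heights", {
  set.seed(31)
  cm <- rand_counts(15, 5)
  dend <- hcluster(distance_matrix(cm, "euclidean", "samples"), "complete")
  nwk <- dendrogram_newick(dend)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, dend$labels)
  ## ultrametric tree: patristic distance = 2 * cophenetic merge height
  pat <- ape::cophenetic.phylo(tr)
  co <- oracle_cophenetic(dend)
  expect_equal(pat[rownames(co), colnames(co)], 2 * co, tolerance = 1e-6)
})

test_that("classical_mds recovers planar configurations", {
  fx <- fixture_suite()
  dm <- distance_matrix(t(fx$planar_points), "euclidean", "samples")
  emb <- classical_mds(dm, k = 2)
  expect_lt(dist_residual(emb, dm), 1e-8)
  expect_equal(colMeans(emb$points), c(dim1 = 0, dim2 = 0),
               tolerance = 1e-9)
  expect_true(all(diff(emb$eig[1:2]) <= 1e-9))  # descending eigenvalues

  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(2 * n, sd = 3), n,
                  dimnames = list(sprintf("p%d", 1:n), NULL))
    dm <- distance_matrix(t(pts), "euclidean", "samples")
    expect_lt(dist_residual(classical_mds(dm, 2), dm), 1e-8)
  }
})

test_that("classical_mds matches cmdscale up to axis sign", {
  set.seed(43)
  pts <- matrix(rnorm(14), 7)
  dm <- distance_matrix(t(pts), "euclidean", "samples")
  emb <- classical_mds(dm, 2)
  ref <- cmdscale(as.dist(unclass(dm)), k = 2)
  for (j in 1:2)
    expect_equal(abs(emb$points[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("classical_mds edge cases: 2 items, degenerate zero matrix", {
  d2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  emb <- classical_mds(d2, 1)
  expect_equal(sort(emb$points[, 1]), c(-3, 3), ignore_attr = TRUE)
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(e0 <- classical_mds(z, 2), "coincide")
  expect_true(all(e0$points == 0))
  expect_error(classical_mds(d2, 2), "k <")
})

test_that("group overlays: hulls contain their points, CCW square corners", {
  fx <- fixture_suite()
  sq <- fx$square_points
  emb <- structure(list(points = cbind(dim1 = sq[, 1] - 0.5,
                                       dim2 = sq[, 2] - 0.5)),
                   class = "mds_embedding")
  md <- sample_metadata(data.frame(sample_id = rownames(sq), grp = "g"))
  ov <- group_overlay(emb, md, "grp", style = "hull")
  v <- ov$groups$g$vertices
  expect_equal(nrow(v), 4)
  ## counter-clockwise: positive signed area
  area2 <- sum(v[, 1] * v[c(2:4, 1), 2] - v[c(2:4, 1), 1] * v[, 2])
  expect_gt(area2, 0)
  for (i in seq_len(nrow(emb$points)))
    expect_true(point_in_polygon(emb$points[i, ], v))
})

test_that("confidence ellipses scale covariance by the chi-square quantile", {
  set.seed(47)
  xy <- cbind(rnorm(40, sd = 2), rnorm(40, sd = 0.5))
  emb <- structure(list(points = cbind(dim1 = xy[, 1], dim2 = xy[, 2])),
                   class = "mds_embedding")
  rownames(emb$points) <- sprintf("s%02d", 1:40)
  md <- sample_metadata(data.frame(sample_id = rownames(emb$points),
                                   grp = "g"))
  ov <- group_overlay(emb, md, "grp", style = "ellipse", level = 0.95)
  ell <- ov$groups$g
  ev <- eigen(cov(xy), symmetric = TRUE)$values
  expect_equal(unname(ell$axes), sqrt(ev * qchisq(0.95, 2)),
               tolerance = 1e-10)
  expect_equal(qchisq(0.95, 2), 5.991, tolerance = 1e-3)
  expect_true(all(ell$axes > 0))

  ## isotropic cloud: near-equal axes
  set.seed(48)
  iso <- cbind(rnorm(500), rnorm(500))
  emb2 <- structure(list(points = cbind(dim1 = iso[, 1], dim2 = iso[, 2])),
                    class = "mds_embedding")
  rownames(emb2$points) <- sprintf("t%03d", 1:500)
  md2 <- sample_metadata(data.frame(sample_id = rownames(emb2$points),
                                    grp = "g"))
  ax <- group_overlay(emb2, md2, "grp", "ellipse")$groups$g$axes
  expect_lt(abs(ax[1] / ax[2] - 1), 0.15)
})

test_that("groups with too few or collinear points are reported, not fatal", {
  pts <- cbind(dim1 = c(0, 1, 2, 0, 1), dim2 = c(0, 1, 2, 5, 5))
  rownames(pts) <- sprintf("s%d", 1:5)
  emb <- structure(list(points = pts), class = "mds_embedding")
  md <- sample_metadata(data.frame(sample_id = rownames(pts),
                                   grp = c("lin", "lin", "lin", "sm", "sm")))
  ov <- group_overlay(emb, md, "grp", style = "hull")
  expect_setequal(ov$skipped, c("lin", "sm"))  # collinear + too few
  expect_length(ov$groups, 0)
})

test_that("cluster_profiles separates shape families and handles k = n", {
  up <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE) *
    c(1, 2, 0.5, 3)
  down <- matrix(rep(c(3, 2, 1), 3), 3, 3, byrow = TRUE) * c(1, 4, 2)
  lfc <- rbind(up, down)
  dimnames(lfc) <- list(sprintf("g%d", 1:7), c("c1", "c2", "c3"))
  mr <- aggDE:::new_master_result(rownames(lfc), colnames(lfc), lfc,
                                  lfc * 0 + 0.01, lfc > 0, "union", 0.05, 0)
  pc <- cluster_profiles(mr, k = 2)
  expect_length(unique(pc$labels[1:4]), 1)
  expect_length(unique(pc$labels[5:7]), 1)
  expect_false(pc$labels[1] == pc$labels[5])
  expect_identical(dim(pc$centers), c(2L, 3L))

  singles <- cluster_profiles(mr, k = 7)
  expect_length(unique(singles$labels), 7)
  expect_error(cluster_profiles(mr, k = 1), "k")
  expect_error(cluster_profiles(mr, k = 8), "k")
})

test_that("profile cluster memberships are invariant to gene row order", {
  set.seed(53)
  lfc <- matrix(rnorm(30), 10, 3,
                dimnames = list(sprintf("g%02d", 1:10), c("a", "b", "c")))
  mr <- aggDE:::new_master_result(rownames(lfc), colnames(lfc), lfc,
                                  lfc * 0 + 0.01, lfc > 0, "union", 0.05, 0)
  perm <- sample(10)
  mr2 <- aggDE:::new_master_result(rownames(lfc)[perm], colnames(lfc),
                                   lfc[perm, ], (lfc * 0 + 0.01)[perm, ],
                                   (lfc > 0)[perm, ], "union", 0.05, 0)
  a <- cluster_profiles(mr, 3)$labels
  b <- cluster_profiles(mr2, 3)$labels[names(a)]
  ## same partition up to label permutation
  canon <- function(lab) sort(vapply(split(names(lab), lab), function(g)
    paste(sort(g), collapse = ","), character(1)))
  expect_identical(unname(canon(a)), unname(canon(b)))
})

test_that("genes with missing fold changes are excluded and reported", {
  lfc <- matrix(c(1, NA, 2, 1, 3, 2), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  mr <- aggDE:::new_master_result(rownames(lfc), colnames(lfc), lfc,
                                  lfc * 0 + 0.01, !is.na(lfc), "union",
                                  0.05, 0)
  pc <- cluster_profiles(mr, 2)
  expect_identical(pc$excluded, "g2")
  expect_setequal(names(pc$labels), c("g1", "g3"))
})
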