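make_pattern_master <- function(mode, p_cut = 0.05, lfc_cut = 1) {
  fx <- fixture_suite()
  aggregate_contrasts(aggDE:::pattern_contrasts(fx$sig_pattern), mode,
                      p_cut = p_cut, lfc_cut = lfc_cut)
}

test_that("union and intersection merging follow set algebra", {
  crs <- aggDE:::pattern_contrasts(list(c1 = c("A", "B"), c2 = c("B", "C")))
  u <- aggregate_contrasts(crs, "union", 0.05, 1)
  i <- aggregate_contrasts(crs, "intersection", 0.05, 1)
  expect_setequal(u$genes, c("A", "B", "C"))
  expect_identical(i$genes, "B")

  ## single contrast: either mode reduces to that contrast's significant set
  one <- aggregate_contrasts(crs[1], "union", 0.05, 1)
  expect_setequal(one$genes, c("A", "B"))
  one_i <- aggregate_contrasts(crs[1], "intersection", 0.05, 1)
  expect_setequal(one_i$genes, c("A", "B"))

  m3 <- make_pattern_master("union")
  expect_setequal(m3$genes, c("A", "B", "C", "D"))  # {A,B} u {B,C} u {B,D}
  expect_false("zz" %in% m3$genes)  # filler gene never passes the cuts
  i3 <- make_pattern_master("intersection")
  expect_identical(i3$genes, "B")
})

test_that("overlap counts match hand enumeration on the 3-contrast pattern", {
  m3 <- make_pattern_master("union")
  oc <- overlap_counts(m3)
  expect_equal(oc[c("A", "B", "C", "D")],
               c(A = 1L, B = 3L, C = 1L, D = 1L))
})

test_that("values are re-extracted for non-significant cells, sig kept apart", {
  m3 <- make_pattern_master("union")
  expect_false(anyNA(m3$lfc))          # every contrast covers every gene
  expect_false(all(m3$sig))            # but not every cell is significant
  expect_equal(m3$lfc["A", "c2"], 0.1) # A is background in c2, value kept
  expect_false(m3$sig["A", "c2"])
  expect_true(m3$sig["A", "c1"])
})

test_that("genes absent from a contrast table: kept as NA in union, dropped in intersection", {
  cr1 <- contrast_result(data.frame(gene = c("A", "B"), mean_expr = 1,
                                    log2fc = 3, pvalue = 1e-4, padj = 1e-3),
                         "c1")
  cr2 <- contrast_result(data.frame(gene = "B", mean_expr = 1, log2fc = 3,
                                    pvalue = 1e-4, padj = 1e-3), "c2")
  u <- aggregate_contrasts(list(cr1, cr2), "union", 0.05, 1)
  expect_setequal(u$genes, c("A", "B"))
  expect_true(is.na(u$lfc["A", "c2"]))
  i <- aggregate_contrasts(list(cr1, cr2), "intersection", 0.05, 1)
  expect_identical(i$genes, "B")
})

test_that("aggregation against a randomized set-algebra oracle", {
  set.seed(14)
  universe <- sprintf("G%02d", 1:30)
  for (trial in 1:10) {
    k <- sample(2:5, 1)
    pattern <- lapply(seq_len(k), function(i)
      sample(universe, sample(3:12, 1)))
    names(pattern) <- sprintf("c%d", seq_len(k))
    crs <- aggDE:::pattern_contrasts(pattern, universe = universe)
    u <- aggregate_contrasts(crs, "union", 0.05, 1)
    i <- suppressWarnings(
      aggregate_contrasts(crs, "intersection", 0.05, 1))
    expect_setequal(u$genes, Reduce(union, pattern))
    expect_setequal(i$genes, Reduce(intersect, pattern))
    expect_true(all(i$genes %in% u$genes))
    ## permutation invariance up to column order
    perm <- sample(k)
    u2 <- aggregate_contrasts(crs[perm], "union", 0.05, 1)
    expect_identical(u2$genes, u$genes)
    expect_equal(u2$lfc[, u$contrasts], u$lfc)
  }
})

test_that("empty intersection yields a valid empty master with a warning", {
  crs <- aggDE:::pattern_contrasts(list(c1 = "A", c2 = "B"))
  expect_warning(m <- aggregate_contrasts(crs, "intersection", 0.05, 1),
                 "empty")
  expect_length(m$genes, 0)
  expect_identical(dim(m$lfc), c(0L, 2L))
})

test_that("filter_master enumerates row-wise and is idempotent", {
  lfc <- matrix(c(3, 0.5, -2.5, 1, 0,
                  0.2, 4, -3, 0.5, 0), 5, 2,
                dimnames = list(sprintf("g%d", 1:5), c("c1", "c2")))
  padj <- matrix(c(0.005, 0.5, 0.009, 0.2, 0.001,
                   0.3, 0.002, 0.05, 0.009, 0.5), 5, 2,
                 dimnames = dimnames(lfc))
  mr <- aggDE:::new_master_result(rownames(lfc), colnames(lfc), lfc, padj,
                                  padj < 0.05, "union", 0.05, 0)
  f <- filter_master(mr, p_cut = 0.01, lfc_cut = 2, scope = "any")
  ## row-wise check: g1 (3, .005), g2 (4, .002), g3 (-2.5,.009)
  expect_setequal(f$genes, c("g1", "g2", "g3"))
  expect_identical(filter_master(f, 0.01, 2, "any")$genes, f$genes)
  fa <- filter_master(mr, p_cut = 0.01, lfc_cut = 2, scope = "all")
  expect_length(fa$genes, 0)
  expect_length(filter_master(mr, lfc_cut = Inf)$genes, 0)
  expect_length(f$filters, 1L)
})

test_that("filtering at the aggregation cuts in matching scope is identity", {
  u <- make_pattern_master("union")
  expect_identical(filter_master(u, u$p_cut, u$lfc_cut, "any")$genes, u$genes)
  i <- make_pattern_master("intersection")
  expect_identical(filter_master(i, i$p_cut, i$lfc_cut, "all")$genes, i$genes)
})

test_that("sort_genes applies the stat with lexicographic tie-breaks", {
  lfc <- matrix(c(1, 2, 2, 3, 2, 2), 3, 2, byrow = TRUE,
                dimnames = list(c("gB", "gA", "gC"), c("c1", "c2")))
  mr <- aggDE:::new_master_result(rownames(lfc), colnames(lfc), lfc,
                                  lfc * 0 + 0.01, lfc > 0, "union", 0.05, 0)
  expect_identical(sort_genes(mr, "max"), c("gA", "gB", "gC"))
  expect_identical(sort_genes(mr, "max", descending = FALSE),
                   c("gB", "gC", "gA"))
  ## variance 0 rows sort last under descending; sd = sqrt(variance)
  expect_identical(sort_genes(mr, "variance")[3], "gC")
  expect_identical(sort_genes(mr, "sd"), sort_genes(mr, "variance"))
  ## ties on the stat resolved by gene ID: gA and gC share mean 2.5? no —
  ## construct an exact tie
  lfc2 <- matrix(c(1, 3, 3, 1, 0, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("gZ", "gA", "gM"), c("c1", "c2")))
  mr2 <- aggDE:::new_master_result(rownames(lfc2), colnames(lfc2), lfc2,
                                   lfc2 * 0 + 0.01, lfc2 > 0, "union",
                                   0.05, 0)
  expect_identical(sort_genes(mr2, "mean"), c("gA", "gZ", "gM"))
  expect_error(sort_genes(mr2, "range"))
})

test_that("subset_samples takes predicate conjunctions over metadata", {
  fx <- fixture_suite()
  s <- subset_samples(fx$counts, fx$metadata, time = "6h")
  expect_identical(colnames(s$counts), c("s1", "s2"))
  expect_identical(rownames(s$counts), rownames(fx$counts))
  s2 <- subset_samples(fx$counts, fx$metadata, time = c("6h", "1d"),
                       treatment = "ebov")
  expect_identical(colnames(s2$counts), c("s2", "s4"))
  ## conjunction = intersection of single-clause subsets
  a <- colnames(subset_samples(fx$counts, fx$metadata,
                               time = c("6h", "1d"))$counts)
  b <- colnames(subset_samples(fx$counts, fx$metadata,
                               treatment = "ebov")$counts)
  expect_identical(colnames(s2$counts), intersect(a, b))
  ## empty predicate is the identity
  id <- subset_samples(fx$counts, fx$metadata)
  expect_identical(unclass(as.matrix(id$counts)),
                   unclass(as.matrix(fx$counts)))
  expect_error(subset_samples(fx$counts, fx$metadata, time = "99h"),
               "no samples")
  expect_error(subset_samples(fx$counts, fx$metadata, batch = "x"), "batch")
})

test_that("derive_metadata_field builds composite factors", {
  fx <- fixture_suite()
  md <- derive_metadata_field(fx$metadata, c("treatment", "time"))
  expect_true("treatment_time" %in% metadata_factors(md))
  expect_identical(as.character(md$treatment_time)[2], "ebov_6h")
  expect_equal(nlevels(md$treatment_time),
               nrow(unique(as.data.frame(fx$metadata)[c("treatment",
                                                        "time")])))
  one <- derive_metadata_field(fx$metadata, "time", name = "t2")
  expect_identical(as.character(one$t2), as.character(fx$metadata$time))
  expect_error(derive_metadata_field(md, "time", name = "treatment_time"),
               "exists")
})

test_that("agreement densities share a grid, normalize, and duplicate for identical contrasts", {
  crs <- aggDE:::pattern_contrasts(list(c1 = c("A", "B"), c2 = c("B", "C")))
  set.seed(6)
  df <- data.frame(gene = sprintf("G%02d", 1:30), mean_expr = 50,
                   log2fc = rnorm(30, sd = 2), pvalue = runif(30)^2,
                   stringsAsFactors = FALSE)
  df$padj <- bh_adjust(df$pvalue)
  big <- list(contrast_result(df, "k1"), contrast_result(df, "k2"))
  mr <- aggregate_contrasts(big, "union", 0.6, 0)
  ad <- agreement_density(mr, on = "lfc")
  expect_equal(ad$curves$k1, ad$curves$k2)  # identical contrasts
  for (cv in ad$curves)
    expect_equal(aggDE:::trapezoid(ad$grid, cv), 1, tolerance = 1e-3)
  adp <- agreement_density(mr, on = "padj")
  expect_true(all(adp$overlap >= 1 & adp$overlap <= 2))

  tiny <- aggregate_contrasts(aggDE:::pattern_contrasts(list(c1 = "A",
                                                             c2 = "A")),
                              "union", 0.05, 1)
  expect_error(agreement_density(tiny), "2 master genes")
})

test_that("master result export writes aligned TSVs plus provenance", {
  m3 <- filter_master(make_pattern_master("union"), p_cut = 0.05,
                      lfc_cut = 1, scope = "any")
  stem <- file.path(withr::local_tempdir(), "master")
  paths <- write_master_result(m3, stem)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  lfc_back <- read.table(paste0(stem, ".lfc.tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE)
  expect_identical(lfc_back$gene, m3$genes)
  expect_equal(as.matrix(lfc_back[-1]), m3$lfc, ignore_attr = TRUE)
  prov <- readLines(paste0(stem, ".provenance.txt"))
  expect_true(any(grepl("mode = union", prov)))
  expect_true(any(grepl("filter_1", prov)))
})
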