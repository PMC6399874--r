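## Deterministic synthetic-data generator: negative-binomial counts over a
## multi-time-point, multi-treatment factorial design with planted
## differentially expressed genes, plus the small literal fixtures used
## across the documentation and tests.

#' Describe a synthetic count experiment
#'
#' The default design miniaturizes a time-course infection study: 3 time
#' points (`6h`, `1d`, `2d`) crossed with 4 treatments (`ebov`, `restv`,
#' `lps`, `mock`), 3 replicates per cell. Baseline gene means are log-normal;
#' counts are negative binomial with `var = mu + dispersion * mu^2`; library
#' sizes vary by a log-uniform factor so scale normalization is exercised.
#' Differential expression is planted per contrast as multiplicative
#' `2^log2fc` effects on all samples of a treatment level.
#'
#' @param n_genes number of genes.
#' @param times,treatments factor levels of the design grid.
#' @param replicates samples per design cell (>= 2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene means.
#' @param dispersion negative-binomial dispersion (constant across genes).
#' @param lib_factor_range range of the log-uniform library-size factors.
#' @param effects planted DE: list of `list(treatment =, genes =, lfc =)`
#'   entries; `lfc` recycles over `genes`. Default plants 200 genes at
#'   |log2fc| 2 for `ebov` and 200 for `restv`, overlapping in 100 genes.
#' @param seed integer seed recorded in the design.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000L,
                       times = c("6h", "1d", "2d"),
                       treatments = c("ebov", "restv", "lps", "mock"),
                       replicates = 3L,
                       baseline_meanlog = log(100), baseline_sdlog = 1.2,
                       dispersion = 0.05,
                       lib_factor_range = c(0.7, 1.4),
                       effects = NULL,
                       seed = 1L) {
  if (replicates < 2L) stop("replicates must be >= 2")
  if (is.null(effects) && n_genes >= 300L) {
    effects <- list(
      list(treatment = "ebov",  genes = 1:200,   lfc = rep(c(2, -2), 100)),
      list(treatment = "restv", genes = 101:300, lfc = rep(c(2, -2), 100)))
  }
  for (e in effects) {
    if (any(e$genes < 1L | e$genes > n_genes))
      stop("planted gene index out of range")
    if (!e$treatment %in% c(treatments, times))
      stop("planted level '", e$treatment, "' not in the design")
  }
  structure(list(n_genes = as.integer(n_genes), times = times,
                 treatments = treatments, replicates = as.integer(replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 lib_factor_range = lib_factor_range,
                 effects = effects, seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate counts from a design
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `baseline * 2^(planted effect) * library factor` and the design's
#' dispersion. The same seed always reproduces the identical matrix.
#'
#' @param design a [sim_design()].
#' @return list: `counts` ([count_matrix()]), `metadata`
#'   ([sample_metadata()] with `time` and `treatment` factors), `truth`
#'   (data.frame of planted effects: `contrast`, `gene`, `lfc`).
#' @export
simulate_counts <- function(design) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(design$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  ng <- design$n_genes
  grid <- expand.grid(rep = seq_len(design$replicates),
                      time = design$times, treatment = design$treatments,
                      stringsAsFactors = FALSE)
  ns <- nrow(grid)
  sample_ids <- sprintf("%s_%s_r%d", grid$treatment, grid$time, grid$rep)
  genes <- sprintf("g%04d", seq_len(ng))
  base <- stats::rlnorm(ng, design$baseline_meanlog, design$baseline_sdlog)
  libf <- exp(stats::runif(ns, log(design$lib_factor_range[1L]),
                           log(design$lib_factor_range[2L])))
  lfc_mat <- matrix(0, ng, ns)
  truth <- NULL
  for (e in design$effects) {
    hit <- grid$treatment == e$treatment | grid$time == e$treatment
    lfc <- rep_len(e$lfc, length(e$genes))
    lfc_mat[e$genes, hit] <- lfc_mat[e$genes, hit] + lfc
    truth <- rbind(truth, data.frame(contrast = e$treatment,
                                     gene = genes[e$genes], lfc = lfc,
                                     stringsAsFactors = FALSE))
  }
  mu <- (base * 2^lfc_mat) * rep(libf, each = ng)
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                  size = 1 / design$dispersion),
                   ng, ns, dimnames = list(genes, sample_ids))
  md <- sample_metadata(data.frame(sample_id = sample_ids,
                                   time = grid$time,
                                   treatment = grid$treatment,
                                   stringsAsFactors = FALSE))
  list(counts = count_matrix(counts), metadata = md, truth = truth)
}

#' Small literal fixtures used across examples and tests
#'
#' Pure construction: no files, no randomness. The bundle holds the toy
#' objects the documentation refers to — a 5-gene contrast table, three
#' overlapping significance patterns, planar point sets with known geometry,
#' and a miniature count matrix with metadata.
#'
#' @return named list of fixtures.
#' @export
fixture_suite <- function() {
  toy_contrast <- contrast_result(
    data.frame(gene = paste0("g", 1:5),
               mean_expr = c(100, 50, 80, 10, 60),
               log2fc = c(2, 3, 0.5, 9, -1.2),
               pvalue = c(0.001, 0.05, 0.01, 0.2, 0.02),
               padj = c(0.01, 0.2, 0.04, NA, 0.049)),
    contrast_label = c("treatment", "a", "b"))
  sig_pattern <- list(c1 = c("A", "B"), c2 = c("B", "C"), c3 = c("B", "D"))
  planar <- matrix(c(0, 0, 4, 0, 4, 3, 0, 3), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("p", 1:4), c("x", "y")))
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("q", 1:4), c("x", "y")))
  counts <- matrix(c(10L, 20L, 12L, 18L, 40L, 36L,
                     100L, 90L, 110L, 95L, 20L, 25L,
                     5L, 8L, 4L, 9L, 6L, 7L,
                     60L, 55L, 70L, 65L, 80L, 75L,
                     15L, 12L, 90L, 85L, 14L, 16L,
                     30L, 28L, 33L, 29L, 31L, 35L),
                   6L, 6L, byrow = TRUE,
                   dimnames = list(paste0("g", 1:6),
                                   paste0("s", 1:6)))
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:6),
    time = rep(c("6h", "1d", "2d"), each = 2),
    treatment = rep(c("mock", "ebov"), 3),
    stringsAsFactors = FALSE))
  list(toy_contrast = toy_contrast,
       sig_pattern = sig_pattern,
       planar_points = planar,
       square_points = square,
       counts = count_matrix(counts),
       metadata = md)
}

## contrast_result from a bare significance pattern: members significant at
## tiny padj / large lfc, one filler gene that never passes (internal helper
## for set-algebra examples)
pattern_contrasts <- function(pattern, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(c(unlist(pattern), "zz")))
  lapply(names(pattern), function(nm) {
    sig <- universe %in% pattern[[nm]]
    contrast_result(
      data.frame(gene = universe,
                 mean_expr = 100,
                 log2fc = ifelse(sig, 3, 0.1),
                 pvalue = ifelse(sig, 1e-4, 0.9),
                 padj = ifelse(sig, 1e-3, 0.95),
                 stringsAsFactors = FALSE),
      contrast_label = nm)
  })
}
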