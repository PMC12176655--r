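#' Configuration for synthetic UMI count matrices
#'
#' Negative-binomial counts per gene with lognormally distributed gene
#' means, a common dispersion, and a planted subset of highly variable
#' genes whose dispersion is multiplied by `hvg_dispersion_factor`. A gene
#' set of the requested size is emitted with a configured overlap with the
#' planted genes, for enrichment testing.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param baseline_mean expected UMI count per gene (lognormal across
#'   genes, CV 1).
#' @param dispersion negative-binomial dispersion (1/size); variance is
#'   mu + dispersion * mu^2.
#' @param n_hvg number of planted overdispersed genes.
#' @param hvg_dispersion_factor dispersion multiplier for planted genes
#'   (1 = no planting).
#' @param geneset_size number of genes in the emitted gene set.
#' @param geneset_hvg_overlap fraction of the gene set drawn from the
#'   planted genes (0..1).
#' @param seed integer seed.
#' @returns object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 2000, n_cells = 500,
                             baseline_mean = 20, dispersion = 0.5,
                             n_hvg = 100, hvg_dispersion_factor = 8,
                             geneset_size = 100, geneset_hvg_overlap = 0.3,
                             seed = 1L) {
  check_positive(n_genes, "n_genes")
  check_positive(n_cells, "n_cells")
  check_positive(baseline_mean, "baseline_mean")
  check_nonneg(dispersion, "dispersion")
  check_nonneg(n_hvg, "n_hvg")
  if (n_hvg > n_genes) abort_config("n_hvg must be <= n_genes")
  check_positive(hvg_dispersion_factor, "hvg_dispersion_factor")
  check_nonneg(geneset_size, "geneset_size")
  if (geneset_hvg_overlap < 0 || geneset_hvg_overlap > 1)
    abort_config("geneset_hvg_overlap must be in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 n_hvg = as.integer(n_hvg),
                 hvg_dispersion_factor = hvg_dispersion_factor,
                 geneset_size = as.integer(geneset_size),
                 geneset_hvg_overlap = geneset_hvg_overlap,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a UMI count matrix with planted highly variable genes
#'
#' @param config a [count_sim_config()].
#' @returns list: `counts` (genes x cells integer matrix with dimnames),
#'   `truth` (data frame: gene, mean, dispersion, planted_hvg, in_geneset),
#'   `gene_set` (character vector of member gene names).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  cells <- sprintf("cell%04d", seq_len(cfg$n_cells))
  mu <- rlnorm_mean_cv(cfg$n_genes, cfg$baseline_mean, 1)
  planted <- sort(sample.int(cfg$n_genes, cfg$n_hvg))
  disp <- rep(cfg$dispersion, cfg$n_genes)
  disp[planted] <- disp[planted] * cfg$hvg_dispersion_factor
  counts <- matrix(0L, cfg$n_genes, cfg$n_cells, dimnames = list(genes, cells))
  for (g in seq_len(cfg$n_genes)) {
    counts[g, ] <- as.integer(if (disp[g] <= 1e-12)
      stats::rpois(cfg$n_cells, mu[g])
    else
      stats::rnbinom(cfg$n_cells, size = 1 / disp[g], mu = mu[g]))
  }
  n_from_hvg <- min(round(cfg$geneset_size * cfg$geneset_hvg_overlap),
                    cfg$n_hvg, cfg$geneset_size)
  from_hvg <- if (n_from_hvg > 0) sample(planted, n_from_hvg) else integer(0)
  pool <- setdiff(seq_len(cfg$n_genes), c(planted, from_hvg))
  n_rest <- cfg$geneset_size - n_from_hvg
  rest <- if (n_rest > 0) sample(pool, min(n_rest, length(pool))) else integer(0)
  gs_idx <- sort(c(from_hvg, rest))
  truth <- data.frame(gene = genes, mean = mu, dispersion = disp,
                      planted_hvg = seq_len(cfg$n_genes) %in% planted,
                      in_geneset = seq_len(cfg$n_genes) %in% gs_idx)
  list(counts = counts, truth = truth, gene_set = genes[gs_idx])
}
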