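#' Configuration for the synthetic-data generators
#'
#' A single configuration object drives every generator so that one call to
#' [simulate_dataset()] yields a coherent world: a SNP universe with
#' block-constant LD, an eQTL catalog mapping SNPs to genes, per-study GWAS
#' summary statistics split into two replication stages, overlapping gene
#' sets with planted causal sets, and directed acyclic gene networks with
#' planted hub drivers.
#'
#' The causal signal is a one-parameter left-skewed law: GWAS p-values of
#' eSNPs that map to a planted causal gene set are drawn from
#' Beta(`signal_strength`, 1), which is exactly Uniform(0,1) at
#' `signal_strength = 1` (pure null) and increasingly enriched for small
#' p-values as `signal_strength` decreases.
#'
#' @param n_snps Number of SNPs in the universe.
#' @param n_genes Number of genes in the universe.
#' @param n_studies_stage1,n_studies_stage2 Number of GWAS cohorts in each
#'   replication stage (defaults 7 and 9, the structure of a 16-cohort
#'   two-stage meta-analysis).
#' @param n_gene_sets Number of gene sets to generate.
#' @param set_size_range Length-2 integer vector, inclusive bounds on gene
#'   set sizes.
#' @param planted_set_ids Identifiers of the causal ("planted") gene sets;
#'   must be among the generated ids `set001 ... setNNN`.
#' @param planted_set_size Number of genes in each planted set.
#' @param signal_strength Shape parameter a in (0, 1] of the Beta(a, 1)
#'   p-value law for causal eSNPs.
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param within_block_r2 Pairwise r-squared inside an LD block (constant);
#'   pairs in different blocks have no LD.
#' @param tissues Character vector of tissue labels for the eQTL catalog.
#' @param network_n_nodes Number of genes per simulated network.
#' @param n_networks Number of independent networks to simulate.
#' @param planted_driver_ids Gene ids planted as network hub drivers.
#' @param hub_degree Minimum out-degree of a planted driver.
#' @param driver_set_fraction Fraction of a planted driver's targets drawn
#'   from the disease gene set (the remainder is background wiring).
#' @param background_parents Mean number of random parents per non-driver
#'   node (Poisson).
#' @param cis_fraction Fraction of eSNP records flagged as cis.
#' @param se_range Range of per-study standard errors for synthesized
#'   effect sizes.
#' @param overlap_pairs Optional list of lists with elements `size_a`,
#'   `size_b`, `r_ab`, `r_ba` describing extra gene-set pairs with
#'   prescribed directional overlap fractions (used to exercise the
#'   superset machinery). `r_ab * size_a` must equal `r_ba * size_b` and be
#'   a whole number not exceeding either size.
#' @param seed Integer seed; every generator derives its own sub-seed from
#'   it, so a fixed seed gives byte-identical outputs. `NULL` uses the
#'   current RNG state.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_snps = 1000, n_genes = 100, seed = 1)
#' cfg$signal_strength
#' @export
sim_config <- function(n_snps = 10000L,
                       n_genes = 1000L,
                       n_studies_stage1 = 7L,
                       n_studies_stage2 = 9L,
                       n_gene_sets = 100L,
                       set_size_range = c(20L, 100L),
                       planted_set_ids = "set001",
                       planted_set_size = 50L,
                       signal_strength = 0.2,
                       ld_block_size = 2L,
                       within_block_r2 = 0.8,
                       tissues = c("adipose", "liver"),
                       network_n_nodes = 1000L,
                       n_networks = 2L,
                       planted_driver_ids = "g00001",
                       hub_degree = 30L,
                       driver_set_fraction = 0.5,
                       background_parents = 2,
                       cis_fraction = 0.8,
                       se_range = c(0.05, 0.2),
                       overlap_pairs = NULL,
                       seed = 1L) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    n_studies_stage1 = as.integer(n_studies_stage1),
    n_studies_stage2 = as.integer(n_studies_stage2),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    planted_set_ids = as.character(planted_set_ids),
    planted_set_size = as.integer(planted_set_size),
    signal_strength = signal_strength,
    ld_block_size = as.integer(ld_block_size),
    within_block_r2 = within_block_r2,
    tissues = as.character(tissues),
    network_n_nodes = as.integer(network_n_nodes),
    n_networks = as.integer(n_networks),
    planted_driver_ids = as.character(planted_driver_ids),
    hub_degree = as.integer(hub_degree),
    driver_set_fraction = driver_set_fraction,
    background_parents = background_parents,
    cis_fraction = cis_fraction,
    se_range = se_range,
    overlap_pairs = overlap_pairs,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_snps", "n_genes", "n_studies_stage1", "n_studies_stage2",
              "n_gene_sets", "ld_block_size", "network_n_nodes",
              "n_networks", "hub_degree")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0L)
      stop("configuration error: '", f, "' must be a positive count",
           call. = FALSE)
  }
  if (cfg$signal_strength <= 0 || cfg$signal_strength > 1)
    stop("configuration error: signal_strength must be in (0, 1]",
         call. = FALSE)
  if (cfg$within_block_r2 < 0 || cfg$within_block_r2 > 1)
    stop("configuration error: within_block_r2 must be in [0, 1]",
         call. = FALSE)
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[1] < 1L ||
      cfg$set_size_range[2] < cfg$set_size_range[1] ||
      cfg$set_size_range[2] > cfg$n_genes)
    stop("configuration error: set_size_range must be within [1, n_genes]",
         call. = FALSE)
  if (cfg$planted_set_size < 1L || cfg$planted_set_size > cfg$n_genes)
    stop("configuration error: planted_set_size must be within [1, n_genes]",
         call. = FALSE)
  gen_ids <- gene_set_ids(cfg)
  if (!all(cfg$planted_set_ids %in% gen_ids))
    stop("configuration error: planted_set_ids must be a subset of the ",
         "generated set ids (", gen_ids[1], " ...)", call. = FALSE)
  if (cfg$hub_degree >= cfg$network_n_nodes)
    stop("configuration error: hub_degree must be smaller than ",
         "network_n_nodes", call. = FALSE)
  if (cfg$network_n_nodes > cfg$n_genes)
    stop("configuration error: network_n_nodes cannot exceed n_genes",
         call. = FALSE)
  if (length(cfg$tissues) < 1L)
    stop("configuration error: at least one tissue label is required",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_snps, "SNPs,", x$n_genes, "genes,",
      x$n_studies_stage1, "+", x$n_studies_stage2, "studies,",
      x$n_gene_sets, "gene sets,",
      "a =", x$signal_strength, "\n")
  invisible(x)
}

snp_ids <- function(cfg) sprintf("s%06d", seq_len(cfg$n_snps))
gene_ids <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))
gene_set_ids <- function(cfg) sprintf("set%03d", seq_len(cfg$n_gene_sets))

# Generators derive distinct sub-seeds from the config seed so that each is
# individually reproducible and the orchestrator stays deterministic.
sim_seed <- function(cfg, offset) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + offset)
  invisible(NULL)
}

sample_safe <- function(x, k) x[sample.int(length(x), k)]
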