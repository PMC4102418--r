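#' Simulate an eQTL/eSNP catalog
#'
#' Each SNP in the universe is assigned to one target gene drawn uniformly
#' at random, a tissue from `config$tissues`, one eQTL study per tissue, a
#' uniform expression-association p-value, and a cis/trans flag. Gene eSNP
#' counts are therefore approximately Poisson with mean
#' `n_snps / n_genes`.
#'
#' @param config A [sim_config()].
#' @return A `data.table` with columns `snp`, `gene`, `tissue`, `study`,
#'   `expr_pvalue`, `cis_trans`.
#' @export
simulate_esnp_catalog <- function(config) {
  validate_sim_config(config)
  sim_seed(config, 1L)
  n <- config$n_snps
  tissue <- sample(config$tissues, n, replace = TRUE)
  data.table(
    snp = snp_ids(config),
    gene = sample(gene_ids(config), n, replace = TRUE),
    tissue = tissue,
    study = paste0("eqtl_", tissue),
    expr_pvalue = runif(n),
    cis_trans = sample(c("cis", "trans"), n, replace = TRUE,
                       prob = c(config$cis_fraction, 1 - config$cis_fraction))
  )
}

#' Simulate a block-structured LD table
#'
#' SNPs are partitioned into consecutive blocks of `ld_block_size`; every
#' within-block pair has `r2 = within_block_r2` and between-block pairs have
#' no LD. Each unordered pair is emitted once (`snp_a < snp_b`); consumers
#' perform symmetric lookup. Pairs with `r2 = 0` are dropped.
#'
#' @param config A [sim_config()].
#' @return A `data.table` with columns `snp_a`, `snp_b`, `r2`.
#' @export
simulate_ld_table <- function(config) {
  validate_sim_config(config)
  snps <- snp_ids(config)
  b <- config$ld_block_size
  if (config$within_block_r2 == 0 || b < 2L)
    return(data.table(snp_a = character(), snp_b = character(),
                      r2 = numeric()))
  n <- config$n_snps
  pairs <- combn(seq_len(b), 2L)
  n_full <- n %/% b
  starts <- (seq_len(n_full) - 1L) * b
  ia <- rep(pairs[1, ], times = n_full) +
    rep(starts, each = ncol(pairs))
  ib <- rep(pairs[2, ], times = n_full) +
    rep(starts, each = ncol(pairs))
  rem <- n - n_full * b
  if (rem >= 2L) {
    pr <- combn(seq_len(rem), 2L)
    ia <- c(ia, n_full * b + pr[1, ])
    ib <- c(ib, n_full * b + pr[2, ])
  }
  data.table(snp_a = snps[ia], snp_b = snps[ib],
             r2 = config$within_block_r2)
}

#' Simulate gene sets with controlled overlaps
#'
#' Generates `n_gene_sets` sets with sizes uniform in `set_size_range`;
#' planted causal sets (ids in `planted_set_ids`) have exactly
#' `planted_set_size` genes and never contain planted network drivers, so
#' that causal-set membership and hub status remain independent. Extra
#' pairs with prescribed directional overlap fractions can be requested via
#' `config$overlap_pairs`; they are appended with ids `ovlNNNa`/`ovlNNNb`.
#'
#' @param config A [sim_config()].
#' @return A named list of character vectors of gene ids.
#' @export
simulate_gene_sets <- function(config) {
  validate_sim_config(config)
  sim_seed(config, 3L)
  universe <- gene_ids(config)
  ids <- gene_set_ids(config)
  planted_pool <- setdiff(universe, config$planted_driver_ids)
  sizes <- sample(config$set_size_range[1]:config$set_size_range[2],
                  config$n_gene_sets, replace = TRUE)
  sets <- vector("list", config$n_gene_sets)
  names(sets) <- ids
  for (i in seq_along(ids)) {
    if (ids[i] %in% config$planted_set_ids) {
      sets[[i]] <- sort(sample(planted_pool, config$planted_set_size))
    } else {
      sets[[i]] <- sort(sample(universe, sizes[i]))
    }
  }
  if (!is.null(config$overlap_pairs)) {
    for (k in seq_along(config$overlap_pairs)) {
      op <- config$overlap_pairs[[k]]
      shared_a <- op$r_ab * op$size_a
      shared_b <- op$r_ba * op$size_b
      if (abs(shared_a - shared_b) > 1e-9 ||
          abs(shared_a - round(shared_a)) > 1e-9)
        stop("requested overlap infeasible: r_ab*size_a must equal ",
             "r_ba*size_b and be a whole number", call. = FALSE)
      shared <- as.integer(round(shared_a))
      if (shared > min(op$size_a, op$size_b) ||
          op$size_a + op$size_b - shared > length(universe))
        stop("requested overlap infeasible for the given sizes",
             call. = FALSE)
      pick <- sample(universe, op$size_a + op$size_b - shared)
      core <- pick[seq_len(shared)]
      only_a <- pick[shared + seq_len(op$size_a - shared)]
      only_b <- pick[op$size_a + seq_len(op$size_b - shared)]
      sets[[sprintf("ovl%03da", k)]] <- sort(c(core, only_a))
      sets[[sprintf("ovl%03db", k)]] <- sort(c(core, only_b))
    }
  }
  sets
}

#' Assemble the ground truth of a simulated world
#'
#' The causal eSNPs are, by definition, exactly the catalog eSNPs mapped to
#' member genes of the planted causal gene sets.
#'
#' @param config A [sim_config()].
#' @param catalog Output of [simulate_esnp_catalog()].
#' @param gene_sets Output of [simulate_gene_sets()].
#' @return A list of class `sim_truth` with elements `causal_gene_sets`,
#'   `causal_genes`, `causal_esnps` and (filled by [simulate_dataset()])
#'   `planted_key_drivers`.
#' @export
simulate_truth <- function(config, catalog, gene_sets) {
  missing <- setdiff(config$planted_set_ids, names(gene_sets))
  if (length(missing) > 0L)
    stop("planted set id(s) absent from gene sets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  causal_genes <- sort(unique(unlist(gene_sets[config$planted_set_ids],
                                     use.names = FALSE)))
  truth <- list(
    causal_gene_sets = config$planted_set_ids,
    causal_genes = causal_genes,
    causal_esnps = sort(unique(catalog$snp[catalog$gene %in% causal_genes])),
    planted_key_drivers = list()
  )
  class(truth) <- c("sim_truth", "list")
  truth
}

#' Simulate per-study GWAS summary statistics
#'
#' Non-causal SNPs get per-study two-sided p-values that are exactly
#' Uniform(0,1); causal eSNPs (from `truth`) get Beta(`signal_strength`, 1)
#' p-values. Effect sizes are synthesized by the inverse-normal: `|z| =
#' qnorm(p/2, lower = FALSE)`, `beta = sign * |z| * se`, so the Wald p-value
#' recomputed from (beta, se) equals the emitted p-value. Causal SNPs carry
#' one effect-direction sign shared across studies (so signals replicate);
#' null SNPs get an independent random sign per study, which together with
#' the uniform p gives `beta/se ~ N(0,1)` exactly. At `signal_strength =
#' 1` causal SNPs are generated exactly like null SNPs, independent signs
#' included: a shared sign alone would correlate z-scores across studies
#' and de-calibrate the meta-analysis under the intended pure null.
#' QC covariates (MAF, HWE
#' p, imputation info, call rate) are drawn inside the passing ranges so
#' that the synthetic world survives default QC.
#'
#' @param config A [sim_config()].
#' @param catalog Output of [simulate_esnp_catalog()]; defines the SNP
#'   universe.
#' @param truth Output of [simulate_truth()].
#' @return A `data.table` with one row per (study, SNP): `study_id`,
#'   `stage`, `snp`, `allele1`, `allele2`, `beta`, `se`, `pvalue`, `maf`,
#'   `hwe_pvalue`, `info`, `call_rate`.
#' @export
simulate_gwas_studies <- function(config, catalog, truth) {
  validate_sim_config(config)
  if (!inherits(truth, "sim_truth"))
    stop("'truth' must be created by simulate_truth()", call. = FALSE)
  sim_seed(config, 4L)
  snps <- sort(unique(catalog$snp))
  n <- length(snps)
  causal <- snps %in% truth$causal_esnps
  a <- config$signal_strength
  bases <- c("A", "C", "G", "T")
  a1 <- sample.int(4L, n, replace = TRUE)
  allele1 <- bases[a1]
  allele2 <- bases[(a1 - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  causal_sign <- sample(c(-1, 1), n, replace = TRUE)

  studies <- data.table(
    study_id = c(sprintf("S1_%02d", seq_len(config$n_studies_stage1)),
                 sprintf("S2_%02d", seq_len(config$n_studies_stage2))),
    stage = rep(c(1L, 2L),
                c(config$n_studies_stage1, config$n_studies_stage2))
  )
  out <- vector("list", nrow(studies))
  for (i in seq_len(nrow(studies))) {
    p <- runif(n)
    if (any(causal) && a < 1) p[causal] <- rbeta(sum(causal), a, 1)
    p <- pmax(p, 1e-300)
    z <- qnorm(p / 2, lower.tail = FALSE)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    # shared signs only when there is a signal: a shared sign with a = 1
    # would correlate z-scores across studies and break the pure null
    if (a < 1) sgn[causal] <- causal_sign[causal]
    se <- runif(n, config$se_range[1], config$se_range[2])
    out[[i]] <- data.table(
      study_id = studies$study_id[i], stage = studies$stage[i],
      snp = snps, allele1 = allele1, allele2 = allele2,
      beta = sgn * z * se, se = se, pvalue = p,
      maf = runif(n, 0.05, 0.5),
      hwe_pvalue = runif(n, 0.001, 1),
      info = runif(n, 0.6, 1),
      call_rate = runif(n, 0.8, 1)
    )
  }
  rbindlist(out)
}

#' Simulate a directed acyclic gene network with planted hub drivers
#'
#' Nodes are arranged in a random topological order with the planted
#' drivers first; all edges point forward in that order, so the graph is
#' acyclic by construction. Each planted driver receives `hub_degree`
#' out-edges of which a fraction `driver_set_fraction` target genes of the
#' supplied disease gene set; every other node receives a Poisson
#' (`background_parents`) number of random parents among earlier nodes.
#'
#' @param config A [sim_config()].
#' @param superset_genes Character vector of disease-set gene ids to wire
#'   the hubs into.
#' @param network_id Integer id; also offsets the sub-seed so different
#'   networks are independent draws.
#' @return An `igraph` directed graph with graph attribute `network_id`.
#' @export
simulate_network <- function(config, superset_genes, network_id = 1L) {
  validate_sim_config(config)
  sim_seed(config, 100L + network_id)
  universe <- gene_ids(config)
  drivers <- config$planted_driver_ids
  nn <- config$network_n_nodes
  set_in <- intersect(setdiff(superset_genes, drivers), universe)
  pool <- setdiff(universe, c(drivers, set_in))
  n_fill <- nn - length(drivers) - length(set_in)
  if (n_fill < 0L)
    stop("configuration error: network_n_nodes too small for drivers ",
         "plus superset genes", call. = FALSE)
  nodes <- c(drivers, sample(c(set_in, sample(pool, n_fill))))
  is_set <- nodes %in% superset_genes
  n_drv <- length(drivers)

  from <- integer(0); to <- integer(0)
  for (d in seq_len(n_drv)) {
    later <- (d + 1L):nn
    cand_set <- later[is_set[later]]
    cand_bg <- later[!is_set[later] & later > n_drv]
    k_set <- min(round(config$hub_degree * config$driver_set_fraction),
                 length(cand_set))
    k_bg <- min(config$hub_degree - k_set, length(cand_bg))
    # sample_safe avoids the sample(x) length-1 pitfall
    tgt <- c(sample_safe(cand_set, k_set), sample_safe(cand_bg, k_bg))
    from <- c(from, rep(d, length(tgt))); to <- c(to, tgt)
  }
  n_par <- pmin(rpois(nn, config$background_parents), seq_len(nn) - 1L)
  for (i in (n_drv + 1L):nn) {
    if (n_par[i] > 0L) {
      par <- sample.int(i - 1L, n_par[i])
      from <- c(from, par); to <- c(to, rep(i, n_par[i]))
    }
  }
  el <- unique(data.table(source = nodes[from], target = nodes[to]))
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g))
    stop("internal error: cycle detected in simulated network")
  g <- igraph::set_graph_attr(g, "network_id", network_id)
  g
}

#' Simulate a complete pipeline input bundle with known ground truth
#'
#' Orchestrates all generators under one seed: gene sets, eSNP catalog,
#' ground truth, LD table, per-study GWAS summary statistics, and
#' `n_networks` directed networks whose hubs are wired into the union of
#' the planted causal sets.
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `gene_sets`, `catalog`, `ld`,
#'   `studies`, `networks` (list of igraph), `truth`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_snps = 2000, n_genes = 200,
#'                                    n_gene_sets = 20, network_n_nodes = 150,
#'                                    set_size_range = c(10, 30),
#'                                    planted_set_size = 15, seed = 7))
#' length(sim$truth$causal_esnps)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  gene_sets <- simulate_gene_sets(config)
  catalog <- simulate_esnp_catalog(config)
  truth <- simulate_truth(config, catalog, gene_sets)
  ld <- simulate_ld_table(config)
  studies <- simulate_gwas_studies(config, catalog, truth)
  networks <- lapply(seq_len(config$n_networks), function(k)
    simulate_network(config, truth$causal_genes, network_id = k))
  truth$planted_key_drivers <- setNames(
    rep(list(config$planted_driver_ids), config$n_networks),
    sprintf("network_%02d", seq_len(config$n_networks)))
  list(config = config, gene_sets = gene_sets, catalog = catalog, ld = ld,
       studies = studies, networks = networks, truth = truth)
}
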