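# Synthetic-data generators: determinism, generating laws, ground truth.

test_that("a fixed seed gives identical outputs across runs", {
  cfg <- small_config()
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$ld, s2$ld)
  expect_identical(s1$gene_sets, s2$gene_sets)
  expect_identical(s1$studies, s2$studies)
  expect_identical(s1$truth$causal_esnps, s2$truth$causal_esnps)
  expect_identical(igraph::as_data_frame(s1$networks[[1]]),
                   igraph::as_data_frame(s2$networks[[1]]))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_snps = 0), "positive count")
  expect_error(sim_config(signal_strength = 0), "signal_strength")
  expect_error(sim_config(signal_strength = 1.2), "signal_strength")
  expect_error(sim_config(within_block_r2 = 1.5), "within_block_r2")
  expect_error(sim_config(planted_set_ids = "nope"), "planted_set_ids")
  expect_error(small_config(hub_degree = 150L), "hub_degree")
  expect_error(sim_config(set_size_range = c(10, 5)), "set_size_range")
})

test_that("catalog respects tissue labels and covers the SNP universe", {
  cfg <- small_config(tissues = "liver")
  cat1 <- simulate_esnp_catalog(cfg)
  expect_true(all(cat1$tissue == "liver"))
  expect_true(all(cat1$study == "eqtl_liver"))
  expect_identical(sort(cat1$snp), sort(sprintf("s%06d", 1:cfg$n_snps)))
  expect_true(all(cat1$cis_trans %in% c("cis", "trans")))
})

test_that("non-causal expression p-values are uniform (K-S, n = 5000)", {
  cfg <- small_config(n_snps = 5000L, n_genes = 500L)
  catalog <- simulate_esnp_catalog(cfg)
  sets <- simulate_gene_sets(cfg)
  truth <- simulate_truth(cfg, catalog, sets)
  noncausal <- catalog$expr_pvalue[!catalog$snp %in% truth$causal_esnps]
  expect_gt(length(noncausal), 4000)
  expect_gt(ks.test(noncausal, "punif")$p.value, 0.01)
})

test_that("LD table enumerates within-block pairs exactly once", {
  cfg <- sim_config(n_snps = 9L, n_genes = 20L, n_gene_sets = 2L,
                    set_size_range = c(2L, 5L), planted_set_size = 3L,
                    ld_block_size = 3L, network_n_nodes = 10L,
                    hub_degree = 3L, seed = 1L)
  ld <- simulate_ld_table(cfg)
  expect_equal(nrow(ld), 9L)  # C(3,2) * 3 blocks
  expect_true(all(ld$snp_a < ld$snp_b))       # one row per unordered pair
  expect_false(any(duplicated(ld[, c("snp_a", "snp_b")])))
  expect_false(any(ld$snp_a == ld$snp_b))
  expect_true(all(ld$r2 == cfg$within_block_r2))

  cfg0 <- sim_config(n_snps = 9L, n_genes = 20L, n_gene_sets = 2L,
                     set_size_range = c(2L, 5L), planted_set_size = 3L,
                     ld_block_size = 3L, within_block_r2 = 0,
                     network_n_nodes = 10L, hub_degree = 3L, seed = 1L)
  expect_equal(nrow(simulate_ld_table(cfg0)), 0L)
})

test_that("GWAS p-values follow the stated generating laws", {
  # signal_strength = 1: causal p-values are uniform (pure null)
  cfg1 <- small_config(signal_strength = 1, n_snps = 5000L,
                       n_genes = 500L)
  catalog <- simulate_esnp_catalog(cfg1)
  sets <- simulate_gene_sets(cfg1)
  truth <- simulate_truth(cfg1, catalog, sets)
  st <- simulate_gwas_studies(cfg1, catalog, truth)
  causal_p <- st$pvalue[st$snp %in% truth$causal_esnps]
  expect_gt(length(causal_p), 100)
  expect_gt(ks.test(causal_p, "punif")$p.value, 0.01)

  # signal_strength = 0.2: causal p-values stochastically smaller
  cfg2 <- sim_config(n_snps = 10000L, n_genes = 1000L, seed = 9L,
                     tissues = "t1")
  catalog2 <- simulate_esnp_catalog(cfg2)
  sets2 <- simulate_gene_sets(cfg2)
  truth2 <- simulate_truth(cfg2, catalog2, sets2)
  one <- simulate_gwas_studies(cfg2, catalog2, truth2)
  one <- one[one$study_id == "S1_01", ]
  expect_lt(median(one$pvalue[one$snp %in% truth2$causal_esnps]),
            median(one$pvalue[!one$snp %in% truth2$causal_esnps]))

  # Wald p recomputed from (beta, se) equals the emitted p
  expect_equal(2 * pnorm(-abs(one$beta / one$se)), one$pvalue,
               tolerance = 1e-10)
})

test_that("gene sets honor sizes and prescribed overlaps", {
  cfg <- small_config(n_genes = 400L, overlap_pairs = list(
    list(size_a = 50L, size_b = 200L, r_ab = 0.4, r_ba = 0.1),
    list(size_a = 10L, size_b = 10L, r_ab = 0, r_ba = 0)))
  sets <- simulate_gene_sets(cfg)
  a <- sets[["ovl001a"]]; b <- sets[["ovl001b"]]
  expect_length(a, 50L); expect_length(b, 200L)
  expect_length(intersect(a, b), 20L)  # 0.4*50 = 0.1*200 = 20
  expect_length(intersect(sets[["ovl002a"]], sets[["ovl002b"]]), 0L)
  sizes <- lengths(sets[sprintf("set%03d", 2:cfg$n_gene_sets)])
  expect_true(all(sizes >= cfg$set_size_range[1] &
                    sizes <= cfg$set_size_range[2]))
  # planted set has its configured size
  expect_length(sets[["set001"]], cfg$planted_set_size)

  bad <- small_config(overlap_pairs = list(
    list(size_a = 10L, size_b = 10L, r_ab = 0.5, r_ba = 0.1)))
  expect_error(simulate_gene_sets(bad), "infeasible")
})

test_that("simulated networks are DAGs with enriched planted hubs", {
  cfg <- small_config()
  sets <- simulate_gene_sets(cfg)
  catalog <- simulate_esnp_catalog(cfg)
  truth <- simulate_truth(cfg, catalog, sets)
  g <- simulate_network(cfg, truth$causal_genes, network_id = 1L)
  expect_true(igraph::is_dag(g))
  drv <- cfg$planted_driver_ids
  expect_gte(igraph::degree(g, drv, mode = "out"), cfg$hub_degree)
  nb <- neighborhood(g, drv, depth = 1L, direction = "out")
  frac_nb <- mean(nb %in% truth$causal_genes)
  frac_all <- mean(igraph::V(g)$name %in% truth$causal_genes)
  expect_gt(frac_nb, frac_all)
})

test_that("ground truth is consistent and validated", {
  cfg <- small_config()
  sets <- simulate_gene_sets(cfg)
  catalog <- simulate_esnp_catalog(cfg)
  truth <- simulate_truth(cfg, catalog, sets)
  causal_genes <- unique(unlist(sets[cfg$planted_set_ids],
                                use.names = FALSE))
  expect_setequal(truth$causal_esnps,
                  unique(catalog$snp[catalog$gene %in% causal_genes]))
  expect_error(simulate_truth(cfg, catalog, sets[-1]), "absent")
})

test_that("null GWAS p-values pass uniformity in >= 95% of 100 seeds", {
  cfg0 <- sim_config(n_snps = 5000L, n_genes = 500L,
                     n_studies_stage1 = 1L, n_studies_stage2 = 1L,
                     signal_strength = 1, tissues = "t1",
                     network_n_nodes = 400L, seed = 1L)
  catalog <- simulate_esnp_catalog(cfg0)
  sets <- simulate_gene_sets(cfg0)
  truth <- simulate_truth(cfg0, catalog, sets)
  pass <- vapply(1:100, function(s) {
    cfg <- cfg0; cfg$seed <- 1000L + s
    st <- simulate_gwas_studies(cfg, catalog, truth)
    p <- st$pvalue[st$stage == 1L]
    ks.test(p, "punif")$p.value > 0.01
  }, NA)
  expect_gte(mean(pass), 0.95)
})

test_that("written dataset round-trips through the plain-text formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_config())
  write_sim_dataset(sim, dir)
  studies <- read_gwas_studies(dir)
  expect_equal(nrow(studies), nrow(sim$studies))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets[order(names(sets))],
                   sim$gene_sets[order(names(sim$gene_sets))])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$causal_esnps), sim$truth$causal_esnps)
})
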