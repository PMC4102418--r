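# SNP-set enrichment: K-S and Fisher components, scores, permutation FDR.

test_that("one-sided K-S tail matches closed form and simulation", {
  # n = 1 closed form: P(D+ >= d) = 1 - d
  for (d in c(0.1, 0.5, 0.9))
    expect_equal(cadnet:::ks_p_upper(d, 1L), 1 - d)
  expect_equal(cadnet:::ks_p_upper(0, 10L), 1)
  expect_equal(cadnet:::ks_p_upper(1, 10L), 0)

  # Monte-Carlo oracle at the generating law (iid uniform samples)
  set.seed(404)
  nmc <- 40000L
  dmc <- vapply(seq_len(nmc), function(i)
    cadnet:::ks_stat_plus(runif(15)), 1.0)
  for (d in c(0.2, 0.3, 0.4)) {
    p_mc <- mean(dmc >= d)
    p_exact <- cadnet:::ks_p_upper(d, 15L)
    se <- sqrt(p_mc * (1 - p_mc) / nmc)
    expect_lt(abs(p_mc - p_exact), 4 * se + 1e-4)
  }

  # compiled mirror agrees with the R implementation on both branches
  for (n in c(5L, 50L, 140L, 200L, 500L))
    for (d in c(0.01, 0.1, 0.33, 0.7))
      expect_equal(cadnet:::cpp_ks_p_upper(d, n),
                   cadnet:::ks_p_upper(d, n), tolerance = 1e-12)
})

test_that("K-S enrichment detects extreme sets and is calibrated", {
  ub <- uniform_background(100, seed = 8)
  top10 <- names(sort(ub$p))[1:10]
  p_top <- ks_enrichment(top10, ub$p, ub$bg)
  # ranks 1..10 of 100: D+ = 0.9; far beyond anything a permutation sees
  expect_equal(p_top, cadnet:::ks_p_upper(0.9, 10L))
  expect_lt(p_top, 1e-10)

  # entire background: ranks are the exact uniform grid
  expect_equal(ks_enrichment(ub$bg$snp_ids, ub$p, ub$bg), 1,
               tolerance = 1e-6)

  expect_warning(p1 <- ks_enrichment(top10[1], ub$p, ub$bg), "smaller")
  expect_equal(p1, 1)
  expect_error(ks_enrichment("nope", ub$p, ub$bg), "subset")

  # null calibration: uniform-or-conservative over random subsets
  set.seed(11)
  ub2 <- uniform_background(500, seed = 12)
  pvals <- vapply(1:200, function(i)
    ks_enrichment(sample(ub2$bg$snp_ids, 25), ub2$p, ub2$bg), 1.0)
  expect_lte(mean(pvals <= 0.05), 0.10)
  expect_gt(suppressWarnings(
    ks.test(pvals, "punif", alternative = "greater")$p.value), 0.01)

  # two-sample mode agrees in direction on the planted case
  expect_lt(ks_enrichment(top10, ub$p, ub$bg, mode = "two.sample"), 1e-6)
})

test_that("Fisher top-fraction test matches the hypergeometric oracle", {
  ub <- uniform_background(100, seed = 3)
  ord <- names(sort(ub$p))
  topT <- ord[1:5]                     # ceiling(0.05 * 100) = 5
  set <- c(topT[1:3], ord[50:56])      # 3 of 10 in the top set
  p <- fisher_top_enrichment(set, ub$p, ub$bg)
  expect_equal(p, hyper_tail(3, 5, 10, 100), tolerance = 1e-12)

  # disjoint from the top: P(X >= 0) = 1
  expect_equal(fisher_top_enrichment(ord[40:49], ub$p, ub$bg), 1)

  # set equal to the top set: minimal attainable p for the margins
  p_min <- fisher_top_enrichment(topT, ub$p, ub$bg)
  expect_equal(p_min, hyper_tail(5, 5, 5, 100), tolerance = 1e-12)
  expect_equal(p_min, 1 / choose(100, 5), tolerance = 1e-9)
})

test_that("the enrichment score is the mean -log10 with clamping", {
  expect_equal(enrichment_score(1e-10, 1e-12), 11)
  expect_equal(enrichment_score(1, 1), 0)
  expect_equal(enrichment_score(1e-29, 1e-29), 29)
  expect_warning(s <- enrichment_score(0, 1e-10), "clamped")
  expect_equal(s, 155)
})

test_that("scores are invariant to monotone transforms of GWAS p", {
  ub <- uniform_background(300, seed = 21)
  set.seed(22)
  sets <- lapply(1:20, function(i) sample(ub$bg$snp_ids, 15))
  p2 <- ub$p^2  # strictly monotone transform
  for (i in seq_along(sets)) {
    expect_equal(ks_enrichment(sets[[i]], ub$p, ub$bg),
                 ks_enrichment(sets[[i]], p2, ub$bg), tolerance = 1e-12)
    expect_equal(fisher_top_enrichment(sets[[i]], ub$p, ub$bg),
                 fisher_top_enrichment(sets[[i]], p2, ub$bg),
                 tolerance = 1e-12)
  }
})

test_that("identity permutation yields FDR 1 for every achieved score", {
  ub <- uniform_background(200, seed = 31)
  set.seed(32)
  sets <- setNames(lapply(1:15, function(i) sample(ub$bg$snp_ids, 10)),
                   paste0("set", 1:15))
  r <- permutation_fdr(sets, ub$p, ub$bg, n_perm = 1L, permute = FALSE)
  expect_true(all(r$fdr == 1))
  expect_error(permutation_fdr(sets, ub$p, ub$bg, n_perm = 0L), "n_perm")
})

test_that("permutation FDR separates a planted set from the null", {
  ub <- uniform_background(500, seed = 41)
  set.seed(42)
  planted <- names(sort(ub$p))[1:20]
  sets <- c(list(planted = planted),
            setNames(lapply(1:30, function(i)
              sample(ub$bg$snp_ids, 20)), paste0("null", 1:30)))
  r <- permutation_fdr(sets, ub$p, ub$bg, n_perm = 100L)
  expect_equal(unname(r$fdr["planted"]), 0)
  # observed scores match the public per-set operations (dual route)
  for (nm in c("planted", "null1", "null7")) {
    sc <- enrichment_score(ks_enrichment(sets[[nm]], ub$p, ub$bg),
                           fisher_top_enrichment(sets[[nm]], ub$p, ub$bg))
    expect_equal(unname(r$observed[nm]), sc, tolerance = 1e-9)
  }
  # FDR is monotone non-increasing in the score threshold
  ord <- order(r$observed, decreasing = TRUE)
  expect_true(all(diff(r$fdr[ord]) >= 0))
})

test_that("null-only runs estimate FDR near 1 at high thresholds", {
  set.seed(51)
  fdrs <- vapply(1:20, function(rep) {
    ub <- uniform_background(300, seed = 600 + rep)
    sets <- lapply(1:200, function(i) sample(ub$bg$snp_ids, 12))
    r <- permutation_fdr(sets, ub$p, ub$bg, n_perm = 50L)
    thr <- quantile(r$observed, 0.95)
    mean(r$fdr[r$observed >= thr])
  }, 1.0)
  expect_gt(mean(fdrs), 0.7)
})

test_that("the two-stage call applies strict thresholds", {
  expect_true(multi_stage_call(0.15, 0.18, 0.04))
  expect_false(multi_stage_call(0.25, 0.05, 0.01))
  expect_false(multi_stage_call(0.20, 0.10, 0.04))  # strict boundary
  expect_identical(multi_stage_call(c(0.1, 0.3), c(0.1, 0.1),
                                    c(0.01, 0.01)),
                   c(TRUE, FALSE))
})

test_that("run_ssea produces one row per set and tissue and recovers
          the planted causal set", {
  cfg <- small_config(n_snps = 3000L, n_genes = 300L,
                      tissues = c("adipose", "liver"))
  sim <- simulate_dataset(cfg)
  meta <- run_stage_meta(qc_filter_snps(sim$studies))
  res <- run_ssea(sim$gene_sets, sim$catalog, sim$ld, meta,
                  tissues = c("all", "adipose", "liver"),
                  n_perm = 100L, seed = 1L)
  expect_equal(nrow(res), length(sim$gene_sets) * 3L)
  expect_true(res$significant[res$set_name == "set001" &
                                res$tissue == "all"])
  expect_error(run_ssea(sim$gene_sets, sim$catalog, sim$ld,
                        meta[c("stage1", "stage2")], n_perm = 10L),
               "missing stage")

  # deterministic under a fixed seed
  res2 <- run_ssea(sim$gene_sets, sim$catalog, sim$ld, meta,
                   tissues = c("all", "adipose", "liver"),
                   n_perm = 100L, seed = 1L)
  expect_identical(res, res2)

  # the fast in-pipeline mapping equals the public map_gene_set()
  bg <- build_background(sim$catalog, sim$ld, "adipose")
  ms <- map_gene_set(sim$gene_sets[["set005"]], sim$catalog, bg)
  row <- res[res$set_name == "set005" & res$tissue == "adipose", ]
  expect_equal(row$n_esnps, length(ms$snp_ids))
})
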