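# cadnet

Integrative genomics for GWAS of complex disease: eQTL-anchored SNP-set
enrichment analysis with a two-stage replication design, merging of
associated gene sets into non-overlapping supersets, and key driver
detection in directed gene networks. The package is aimed at statistical
geneticists and systems biologists who have (i) per-study GWAS summary
statistics, (ii) eQTL/eSNP catalogs for disease-relevant tissues, (iii)
gene-set collections (pathways and/or co-expression modules, GMT), and
(iv) directed gene-network edge lists — and who want to move from
SNP-level association to process-level and regulator-level statements.

## The statistics at the core

**Meta-analysis.** Per SNP, fixed-effect inverse variance pooling,
β̂ = Σwᵢβᵢ/Σwᵢ with wᵢ = 1/seᵢ², Cochran's Q and I² = max(0, (Q−df)/Q);
SNPs with Q-test p < 1e-4 switch to DerSimonian–Laird random effects,
τ² = max(0, (Q−df)/(Σw − Σw²/Σw)). Stage 1 and Stage 2 cohort groups are
pooled separately plus combined.

**SNP-set enrichment (SSEA).** A gene set is mapped to the eSNPs of its
member genes inside an LD-pruned, tissue-specific eSNP background (greedy
pruning at r² ≥ 0.7, preferentially keeping SNPs with strong expression
association after within-study rank scaling). Enrichment of low GWAS
p-values is scored by

    score = ( −log10 p_KS − log10 p_Fisher ) / 2

where p_KS is a one-sided one-sample Kolmogorov–Smirnov test of the set's
background-rank fractions against Uniform(0,1) (many weak signals) and
p_Fisher a one-sided hypergeometric test of over-representation in the
top 5% of the background (few strong signals). False discovery rates come
from permuting the assignment of GWAS p-values to background eSNPs
(1000 permutations by default); a set is significant at FDR < 20% in both
independent stages and FDR < 5% combined (20% × 20% = 4% joint bound).

**Supersets.** Overlapping significant sets (overlap ratio
r = √(r_AB·r_BA) with a Bonferroni-significant Fisher overlap) are merged
by connected components and trimmed to ≤ 200-gene cores by removing whole
strata of least-shared genes, over two rounds, targeting < 20% pairwise
overlap; supersets are annotated against reference categories or labeled
"Unknown".

**Key driver analysis (KDA).** Every network gene is tested for
enrichment of a superset in its neighborhood (depth 1, undirected by
default; Fisher test, Bonferroni over genes tested). Across networks,
genes are ranked by (N − 0.99) × mean(−log10 p) — consistency times
significance, strongly favoring drivers replicated in ≥ 2 networks.
`neighbor_set_enrichment()` provides the fold-enrichment statistic
(observed vs |pool|·|query|/universe) used to check that experimentally
perturbed genes concentrate around key drivers.

A synthetic-data module (`sim_config()`, `simulate_dataset()`) generates
every input with known ground truth — planted causal gene sets whose
eSNPs draw Beta(a,1) p-values, block LD, two-stage study structure, and
DAG networks with planted hubs — so the full pipeline is testable
without external data. See the methods vignette
(`vignettes/integrative-esnp-enrichment.Rmd`) for models, assumptions,
and design choices.

## Worked example

```r
library(cadnet)

cfg <- sim_config(n_snps = 4000, n_genes = 400, n_gene_sets = 40,
                  set_size_range = c(10, 40), planted_set_size = 25,
                  network_n_nodes = 300, seed = 11)
sim  <- simulate_dataset(cfg)                      # inputs + ground truth
meta <- run_stage_meta(qc_filter_snps(sim$studies))
res  <- run_ssea(sim$gene_sets, sim$catalog, sim$ld, meta,
                 tissues = "all", n_perm = 200, seed = 11)
res[res$significant, ]
```

```
   set_name tissue n_esnps          p_ks      p_fisher      score fdr_stage1 fdr_stage2 fdr_combined significant
1:   set001    all     139 1.086716e-161 4.608486e-137 148.650163      0.000 0.00000000        0.000        TRUE
2:   set010    all     154  1.368982e-01  3.173451e-03   1.681035      0.008 0.05125000        0.044        TRUE
...
```

The planted causal set (`set001`, 25 genes, 139 background eSNPs) is
recovered with an overwhelming score of 148.7 and FDR 0 in every stage.
The other flagged sets are not artifacts: in a small 400-gene universe,
random sets share member genes with the planted set and genuinely inherit
part of its signal (under a fully null world the rule flags ≈ 0 sets; see
the acceptance tests).

```r
kd <- lapply(sim$networks, find_key_drivers,
             superset_genes = sim$truth$causal_genes)
rank_across_networks(kd)
```

```
   gene_id     N consistency significance rank_score
1:  g00001     2        1.01     8.863568   8.952204
```

The planted hub `g00001` is a Bonferroni-significant key driver in both
networks (N = 2, consistency 1.01) with mean −log10 p of 8.86, giving
rank score 8.95 — the top-ranked regulator of the planted gene set.

A file-based CLI covers the same pipeline:
`inst/cli/cadnet simulate|meta|map-esnps|ssea|merge|kda ...`
(see `?pipeline_cli`).

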