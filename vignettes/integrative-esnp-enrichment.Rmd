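---
title: "Methods: eQTL-anchored SNP-set enrichment and key driver analysis"
author: "cadnet developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL-anchored SNP-set enrichment and key driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadnet)
```

## The problem

Genome-wide association studies of complex diseases such as coronary
artery disease yield thousands of SNP-level association p-values, but
individual susceptibility loci explain little heritability and rarely
reveal mechanism. cadnet implements an integrative strategy that asks a
different question: do the *expression SNPs* (eSNPs) that collectively
regulate a biological process — a curated pathway or a data-driven
co-expression module — carry more disease association than expected by
chance? Gene sets are mapped to eSNP sets through tissue-specific eQTL
catalogs, scored against GWAS meta-analysis p-values, merged into
non-overlapping supersets, and finally projected onto directed gene
networks to nominate *key driver* genes whose network neighborhoods
concentrate the disease-associated set.

Because the original analyses of this kind depend on consortium GWAS,
proprietary eQTL corpora and large pathway collections, the package ships
a first-class synthetic-data module that generates every input with known
ground truth, so that each stage — and the pipeline end to end — is
testable on a desktop.

## Pipeline stages and their models

### 1. Two-stage GWAS meta-analysis (`qc_filter_snps`, `run_stage_meta`)

Per-study summary statistics are filtered with the conventional
exclusions: minor allele frequency < 1%, Hardy–Weinberg disequilibrium
p < 1e-4, imputation quality < 50%, call rate < 75%, and a presence rule
requiring a SNP in at least 3 Stage-1 and 5 Stage-2 cohorts (the default
study design is 7 + 9 = 16 cohorts). Each stage is pooled per SNP by the
fixed-effect inverse-variance model
\[
\hat\beta = \frac{\sum_i w_i \beta_i}{\sum_i w_i},\qquad
w_i = 1/\mathrm{se}_i^2,\qquad
\mathrm{se}(\hat\beta) = \Big(\sum_i w_i\Big)^{-1/2},
\]
with Cochran's \(Q = \sum_i w_i (\beta_i - \hat\beta)^2\) on \(k-1\)
degrees of freedom and \(I^2 = \max(0, (Q - df)/Q)\). SNPs whose Q-test
p-value falls below 1e-4 are switched to the DerSimonian–Laird
random-effects model with
\(\tau^2 = \max\{0, (Q - df) / (\sum w - \sum w^2/\sum w)\}\) and weights
\(1/(\mathrm{se}_i^2 + \tau^2)\). The heterogeneity gate acts on Q only:
\(I^2\) is a descriptive quantity with no native p-value, so "significant
Q and I" is implemented as the single inferential test on Q. The combined
Stage 1+2 analysis covers the *union* of SNPs passing either stage's
presence rule — a SNP failing presence in one stage but not the other is
a genuinely ambiguous case, and union semantics keeps every SNP that any
stage can legitimately meta-analyze.

No genomic-control correction is applied; two-sided p-values come from
the normal distribution of \(\hat\beta/\mathrm{se}\).

### 2. eSNP backgrounds (`rank_scale`, `ld_prune`, `build_background`)

eSNPs are enriched for disease associations as a class, so testing a gene
set's eSNPs against *all* SNPs would inflate every set. The null universe
is therefore the pool of eSNPs itself, per tissue (or pooled over tissues,
`"all"`).

Raw expression p-values are not comparable across eQTL studies of
different size, so within each study the records are ranked by expression
p-value and the ranks scaled to \([0,1]\) as \((\mathrm{rank}-1)/(n-1)\)
(mean rank for ties, 0 for a single record) before pooling. The scaling
convention is one of several that map ranks onto the unit interval; the
choice only fixes endpoints and cannot change the pruning order between
two SNPs from the same study.

LD pruning is greedy keep-best: a SNP's priority is the *minimum* scaled
rank over all of its records (a SNP may be an eSNP for several genes and
studies), SNPs are visited in ascending priority with lexicographic
tie-breaks, and a SNP is kept iff no previously kept SNP is linked to it
at \(r^2 \ge 0.7\). The output is an independent set of the conflict
graph, deterministic, and preferentially retains SNPs with strong
expression association. At the default synthetic LD structure (blocks of
2 SNPs at \(r^2 = 0.8\)) pruning rejects 50% of eSNPs, matching the
regime the method was designed for. The upstream eSNP FDR < 10% filter is
assumed already applied to input eQTL tables.

### 3. SNP-set enrichment (`run_ssea`)

A gene set's eSNP set is the subset of the tissue background with a
record to a member gene. Enrichment of low GWAS p-values is scored with
two complementary statistics:

* **K-S component** (`ks_enrichment`) — ranks of the set members within
  the background p-value ordering are scaled to fractions in \((0,1]\)
  and tested against Uniform(0,1) with a one-sample, one-sided
  Kolmogorov–Smirnov test (\(D^+ = \max_i (i/n - u_{(i)})\); alternative:
  ranks smaller than uniform). Sensitive to many weak signals. The
  p-value is the exact Birnbaum–Tingey tail for \(n \le 140\) and the
  asymptotic \(e^{-2 n d^2}\) above; by the sharp
  Dvoretzky–Kiefer–Wolfowitz bound the asymptotic form is an upper bound
  on the exact tail, so large sets are never anti-conservative. Both
  one-sample (ranks vs. the uniform grid) and two-sample (set vs.
  background complement) variants are defensible; the one-sample form is
  the default and the two-sample mode is available behind `mode =
  "two.sample"`.
* **Fisher component** (`fisher_top_enrichment`) — one-sided
  hypergeometric test of over-representation among the top 5% of
  background SNPs by association strength (\(\lceil 0.05 N\rceil\) SNPs,
  p-value ties broken by SNP id). Sensitive to a few strong signals.

The enrichment score is \(\tfrac12(-\log_{10} p_{KS} - \log_{10}
p_{Fisher})\), with p-values clamped at 1e-300 before the logarithm. Sets
mapping to fewer than 2 background eSNPs are reported with p = 1 and
score 0.

**Permutation FDR** (`permutation_fdr`): the assignment of GWAS p-values
to background eSNPs is randomly permuted while set memberships and the
pruned background stay intact; all set scores are recomputed per
permutation, and for each observed score \(s\),
\[
\mathrm{FDR}(s) = \frac{\frac{1}{P}\sum_{p=1}^{P} \#\{\text{permuted
scores} \ge s\}}{\#\{\text{observed scores} \ge s\}}
\]
capped at 1 (1000 permutations by default; the heavy acceptance
simulations use 200, stated where they do). Raw ratios are then
monotonized by a running maximum from the top score downwards, a
conservative correction guaranteeing that FDR is non-increasing in the
score threshold. FDRs are pooled within a tissue run, not across tissues.

A set is **significant** when FDR < 20% in each of the two independent
stages and FDR < 5% in the combined Stage 1+2 analysis (strict
inequalities). Independence of the stages alone bounds the joint FDR by
\(0.2 \times 0.2 = 4\% < 5\%\). For a confirmatory second SSEA round on
merged supersets, a Bonferroni threshold over the number of *original*
gene sets is the documented convention; the correction count is an
explicit parameter wherever it appears.

### 4. Supersets (`build_supersets`)

Pathway databases and module collections overlap heavily. Two sets A and
B overlap with \(r_{AB} = |A\cap B|/|A|\), \(r_{BA} = |A\cap B|/|B|\) and
the symmetric ratio \(r = \sqrt{r_{AB} r_{BA}}\) (distance \(d = 1-r\));
the geometric mean stays small for nested sets of very different sizes
and so discourages merging a subset into a giant superset. Overlaps must
also be significant by a one-sided Fisher test, Bonferroni-corrected over
the pairs tested in the round. Clusters are connected components of the
significant-overlap graph — equivalent to single-linkage hierarchical
clustering of \(d\) cut at any nonzero overlap, which is why the linkage
choice is immaterial at that cutoff. Merged sets are trimmed to a
200-gene core by removing whole strata of the least-shared genes
(smallest number of constituent sets), stopping before a removal that
would cross below the limit; this whole-stratum rule is deterministic and
needs no intra-stratum tie-break, and a per-gene mode with lexicographic
ties is available (`trim_core(mode = "per_gene")`). Note that with
whole-stratum semantics the final size reaches the limit exactly only
when a stratum boundary lands there; otherwise trimming stops above it
rather than splitting a stratum arbitrarily. The
overlap–cluster–merge–trim cycle runs twice by default; if the maximum
pairwise ratio still exceeds 20% afterwards the function warns rather
than looping. Supersets are annotated by Fisher over-representation
against reference categories (Bonferroni over the number of categories;
universe defaulting to the genes appearing in any category) or labeled
`"Unknown"`.

### 5. Key driver analysis (`find_key_drivers`, `rank_across_networks`)

Within a directed gene network, a candidate gene's neighborhood (depth 1,
undirected by default — the natural reading of "neighbors"; both depth
and direction are configurable) is tested for enrichment of superset
genes with a one-sided hypergeometric test; the universe is the network's
nodes minus the candidate. Key drivers are calls at Bonferroni-corrected
p < 0.05 over the genes tested. Across networks, a gene's consistency is
\(N - 0.99\) (number of networks where it is a key driver, shifted so
that a single-network driver scores 0.01 and replication in two networks
dominates any single-network significance), its significance is
\(\mathrm{mean}(-\log_{10} p)\) over those networks, and the final rank
score is their product. This consistency-times-significance formula is
conventionally written with an unspecified log base; base 10 is used for
consistency with the enrichment score. For experimental validation-style questions,
`neighbor_set_enrichment` pools depth-2 neighborhoods of seed genes
across networks and tests a query gene list for over-representation
(fold = observed/expected with expected \(= |pool|\,|query|/universe\));
the gene universe behind such fold computations is never published with
the statistic and is therefore a required explicit argument. A consensus
edge filter (`consensus_edges`, default: edges in >30% of networks) is
provided for network construction and display; it is not part of the KDA
statistic. Bayesian network reconstruction itself is out of scope:
networks are inputs.

## The synthetic world (`sim_config`, `simulate_dataset`)

The generator's defaults state one coherent world:

| parameter | default | why |
|---|---|---|
| `n_snps`, `n_genes` | 10000, 1000 | ~10 eSNPs/gene, desk-scale |
| stages | 7 + 9 cohorts | the 16-cohort two-stage design |
| `n_gene_sets` | 100 (sizes 20–100) | pathway-like collection |
| planted set | `set001`, 50 genes | ≥150 background eSNPs at defaults |
| `signal_strength` | 0.2 | Beta(a,1) p-values for causal eSNPs |
| LD | blocks of 2 at r² = 0.8 | pruning rejects ~50% at r² ≥ 0.7 |
| networks | 2 × 1000 nodes | hub degree 30, 50% wired to the planted set |

Causal eSNPs are exactly the catalog eSNPs of planted-set member genes.
Their per-study p-values follow Beta(a, 1) — uniform at a = 1, left-skewed
below — and each causal SNP carries one effect direction shared across
studies so that signals replicate between stages. Null SNPs draw
independent uniform p-values and independent signs, which makes the
per-study and meta-analyzed null z-scores exactly N(0,1). At a = 1 causal
SNPs are generated *identically* to null SNPs, signs included: keeping a
shared sign with uniform p-values would correlate z-scores across studies
and silently de-calibrate the "pure null" world.

Effect sizes are synthesized by the inverse normal (\(|z| =
\Phi^{-1}(1-p/2)\), \(\beta = \pm|z|\cdot\mathrm{se}\)) so the
meta-analysis stage is fully exercised; standard errors are uniform on
[0.05, 0.2]. QC covariates are drawn inside the passing ranges: the QC
stage is exercised by dedicated fixtures, not by random attrition.
Networks are DAGs by construction (edges forward in a random topological
order with drivers first); planted hubs receive `hub_degree` out-edges,
half into the planted gene set, and all other nodes get Poisson(2)
background parents.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic allele-frequency spectra or genotypes, LD decay
(blocks are constant-r²), effect-size distributions of real complex-trait
loci (Beta(a,1) is a convenience law; real studies provide no generative
model to copy), correlated expression across tissues, scale-free network
topology, or gene sets with realistic redundancy structure. Green tests
establish that the *statistics* are calibrated and that planted structure
of stated strength is recovered; they do not certify power on real data.

## Numerical and design choices

* Exact vs. asymptotic K-S switch at n = 140; identical formulas in the R
  reference path and the compiled permutation engine, asserted equal in
  tests to 1e-12.
* Permutations shuffle with Fisher–Yates on R's RNG stream, so
  `set.seed()` makes entire pipeline runs byte-reproducible; every
  generator derives a distinct sub-seed from `sim_config(seed = )`.
* p-value underflow is clamped at 1e-300 before logarithms.
* Top-5% membership and LD-pruning order both break ties
  deterministically (p-value then SNP id; priority then SNP id).
* `permutation_fdr(n_perm = 1, permute = FALSE)` is the identity
  assignment and returns FDR 1 for every achieved score — a
  self-consistency check wired into the test suite.
* The null-calibration test world uses a genome-scale universe (20000
  genes for 2000 sets). In a small universe the sets overlap so heavily
  that their enrichment p-values are strongly positively dependent, and a
  pooled uniformity check rejects even though marginal calibration is
  exact (verified against disjoint sets); approximate independence is an
  assumption of that check, not of the method.
* Allele harmonization is by exact (allele1, allele2) string comparison;
  strand flips are out of scope for synthetic data.

## Known limitations

* The K-S p-value for set ranks treats the background as continuous;
  heavy ties in GWAS p-values (not produced by the generator) would make
  it more conservative.
* Whole-stratum trimming can leave a superset above the size limit when
  no stratum boundary coincides with it (see above); the per-gene mode
  trims exactly but needs an arbitrary intra-stratum order.
* FDR estimates below ~1/`n_perm` are reported as 0; ranking among the
  strongest sets should rely on scores, not on tied zero FDRs.
* `neighbor_set_enrichment` treats the neighbor pool as fixed; it does
  not propagate uncertainty in network structure.
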