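#' Kolmogorov-Smirnov enrichment of a SNP set for low GWAS p-values
#'
#' Ranks of the set members within the background GWAS p-value ordering are
#' converted to fractions in (0, 1] and tested against Uniform(0,1) with a
#' one-sample, one-sided K-S test (alternative: ranks smaller than
#' uniform). This statistic is sensitive to many weak signals. A two-sample
#' mode (`mode = "two.sample"`: set p-values against the p-values of the
#' background complement, via [stats::ks.test()]) is available.
#'
#' @param set_snps An [esnp_set()] or character vector of SNP ids; must be
#'   a subset of the background.
#' @param gwas_p Named numeric vector of GWAS p-values covering every
#'   background SNP.
#' @param background An [esnp_set()]; the null universe.
#' @param mode `"one.sample"` (default) or `"two.sample"`.
#' @return A single p-value. Sets with fewer than 2 SNPs return 1 with a
#'   warning.
#' @export
ks_enrichment <- function(set_snps, gwas_p, background,
                          mode = c("one.sample", "two.sample")) {
  mode <- match.arg(mode)
  set <- if (inherits(set_snps, "esnp_set")) set_snps$snp_ids
         else unique(as.character(set_snps))
  bg <- background$snp_ids
  if (!all(set %in% bg))
    stop("set SNPs must be a subset of the background", call. = FALSE)
  if (anyNA(gwas_p[bg]))
    stop("every background SNP needs a GWAS p-value", call. = FALSE)
  if (length(set) < 2L) {
    warning("SNP set smaller than 2; returning p = 1")
    return(1)
  }
  if (mode == "two.sample") {
    rest <- setdiff(bg, set)
    return(suppressWarnings(
      ks.test(gwas_p[set], gwas_p[rest], alternative = "greater")$p.value))
  }
  fr <- rank(gwas_p[bg], ties.method = "average") / length(bg)
  u <- fr[match(set, bg)]
  ks_p_upper(ks_stat_plus(u), length(u))
}

top_positions <- function(gwas_p, bg) {
  # position of each background SNP in the (p, snp_id) order; deterministic
  # tie-breaking so the top fraction is well defined
  ord <- order(gwas_p[bg], bg)
  pos <- integer(length(bg))
  pos[ord] <- seq_along(bg)
  pos
}

#' Fisher top-fraction enrichment of a SNP set
#'
#' Tests whether the set is over-represented among the top
#' `top_fraction` of background SNPs ranked by GWAS association strength
#' (smallest p-values; ties broken by SNP id). One-sided hypergeometric
#' upper-tail p-value for the 2x2 table set-membership x top-membership.
#' This statistic is sensitive to a few strong signals.
#'
#' @inheritParams ks_enrichment
#' @param top_fraction Fraction of the background taken as the top set;
#'   its size is `ceiling(top_fraction * N)`.
#' @return A single p-value.
#' @export
fisher_top_enrichment <- function(set_snps, gwas_p, background,
                                  top_fraction = 0.05) {
  set <- if (inherits(set_snps, "esnp_set")) set_snps$snp_ids
         else unique(as.character(set_snps))
  bg <- background$snp_ids
  if (!all(set %in% bg))
    stop("set SNPs must be a subset of the background", call. = FALSE)
  N <- length(bg)
  K <- as.integer(ceiling(top_fraction * N))
  pos <- top_positions(gwas_p, bg)
  hits <- sum(pos[match(set, bg)] <= K)
  phyper(hits - 1, K, N - K, length(set), lower.tail = FALSE)
}

#' Combined enrichment score
#'
#' `score = mean(-log10 p_KS, -log10 p_Fisher)`. Zero p-values are clamped
#' to 1e-300 with a warning before the log transform.
#'
#' @param p_ks,p_fisher P-values in (0, 1] (vectorized).
#' @return Non-negative numeric score(s).
#' @examples
#' enrichment_score(1e-10, 1e-12)  # 11
#' @export
enrichment_score <- function(p_ks, p_fisher) {
  if (any(p_ks <= 0) || any(p_fisher <= 0))
    warning("p-value of 0 clamped to 1e-300")
  p_ks <- pmax(p_ks, 1e-300)
  p_fisher <- pmax(p_fisher, 1e-300)
  (-log10(p_ks) - log10(p_fisher)) / 2
}

# Vectorized observed scores for a list of sets over one background.
# Shares ks_p_upper()/top-fraction conventions with the public per-set
# operations; equivalence is asserted in the test suite. Sets with fewer
# than 2 background eSNPs are reported as p = 1, score = 0.
ssea_scores <- function(set_idx, rank_avg, pos, n_top) {
  N <- length(rank_avg)
  out <- lapply(set_idx, function(idx) {
    k <- length(idx)
    if (k < 2L) return(c(1, 1, 0))
    u <- sort(rank_avg[idx] / N)
    dplus <- max(seq_len(k) / k - u)
    p_ks <- ks_p_upper(dplus, k)
    hits <- sum(pos[idx] <= n_top)
    p_f <- phyper(hits - 1, n_top, N - n_top, k, lower.tail = FALSE)
    c(p_ks, p_f,
      (-log10(max(p_ks, 1e-300)) - log10(max(p_f, 1e-300))) / 2)
  })
  m <- do.call(rbind, out)
  data.table(p_ks = m[, 1], p_fisher = m[, 2], score = m[, 3])
}

#' Permutation-based FDR for enrichment scores
#'
#' Randomly permutes the assignment of GWAS p-values to background eSNPs
#' (set memberships and the pruned background stay intact), recomputes all
#' set scores per permutation, and estimates, for each observed score `s`,
#' `FDR(s) = mean over permutations of (# permuted scores >= s)` divided by
#' `(# observed scores >= s)`, capped at 1. Raw FDRs are made monotone
#' non-increasing in the score by a running maximum from the top score
#' downwards (a conservative correction of sampling noise).
#'
#' @param set_snps_list Named list of SNP-id vectors (or [esnp_set()]s),
#'   each a subset of the background.
#' @param gwas_p Named numeric vector of p-values for every background SNP.
#' @param background An [esnp_set()].
#' @param n_perm Number of permutations (>= 1).
#' @param top_fraction Passed to the Fisher component.
#' @param permute If `FALSE`, the single "permutation" is the identity
#'   assignment, in which case every achieved score has FDR 1 (used as a
#'   self-consistency check).
#' @return A list with `observed` (named score vector), `fdr` (named,
#'   monotone), and `n_perm`.
#' @export
permutation_fdr <- function(set_snps_list, gwas_p, background,
                            n_perm = 1000L, top_fraction = 0.05,
                            permute = TRUE) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  bg <- background$snp_ids
  N <- length(bg)
  sets <- lapply(set_snps_list, function(s)
    if (inherits(s, "esnp_set")) s$snp_ids else unique(as.character(s)))
  # one match over the concatenation (per-set match would re-hash bg)
  lens <- vapply(sets, length, 1L)
  flat <- match(unlist(sets, use.names = FALSE), bg)
  if (anyNA(flat)) stop("set SNPs must be a subset of the background",
                        call. = FALSE)
  idx <- split(flat, factor(rep(seq_along(sets), lens),
                            levels = seq_along(sets)))
  rank_avg <- rank(gwas_p[bg], ties.method = "average")
  pos <- top_positions(gwas_p, bg)
  n_top <- as.integer(ceiling(top_fraction * N))
  set_idx0 <- as.integer(unlist(idx, use.names = FALSE) - 1L)
  set_len <- vapply(idx, length, 1L)

  observed <- as.vector(cpp_perm_scores(rank_avg, pos, set_idx0, set_len,
                                        n_top, 1L, FALSE))
  perm <- cpp_perm_scores(rank_avg, pos, set_idx0, set_len,
                          n_top, as.integer(n_perm), permute)
  pooled <- sort(as.vector(perm))
  obs_sorted <- sort(observed)
  n_perm_ge <- length(pooled) -
    findInterval(observed, pooled, left.open = TRUE)
  n_obs_ge <- length(obs_sorted) -
    findInterval(observed, obs_sorted, left.open = TRUE)
  fdr <- pmin(1, (n_perm_ge / n_perm) / n_obs_ge)
  ord <- order(observed, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  names(observed) <- names(fdr) <- names(set_snps_list)
  list(observed = observed, fdr = fdr, n_perm = n_perm)
}

#' Two-stage significance rule
#'
#' A gene set is called significant when its permutation FDR is below 20%
#' in both independent stages and below 5% in the combined analysis (all
#' strict inequalities). Because the stages are independent, the two 20%
#' thresholds alone already bound the joint FDR by 20% x 20% = 4%.
#'
#' @param fdr1,fdr2,fdr12 FDR values in `[0, 1]` (vectorized).
#' @param stage_threshold,combined_threshold The per-stage and combined
#'   cutoffs (defaults 0.20 and 0.05).
#' @return Logical vector.
#' @export
multi_stage_call <- function(fdr1, fdr2, fdr12,
                             stage_threshold = 0.20,
                             combined_threshold = 0.05) {
  fdr1 < stage_threshold & fdr2 < stage_threshold &
    fdr12 < combined_threshold
}

#' SNP-set enrichment analysis of gene sets against GWAS meta-analyses
#'
#' For each tissue, builds the LD-pruned eSNP background, maps every gene
#' set to its eSNP set, scores enrichment of low GWAS p-values (K-S +
#' Fisher top-fraction) for the Stage 1, Stage 2, and combined
#' meta-analyses, estimates permutation FDRs per stage, and applies the
#' two-stage significance rule. The reported `p_ks`, `p_fisher` and
#' `score` come from the combined Stage 1+2 analysis.
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param records eSNP record table.
#' @param ld LD table.
#' @param meta Named list of meta-analysis tables `stage1`, `stage2`,
#'   `combined` (each with columns `snp`, `pvalue`), e.g. from
#'   [run_stage_meta()].
#' @param tissues Character vector of tissues to analyze (`"all"` pools
#'   every tissue).
#' @param n_perm Permutations per stage and tissue.
#' @param seed Optional integer seed (set once at entry).
#' @param top_fraction,r2_max Passed through to the Fisher test and LD
#'   pruning.
#' @return A `data.table` with one row per (gene set, tissue): `set_name`,
#'   `tissue`, `n_esnps`, `p_ks`, `p_fisher`, `score`, `fdr_stage1`,
#'   `fdr_stage2`, `fdr_combined`, `significant`.
#' @export
run_ssea <- function(gene_sets, records, ld, meta, tissues = "all",
                     n_perm = 1000L, seed = NULL, top_fraction = 0.05,
                     r2_max = 0.7) {
  stages <- c("stage1", "stage2", "combined")
  if (!all(stages %in% names(meta)))
    stop("missing stage table(s): ",
         paste(setdiff(stages, names(meta)), collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  records <- as.data.table(records)
  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    bg <- build_background(records, ld, tissue, r2_max)
    covered <- Reduce(intersect, lapply(meta[stages], function(m) m$snp))
    missing <- setdiff(bg$snp_ids, covered)
    if (length(missing) > 0L) {
      warning(length(missing), " background eSNP(s) lack meta-analysis ",
              "p-values and were dropped from the '", tissue,
              "' background")
      bg$snp_ids <- setdiff(bg$snp_ids, missing)
    }
    # fast equivalent of map_gene_set() over many sets: one gene->SNP
    # index, membership restricted to the pruned background
    keep_rec <- if (identical(tissue, "all")) rep(TRUE, nrow(records))
                else records$tissue == tissue
    sl <- records[keep_rec, ]
    in_bg <- sl$snp %in% bg$snp_ids
    lookup <- split(sl$snp[in_bg], sl$gene[in_bg])
    sets <- lapply(gene_sets, function(gs)
      sort(unique(unlist(lookup[unique(as.character(gs))],
                         use.names = FALSE))))
    fdr <- list()
    sc <- NULL
    for (st in stages) {
      m <- meta[[st]]
      pv <- setNames(m$pvalue, m$snp)[bg$snp_ids]
      pf <- permutation_fdr(sets, pv, bg, n_perm = n_perm,
                            top_fraction = top_fraction)
      fdr[[st]] <- unname(pf$fdr)
      if (st == "combined") {
        rank_avg <- rank(pv, ties.method = "average")
        pos <- top_positions(pv, bg$snp_ids)
        n_top <- as.integer(ceiling(top_fraction * length(bg$snp_ids)))
        lens <- vapply(sets, length, 1L)
        idx <- split(match(unlist(sets, use.names = FALSE), bg$snp_ids),
                     factor(rep(seq_along(sets), lens),
                            levels = seq_along(sets)))
        sc <- ssea_scores(idx, rank_avg, pos, n_top)
      }
    }
    out[[ti]] <- data.table(
      set_name = names(gene_sets), tissue = tissue,
      n_esnps = vapply(sets, length, 1L),
      p_ks = sc$p_ks, p_fisher = sc$p_fisher, score = sc$score,
      fdr_stage1 = fdr$stage1, fdr_stage2 = fdr$stage2,
      fdr_combined = fdr$combined,
      significant = multi_stage_call(fdr$stage1, fdr$stage2,
                                     fdr$combined))
  }
  rbindlist(out)
}
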