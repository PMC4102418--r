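#' Lightweight eSNP set container
#'
#' @param name Set label (gene-set name or `"background"`).
#' @param tissue Tissue label (`"all"` pools every tissue).
#' @param snp_ids Character vector of unique SNP identifiers.
#' @return An object of class `esnp_set`.
#' @export
esnp_set <- function(name, tissue, snp_ids) {
  structure(list(name = name, tissue = tissue,
                 snp_ids = unique(as.character(snp_ids))),
            class = "esnp_set")
}

#' @export
print.esnp_set <- function(x, ...) {
  cat("esnp_set '", x$name, "' (", x$tissue, "): ",
      length(x$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}

#' Rank-scale expression p-values within each eQTL study
#'
#' Because the eQTL studies differ in sample size and design, raw
#' expression p-values are not comparable across studies. Within each
#' study, records are ranked by ascending `expr_pvalue` (ties share the
#' mean rank) and the ranks are scaled to `[0, 1]` as `(rank - 1)/(n - 1)`
#' (0 for a single-record study) before studies are pooled.
#'
#' @param records eSNP record table with columns `snp`, `gene`, `tissue`,
#'   `study`, `expr_pvalue`.
#' @return The same table with a `scaled_rank` column added.
#' @export
rank_scale <- function(records) {
  records <- as.data.table(records)
  if (!"expr_pvalue" %in% names(records))
    stop("format error: missing required column: expr_pvalue",
         call. = FALSE)
  records[, scaled_rank := {
    r <- rank(expr_pvalue, ties.method = "average")
    if (.N == 1L) 0 else (r - 1) / (.N - 1)
  }, by = study]
  records[]
}

#' Greedy LD pruning of pooled eSNPs
#'
#' Removes eSNPs in strong linkage disequilibrium while preferentially
#' keeping those with the strongest expression association. SNP priority is
#' the minimum `scaled_rank` across all of a SNP's records (a SNP can be an
#' eSNP for several genes and studies); SNPs are visited in ascending
#' priority (ties broken lexicographically by SNP id) and kept only if no
#' already-kept SNP is linked to them at `r2 >= r2_max`. The output is an
#' independent set of the `r2 >= r2_max` graph.
#'
#' @param records eSNP records with `scaled_rank` (see [rank_scale()]).
#' @param ld LD table with columns `snp_a`, `snp_b`, `r2` (one row per
#'   unordered pair; lookup is symmetric). Pairs naming SNPs absent from
#'   `records` are ignored with a warning.
#' @param r2_max LD threshold: linked pairs at `r2 >= r2_max` conflict
#'   (default 0.7, i.e. SNPs are retained only while pairwise `r2 < 0.7`).
#' @return Sorted character vector of retained SNP ids.
#' @export
ld_prune <- function(records, ld, r2_max = 0.7) {
  records <- as.data.table(records)
  if (!"scaled_rank" %in% names(records))
    stop("run rank_scale() before ld_prune()", call. = FALSE)
  prio <- records[, .(priority = min(scaled_rank)), by = snp]
  snps <- prio$snp
  ld <- as.data.table(ld)
  if (nrow(ld) > 0L) {
    known <- ld$snp_a %in% snps & ld$snp_b %in% snps
    if (!all(known)) {
      warning(sum(!known), " LD pair(s) reference unknown SNPs; ignored")
      ld <- ld[known, ]
    }
    ld <- ld[ld$r2 >= r2_max, ]
  }
  ord <- order(prio$priority, prio$snp)
  if (nrow(ld) == 0L) return(sort(snps))
  ai <- match(ld$snp_a, snps); bi <- match(ld$snp_b, snps)
  # symmetric CSR adjacency of the conflict graph
  deg <- tabulate(c(ai, bi), nbins = length(snps))
  adj_start <- c(0L, cumsum(deg))
  edge_ord <- order(c(ai, bi))
  adj_idx <- c(bi, ai)[edge_ord] - 1L
  keep <- cpp_ld_prune(ord - 1L, adj_start, adj_idx)
  sort(snps[keep])
}

#' Build the LD-pruned eSNP background of a tissue
#'
#' The background is the null universe for SNP-set enrichment: all eSNPs of
#' a tissue (or the union over every tissue for `tissue = "all"`),
#' rank-scaled within study and LD-pruned.
#'
#' @param records eSNP record table (see [simulate_esnp_catalog()] for the
#'   columns).
#' @param ld LD table (`snp_a`, `snp_b`, `r2`).
#' @param tissue Tissue label, or `"all"` to pool every tissue.
#' @param r2_max LD pruning threshold passed to [ld_prune()].
#' @return An [esnp_set()] named `"background"`.
#' @export
build_background <- function(records, ld, tissue = "all", r2_max = 0.7) {
  records <- as.data.table(records)
  keep <- if (identical(tissue, "all")) rep(TRUE, nrow(records))
          else records$tissue == tissue  # evaluated outside [ ] on purpose
  sl <- records[keep, ]
  if (nrow(sl) == 0L)
    stop("no eSNP records for tissue '", tissue, "'", call. = FALSE)
  sl <- rank_scale(copy(sl))
  # a tissue background only consults LD among its own eSNPs; pairs
  # involving other tissues' SNPs are irrelevant here, not suspicious
  ld <- as.data.table(ld)
  ld <- ld[ld$snp_a %in% sl$snp & ld$snp_b %in% sl$snp, ]
  esnp_set("background", tissue, ld_prune(sl, ld, r2_max))
}

#' Map a gene set to its eSNP set within a tissue background
#'
#' The eSNP set of a gene set is the subset of the tissue background whose
#' records target a member gene in that tissue. Gene ids absent from the
#' catalog are silently ignored but counted in the `coverage` attribute
#' (fraction of member genes with at least one eSNP record).
#'
#' @param gene_set Character vector of gene ids (or a single element of a
#'   [read_gmt()] list).
#' @param records eSNP record table.
#' @param background An [esnp_set()] built by [build_background()] for the
#'   same tissue.
#' @return An [esnp_set()]; empty sets are allowed and flagged with a
#'   warning.
#' @export
map_gene_set <- function(gene_set, records, background) {
  genes <- unique(as.character(gene_set))
  records <- as.data.table(records)
  sl <- if (identical(background$tissue, "all")) records
        else records[records$tissue == background$tissue, ]
  hit <- sl$gene %in% genes
  snps <- intersect(background$snp_ids, unique(sl$snp[hit]))
  out <- esnp_set("gene_set", background$tissue, snps)
  attr(out, "coverage") <- mean(genes %in% sl$gene)
  if (length(snps) == 0L)
    warning("gene set maps to zero background eSNPs")
  out
}
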