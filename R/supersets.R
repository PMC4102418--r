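#' Symmetric overlap ratio between two gene sets
#'
#' For sets A and B, `r_ab = |A∩B|/|A|`, `r_ba = |A∩B|/|B|`, and the
#' symmetric ratio is the geometric mean `r = sqrt(r_ab * r_ba)`. The
#' geometric mean is small whenever the set sizes are very different, which
#' discourages the merging of nested sets.
#'
#' @param genes_a,genes_b Non-empty character vectors of gene ids.
#' @return A list with `r_ab`, `r_ba`, `r`, `d = 1 - r`, `n_shared`.
#' @examples
#' overlap_ratio(paste0("g", 1:50), paste0("g", 31:230))$r  # sqrt(.4*.1)
#' @export
overlap_ratio <- function(genes_a, genes_b) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  if (length(genes_a) == 0L || length(genes_b) == 0L)
    stop("gene sets must be non-empty", call. = FALSE)
  n <- length(intersect(genes_a, genes_b))
  r_ab <- n / length(genes_a)
  r_ba <- n / length(genes_b)
  r <- sqrt(r_ab * r_ba)
  list(r_ab = r_ab, r_ba = r_ba, r = r, d = 1 - r, n_shared = n)
}

#' Fisher significance of a gene-set overlap
#'
#' One-sided hypergeometric upper-tail p-value for observing at least the
#' realized intersection, with Bonferroni correction over `m_tests`
#' pairwise tests.
#'
#' @inheritParams overlap_ratio
#' @param universe_size Size of the gene universe (must be at least
#'   `|A ∪ B|`).
#' @param m_tests Number of pairwise tests for the Bonferroni correction.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list with `p_overlap` and `significant_overlap`.
#' @export
overlap_significance <- function(genes_a, genes_b, universe_size,
                                 m_tests = 1L, alpha = 0.05) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  if (universe_size < length(union(genes_a, genes_b)))
    stop("universe smaller than the union of the two sets", call. = FALSE)
  n <- length(intersect(genes_a, genes_b))
  p <- phyper(n - 1, length(genes_a), universe_size - length(genes_a),
              length(genes_b), lower.tail = FALSE)
  list(p_overlap = p, significant_overlap = p < alpha / m_tests)
}

#' Cluster gene sets by significant overlap
#'
#' Non-significant overlaps are zeroed; clusters are the connected
#' components of the graph whose edges join pairs with `r > 0` and a
#' significant Fisher overlap. (This equals single-linkage hierarchical
#' clustering of the distances `d = 1 - r` cut at any nonzero overlap.)
#' Singletons are allowed.
#'
#' @param set_names Character vector of all candidate set labels.
#' @param overlaps `data.table`/data.frame with columns `set_a`, `set_b`,
#'   `r`, `significant_overlap` covering the tested pairs.
#' @return A list of character vectors (the clusters).
#' @export
cluster_overlaps <- function(set_names, overlaps) {
  overlaps <- as.data.table(overlaps)
  keep <- overlaps$r > 0 & overlaps$significant_overlap
  g <- igraph::graph_from_data_frame(
    overlaps[keep, c("set_a", "set_b")], directed = FALSE,
    vertices = data.frame(name = set_names))
  comp <- igraph::components(g)
  unname(split(set_names, comp$membership))
}

#' Trim a merged superset to its core genes
#'
#' Share counts record in how many constituent gene sets each gene occurs.
#' Whole strata of the least-shared genes are removed, lowest count first,
#' while the remaining size stays at or above `size_limit`; the trimming
#' stops before a removal that would drop below the limit. A per-gene mode
#' (`mode = "per_gene"`, ties broken lexicographically by gene id) removes
#' genes one at a time until the size equals the limit.
#'
#' @param genes Character vector of merged genes.
#' @param share_counts Integer vector (parallel to `genes`) of constituent
#'   set counts, all >= 1.
#' @param size_limit Target core size (default 200).
#' @param mode `"stratum"` (default) or `"per_gene"`.
#' @return Character vector of retained core genes.
#' @export
trim_core <- function(genes, share_counts, size_limit = 200L,
                      mode = c("stratum", "per_gene")) {
  mode <- match.arg(mode)
  stopifnot(length(genes) == length(share_counts), all(share_counts >= 1))
  if (length(genes) <= size_limit) return(genes)
  if (mode == "per_gene") {
    ord <- order(share_counts, genes)
    drop_n <- length(genes) - size_limit
    return(genes[-ord[seq_len(drop_n)]])
  }
  repeat {
    if (length(genes) <= size_limit) break
    m <- min(share_counts)
    stratum <- share_counts == m
    if (length(genes) - sum(stratum) < size_limit) break
    genes <- genes[!stratum]
    share_counts <- share_counts[!stratum]
  }
  genes
}

superset_overlap_table <- function(sets, universe_size, alpha = 0.05) {
  nms <- names(sets)
  if (length(nms) < 2L)
    return(data.table(set_a = character(), set_b = character(),
                      r = numeric(), p_overlap = numeric(),
                      significant_overlap = logical()))
  pr <- combn(nms, 2L)
  m_tests <- ncol(pr)
  rows <- lapply(seq_len(m_tests), function(i) {
    a <- pr[1, i]; b <- pr[2, i]
    ov <- overlap_ratio(sets[[a]], sets[[b]])
    sig <- overlap_significance(sets[[a]], sets[[b]], universe_size,
                                m_tests = m_tests, alpha = alpha)
    data.table(set_a = a, set_b = b, r = ov$r, p_overlap = sig$p_overlap,
               significant_overlap = sig$significant_overlap)
  })
  rbindlist(rows)
}

#' Merge overlapping gene sets into non-overlapping supersets
#'
#' Runs `n_rounds` rounds of overlap testing, single-linkage clustering of
#' significantly overlapping sets, merging, and core trimming to at most
#' `size_limit` genes. Share counts used for trimming always refer to the
#' original constituent sets (provenance is carried across rounds). After
#' the final round every pairwise overlap ratio is expected to be below
#' `max_overlap`; if not, a warning is raised (the procedure does not loop
#' adaptively).
#'
#' @param significant_sets Named list of character vectors (the gene sets
#'   to merge, e.g. the SSEA-significant sets).
#' @param universe_size Gene-universe size for the Fisher overlap tests.
#' @param size_limit Maximum superset size after trimming (default 200).
#' @param max_overlap Maximum tolerated pairwise overlap ratio between
#'   final supersets (default 0.20).
#' @param n_rounds Number of merge/trim rounds (default 2).
#' @param alpha Family-wise level of the overlap tests.
#' @param trim_mode Passed to [trim_core()].
#' @return A list with `supersets` (named list of gene vectors),
#'   `constituents` (named list mapping each superset to its original
#'   input sets), and `overlaps` (final all-pairs overlap table).
#' @export
build_supersets <- function(significant_sets, universe_size,
                            size_limit = 200L, max_overlap = 0.20,
                            n_rounds = 2L, alpha = 0.05,
                            trim_mode = "stratum") {
  if (length(significant_sets) < 1L)
    stop("at least one input gene set is required", call. = FALSE)
  sets <- lapply(significant_sets, unique)
  constituents <- setNames(as.list(names(sets)), names(sets))
  originals <- sets
  next_id <- 1L

  for (round in seq_len(n_rounds)) {
    if (length(sets) < 2L) break
    ov <- superset_overlap_table(sets, universe_size, alpha)
    clusters <- cluster_overlaps(names(sets), ov)
    if (all(vapply(clusters, length, 1L) == 1L)) break
    new_sets <- list(); new_const <- list()
    for (cl in clusters) {
      const <- sort(unique(unlist(constituents[cl], use.names = FALSE)))
      if (length(cl) == 1L) {
        nm <- cl
        genes <- sets[[cl]]
      } else {
        nm <- sprintf("superset%03d", next_id)
        next_id <- next_id + 1L
        merged <- sort(unique(unlist(sets[cl], use.names = FALSE)))
        shares <- vapply(merged, function(g)
          sum(vapply(originals[const], function(s) g %in% s, NA)), 1L)
        genes <- trim_core(merged, shares, size_limit, mode = trim_mode)
      }
      new_sets[[nm]] <- genes
      new_const[[nm]] <- const
    }
    sets <- new_sets
    constituents <- new_const
  }

  final_ov <- superset_overlap_table(sets, universe_size, alpha)
  if (nrow(final_ov) > 0L && max(final_ov$r) >= max_overlap)
    warning("maximum pairwise overlap ratio ",
            signif(max(final_ov$r), 3), " still >= ", max_overlap,
            " after ", n_rounds, " round(s)")
  list(supersets = sets, constituents = constituents, overlaps = final_ov)
}

#' Annotate a superset against reference functional categories
#'
#' One-sided Fisher over-representation test of the superset genes in each
#' reference category, Bonferroni-corrected over the number of categories.
#' Significant category names (sorted by p-value) become the annotation;
#' with none, the superset is labeled `"Unknown"`.
#'
#' @param superset_genes Character vector of superset member genes.
#' @param reference_categories Named list of character vectors.
#' @param universe_size Gene universe for the tests; defaults to the number
#'   of distinct genes appearing in any reference category or the superset.
#' @param alpha Family-wise level (default 0.05).
#' @return A list with `annotation` (character vector, or `"Unknown"`) and
#'   `p_values` (named, all categories).
#' @export
annotate_superset <- function(superset_genes, reference_categories,
                              universe_size = NULL, alpha = 0.05) {
  if (length(reference_categories) == 0L)
    stop("reference categories must be non-empty", call. = FALSE)
  superset_genes <- unique(superset_genes)
  if (is.null(universe_size))
    universe_size <- length(unique(c(
      unlist(reference_categories, use.names = FALSE), superset_genes)))
  m <- length(reference_categories)
  p <- vapply(reference_categories, function(cat) {
    cat <- unique(cat)
    n <- length(intersect(superset_genes, cat))
    phyper(n - 1, length(cat), universe_size - length(cat),
           length(superset_genes), lower.tail = FALSE)
  }, 1.0)
  sig <- names(p)[p < alpha / m]
  list(annotation = if (length(sig) == 0L) "Unknown"
       else sig[order(p[sig])],
       p_values = p)
}
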