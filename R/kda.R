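#' Build a gene network from an edge list
#'
#' @param edges Data frame with two columns (source, target gene ids).
#'   Duplicate edges and self-loops are dropped.
#' @param network_id Label stored as a graph attribute.
#' @param directed Directed graph (default `TRUE`).
#' @return An `igraph` graph.
#' @export
as_gene_network <- function(edges, network_id = "network", directed = TRUE) {
  edges <- unique(as.data.frame(edges)[, 1:2])
  edges <- edges[edges[[1]] != edges[[2]], ]
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  igraph::set_graph_attr(g, "network_id", network_id)
}

network_label <- function(g, default = "network") {
  id <- igraph::graph_attr(g, "network_id")
  if (is.null(id)) default else as.character(id)
}

ego_mode <- function(direction) {
  switch(direction, out = "out", `in` = "in", undirected = "all",
         stop("direction must be 'out', 'in' or 'undirected'",
              call. = FALSE))
}

#' Depth-limited network neighborhood of a gene
#'
#' All genes reachable from `gene` within `depth` edges under the given
#' edge direction, excluding the seed gene itself.
#'
#' @param network An `igraph` graph.
#' @param gene Gene id; must be a node of the network.
#' @param depth Maximum number of edges (default 1).
#' @param direction `"undirected"` (default), `"out"`, or `"in"`.
#' @return Character vector of neighbor gene ids.
#' @export
neighborhood <- function(network, gene, depth = 1L,
                         direction = "undirected") {
  if (!gene %in% igraph::V(network)$name)
    stop("gene '", gene, "' is not in the network", call. = FALSE)
  nb <- igraph::ego(network, order = depth, nodes = gene,
                    mode = ego_mode(direction))[[1]]
  setdiff(nb$name, gene)
}

#' Neighborhood enrichment test for a candidate key driver
#'
#' Tests whether the candidate's depth-limited neighborhood is enriched
#' for members of a disease gene set: one-sided hypergeometric upper-tail
#' p-value for the overlap given the neighborhood size, the number of
#' in-network set genes, and the network size minus the candidate (the
#' candidate itself is excluded from the universe and the set margin).
#'
#' @param network An `igraph` graph.
#' @param superset_genes Character vector of disease-set gene ids.
#' @param candidate Candidate gene id.
#' @param depth,direction Neighborhood definition (see [neighborhood()]).
#' @return A list with `n_neighbors`, `n_hits`, `p_kda`. An empty
#'   neighborhood returns `p_kda = 1` with a warning.
#' @export
key_driver_test <- function(network, superset_genes, candidate,
                            depth = 1L, direction = "undirected") {
  nb <- neighborhood(network, candidate, depth, direction)
  nodes <- igraph::V(network)$name
  set_in <- setdiff(intersect(superset_genes, nodes), candidate)
  n_hits <- length(intersect(nb, set_in))
  if (length(nb) == 0L) {
    warning("candidate '", candidate, "' has an empty neighborhood")
    return(list(n_neighbors = 0L, n_hits = 0L, p_kda = 1))
  }
  N <- length(nodes) - 1L
  K <- length(set_in)
  p <- phyper(n_hits - 1, K, N - K, length(nb), lower.tail = FALSE)
  list(n_neighbors = length(nb), n_hits = n_hits, p_kda = p)
}

#' Key driver detection in one network
#'
#' Every network gene is tested with [key_driver_test()]; genes with a
#' Bonferroni-corrected p-value below `alpha` (correction over the number
#' of genes tested) are flagged as key drivers. Statistics for all genes
#' are returned.
#'
#' @inheritParams key_driver_test
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `data.table` with columns `gene_id`, `network_id`,
#'   `n_neighbors`, `n_hits`, `p_kda`, `is_key_driver`.
#' @export
find_key_drivers <- function(network, superset_genes, depth = 1L,
                             direction = "undirected", alpha = 0.05) {
  nodes <- igraph::V(network)$name
  if (length(nodes) == 0L) stop("network is empty", call. = FALSE)
  nbs <- igraph::ego(network, order = depth, mode = ego_mode(direction))
  in_set <- nodes %in% superset_genes
  n_set <- sum(in_set)
  N <- length(nodes) - 1L
  set_env <- new.env(hash = TRUE, parent = emptyenv())
  for (g in nodes[in_set]) assign(g, TRUE, envir = set_env)
  stats <- vapply(seq_along(nodes), function(i) {
    nb <- setdiff(nbs[[i]]$name, nodes[i])
    hits <- sum(vapply(nb, exists, NA, envir = set_env, inherits = FALSE))
    K <- n_set - in_set[i]
    p <- if (length(nb) == 0L) 1
         else phyper(hits - 1, K, N - K, length(nb), lower.tail = FALSE)
    c(length(nb), hits, p)
  }, numeric(3))
  out <- data.table(
    gene_id = nodes, network_id = network_label(network),
    n_neighbors = as.integer(stats[1, ]), n_hits = as.integer(stats[2, ]),
    p_kda = stats[3, ])
  out[, is_key_driver := p_kda < alpha / length(nodes)]
  setorder(out, p_kda, gene_id)
  out[]
}

#' Rank key drivers across networks
#'
#' For each gene flagged as a key driver in at least one network: `N` is
#' the number of networks where it is a key driver, consistency is
#' `N - 0.99` (strongly favoring drivers replicated in at least two
#' networks), significance is `mean(-log10 p)` over those networks, and
#' the rank score is their product. Output is sorted by descending rank
#' score; the ordering is invariant to the input order of networks.
#'
#' @param results List of [find_key_drivers()] tables (one per network).
#' @return A `data.table` with columns `gene_id`, `N`, `consistency`,
#'   `significance`, `rank_score`.
#' @examples
#' # N = 2 with p = 1e-4 and 1e-6: (2 - 0.99) * mean(4, 6) = 5.05
#' @export
rank_across_networks <- function(results) {
  if (length(results) < 1L) stop("need results from >= 1 network",
                                 call. = FALSE)
  all_res <- rbindlist(results)
  kd <- all_res[all_res$is_key_driver, ]
  if (nrow(kd) == 0L)
    return(data.table(gene_id = character(), N = integer(),
                      consistency = numeric(), significance = numeric(),
                      rank_score = numeric()))
  out <- kd[, .(N = .N,
                significance = mean(-log10(pmax(p_kda, 1e-300)))),
            by = gene_id]
  out[, consistency := N - 0.99]
  out[, rank_score := consistency * significance]
  setorder(out, -rank_score, gene_id)
  out[, c("gene_id", "N", "consistency", "significance", "rank_score"),
      with = FALSE]
}

#' Enrichment of a query gene list among multi-network seed neighborhoods
#'
#' Builds the pool of genes that are neighbors within `depth` edges of any
#' seed gene in at least `min_networks` of the supplied networks (seeds
#' themselves excluded), then tests whether the query list is
#' over-represented in that pool: `expected = |pool| * |query| /
#' universe_size`, `fold = observed / expected`, and a one-sided Fisher
#' (hypergeometric upper-tail) p-value. This is the statistic used to
#' check that experimentally perturbed genes concentrate around key
#' drivers.
#'
#' @param networks List of `igraph` graphs.
#' @param seed_genes Character vector of seed (key driver) gene ids; must
#'   be present in at least one network.
#' @param query_genes Character vector of query gene ids (e.g.
#'   differentially expressed genes).
#' @param universe_size Total number of genes in the universe the query
#'   and pool are drawn from (an explicit, required parameter).
#' @param depth Neighborhood depth (default 2).
#' @param min_networks Minimum number of networks a gene must neighbor a
#'   seed in to enter the pool (default 1).
#' @param direction Passed to [neighborhood()].
#' @return A list with `n_neighbors`, `observed`, `expected`, `fold`, `p`.
#' @export
neighbor_set_enrichment <- function(networks, seed_genes, query_genes,
                                    universe_size, depth = 2L,
                                    min_networks = 1L,
                                    direction = "undirected") {
  if (!any(seed_genes %in% unlist(lapply(networks, function(g)
    igraph::V(g)$name))))
    stop("no seed gene is present in any network", call. = FALSE)
  query_genes <- unique(query_genes)
  per_network <- lapply(networks, function(g) {
    present <- intersect(seed_genes, igraph::V(g)$name)
    if (length(present) == 0L) return(character())
    nb <- unique(unlist(lapply(present, function(s)
      neighborhood(g, s, depth, direction)), use.names = FALSE))
    setdiff(nb, seed_genes)
  })
  counts <- table(unlist(per_network, use.names = FALSE))
  pool <- names(counts)[counts >= min_networks]
  if (universe_size < length(union(pool, query_genes)))
    stop("universe smaller than the union of pool and query",
         call. = FALSE)
  observed <- length(intersect(pool, query_genes))
  expected <- length(pool) * length(query_genes) / universe_size
  p <- if (length(pool) == 0L) 1 else
    phyper(observed - 1, length(query_genes),
           universe_size - length(query_genes), length(pool),
           lower.tail = FALSE)
  list(n_neighbors = length(pool), observed = observed,
       expected = expected,
       fold = if (expected > 0) observed / expected else NA_real_,
       p = p)
}

#' Consensus edges across networks
#'
#' Utility filter returning the edges present in at least `min_fraction`
#' of the supplied networks (or at least `min_count` networks if given).
#' Intended for visualization and consensus-network construction; it is
#' not part of the key-driver statistic.
#'
#' @param networks List of `igraph` graphs.
#' @param min_fraction Minimum fraction of networks an edge must appear in
#'   (default 0.3).
#' @param min_count Optional absolute count overriding `min_fraction`.
#' @return A `data.table` with columns `source`, `target`, `n_networks`.
#' @export
consensus_edges <- function(networks, min_fraction = 0.3,
                            min_count = NULL) {
  edges <- rbindlist(lapply(networks, function(g) {
    el <- unique(igraph::as_data_frame(g, what = "edges")[, 1:2])
    setnames(as.data.table(el), c("source", "target"))
  }))
  counts <- edges[, .(n_networks = .N), by = c("source", "target")]
  thr <- if (is.null(min_count)) min_fraction * length(networks)
         else min_count
  counts[counts$n_networks >= thr, ]
}
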