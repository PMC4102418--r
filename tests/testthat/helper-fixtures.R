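# Shared fixtures and independent oracles, all built in code.

# Small but complete simulation world for unit tests.
small_config <- function(...) {
  defaults <- list(
    n_snps = 2000L, n_genes = 200L, n_gene_sets = 20L,
    set_size_range = c(10L, 30L), planted_set_size = 15L,
    network_n_nodes = 150L, hub_degree = 20L, seed = 42L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Brute-force hypergeometric upper-tail oracle: P(X >= x) for
# X ~ Hypergeom(N, K, n), summed term by term from binomial coefficients.
hyper_tail <- function(x, K, n, N) {
  hi <- min(K, n)
  if (x > hi) return(0)
  j <- max(x, 0):hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Log-space variant for margins where choose() overflows.
hyper_tail_log <- function(x, K, n, N) {
  hi <- min(K, n)
  if (x > hi) return(0)
  j <- max(x, 0):hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Directed graph from a two-column edge matrix, or from a flat sequence
# of from/to pairs.
graph_from_edges <- function(...) {
  args <- list(...)
  el <- if (length(args) == 1L && !is.null(dim(args[[1]]))) args[[1]]
        else matrix(unlist(args), ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(as.data.frame(el, stringsAsFactors = FALSE),
                                directed = TRUE)
}

# Random small DAG on `n` nodes: forward edges in a random node order.
random_dag <- function(n, p_edge = 0.15) {
  nodes <- sprintf("n%02d", sample(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    tgt <- which(runif(n - i) < p_edge) + i
    from <- c(from, rep(nodes[i], length(tgt)))
    to <- c(to, nodes[tgt])
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE, vertices = data.frame(name = nodes))
}

# QC fixture: six SNPs engineered so that each record/presence filter
# removes exactly one SNP entirely, leaving a single survivor.
qc_fixture <- function() {
  studies <- data.table::CJ(
    study_id = c(sprintf("A%d", 1:3), sprintf("B%d", 1:5)),
    snp = sprintf("snp%d", 1:6)
  )
  studies$stage <- ifelse(grepl("^A", studies$study_id), 1L, 2L)
  n <- nrow(studies)
  studies$beta <- 0.1
  studies$se <- 0.1
  studies$pvalue <- 0.5
  studies$maf <- 0.2
  studies$hwe_pvalue <- 0.5
  studies$info <- 0.9
  studies$call_rate <- 0.95
  studies$maf[studies$snp == "snp1"] <- 0.005       # fails MAF everywhere
  studies$hwe_pvalue[studies$snp == "snp2"] <- 1e-6 # fails HWE
  studies$info[studies$snp == "snp3"] <- 0.3        # fails imputation
  studies$call_rate[studies$snp == "snp4"] <- 0.5   # fails call rate
  # snp5 present in too few studies per stage (2 of 3 / 4 of 5)
  studies <- studies[!(studies$snp == "snp5" &
                         studies$study_id %in% c("A3", "B5")), ]
  studies
}

# Uniform background of N named p-values plus the rank machinery inputs.
uniform_background <- function(N, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%05d", seq_len(N))
  list(bg = esnp_set("background", "all", ids),
       p = stats::setNames(stats::runif(N), ids))
}
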