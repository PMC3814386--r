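# Independent oracles used across the suite. Deliberately naive: they trade
# speed for obvious correctness and stay independent of the implementations
# they check.

# Exhaustive randomized peeling: delete ONE random violating vertex at a
# time until none violates the within-subgraph degree condition. Confluence
# of the peeling process means the final vertex set must not depend on the
# deletion order.
peel_oracle <- function(g, m) {
  vs <- igraph::V(g)$name
  repeat {
    sub <- igraph::induced_subgraph(g, vs)
    deg <- igraph::degree(sub)
    bad <- names(deg)[deg < m]
    if (length(bad) == 0L) break
    vs <- setdiff(vs, if (length(bad) == 1L) bad else sample(bad, 1L))
  }
  sort(vs)
}

# Full enumeration of n-subsets of {1..N} with members {1..K} marked:
# upper-tail overlap probabilities without any distribution function.
hyper_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# Erdos-Renyi graph with lexicographically padded vertex names.
random_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%03d", seq_len(n)))
}

# Iterative reference for the PSN core: peel genes below the in-degree
# threshold repeatedly, recomputing in-degrees each round (they cannot in
# fact change, which is the property under test).
psn_core_iterative <- function(rg, m) {
  edges <- rg$edges
  genes <- rg$genes
  repeat {
    indeg <- table(factor(edges$gene, levels = genes))
    bad <- names(indeg)[indeg < m]
    if (length(bad) == 0L) break
    genes <- setdiff(genes, bad)
    edges <- edges[edges$gene %in% genes, , drop = FALSE]
  }
  sort(genes)
}

# Small default bundle for fast tests.
tiny_config <- function(seed, n_genes = 300L, n_mutants = 60L, ...) {
  synthetic_config(n_genes = n_genes, n_mutants = n_mutants, seed = seed, ...)
}

# Build both networks and the joint table from an in-memory bundle.
bundle_networks <- function(bundle) {
  ppi <- build_ppi(bundle$edges)
  psn <- build_response_graph(bundle$pvalues, bundle$config$alpha)
  list(ppi = ppi, psn = psn, joint = joint_degrees(ppi, psn))
}

named_flag <- function(ann, col) stats::setNames(ann[[col]], ann$gene)
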