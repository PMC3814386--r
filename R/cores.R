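#' m-core of an undirected network by iterative peeling
#'
#' Repeatedly deletes every vertex whose degree within the remaining
#' subgraph is below `m`, until no such vertex is left. The surviving vertex
#' set is the standard k-core: the maximal set in which every member has at
#' least `m` neighbours inside the set. The result is independent of
#' deletion order. Connected components of the core are reported separately
#' (some definitions take the m-core to be a single maximal connected
#' subgraph; `largest_component` serves that reading, while `member_genes`
#' is the union of components, which preserves nestedness across m).
#'
#' @param net Undirected igraph graph (e.g. from [build_ppi()]).
#' @param m Minimum within-core degree, integer >= 1.
#' @return List of class `m_core`: `m`, `member_genes` (sorted), `components`
#'   (list of sorted gene sets, largest first), `largest_component`.
#' @export
peel_core <- function(net, m) {
  if (!(length(m) == 1L && !is.na(m) && m >= 1)) stop("m must be an integer >= 1")
  m <- as.integer(m)
  g <- net
  repeat {
    deg <- igraph::degree(g)
    drop <- names(deg)[deg < m]
    if (length(drop) == 0L) break
    g <- igraph::delete_vertices(g, drop)
  }
  members <- sort(igraph::V(g)$name)
  comps <- .gene_components(g)
  .m_core(m, members, comps)
}

#' m-core of the perturbation sensitivity network
#'
#' In the directed bipartite PSN only genes carry the degree constraint
#' (in-degree S_i >= m); mutant nodes are scaffolding and are never peeled.
#' Because every edge runs mutant -> gene, removing genes never changes
#' another gene's in-degree, so no iteration is required: the core is simply
#' the set of genes with in-degree at least m. Components are computed on
#' the bipartite subgraph induced by the member genes plus the mutants that
#' retain at least one edge into them, then projected to genes.
#'
#' @param rg A `response_graph` from [build_response_graph()].
#' @param m Minimum in-degree, integer >= 1.
#' @return List of class `m_core` (gene sets only; mutants are not counted).
#' @export
peel_core_psn <- function(rg, m) {
  if (!(length(m) == 1L && !is.na(m) && m >= 1)) stop("m must be an integer >= 1")
  m <- as.integer(m)
  stopifnot(inherits(rg, "response_graph"))
  members <- sort(names(rg$in_degree)[rg$in_degree >= m])
  if (length(members) == 0L) return(.m_core(m, character(0), list()))
  e <- rg$edges[rg$edges$gene %in% members, , drop = FALSE]
  # bipartite component structure: mutants with surviving edges link genes
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("m\r", e$mutant), to = paste0("g\r", e$gene),
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  comps_all <- igraph::components(g)
  comps <- lapply(seq_len(comps_all$no), function(i) {
    v <- names(comps_all$membership)[comps_all$membership == i]
    sort(substring(v[startsWith(v, "g\r")], 3L))
  })
  comps <- comps[lengths(comps) > 0L]
  .m_core(m, members, comps)
}

#' Core series over increasing m
#'
#' Applies [peel_core()] (undirected graph) or [peel_core_psn()]
#' (`response_graph`) at each requested m. Member sets are nested:
#' the (m+1)-core is a subset of the m-core.
#'
#' @param x Undirected igraph graph or `response_graph`.
#' @param m_values Strictly increasing integer vector.
#' @return List of `m_core` results, one per m.
#' @export
core_series <- function(x, m_values) {
  if (length(m_values) == 0L) stop("m_values must be non-empty")
  if (any(diff(m_values) <= 0)) stop("m_values must be strictly increasing")
  peel <- if (inherits(x, "response_graph")) peel_core_psn else peel_core
  lapply(m_values, function(m) peel(x, m))
}

.m_core <- function(m, members, comps) {
  ord <- order(-lengths(comps),
               vapply(comps, function(s) if (length(s)) s[1L] else "", ""))
  comps <- comps[ord]
  structure(
    list(
      m = m,
      member_genes = members,
      components = comps,
      largest_component = if (length(comps)) comps[[1L]] else character(0)
    ),
    class = "m_core"
  )
}

.gene_components <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comps_all <- igraph::components(g)
  lapply(seq_len(comps_all$no), function(i) {
    sort(names(comps_all$membership)[comps_all$membership == i])
  })
}

#' @export
print.m_core <- function(x, ...) {
  cat(sprintf("%d-core: %d genes in %d component(s); largest has %d\n",
              x$m, length(x$member_genes), length(x$components),
              length(x$largest_component)))
  invisible(x)
}

#' Write core membership as TSV
#'
#' @param series List of `m_core` results (e.g. from [core_series()]).
#' @param path Output path.
#' @return The path, invisibly. Columns: `m`, `gene`, `component_index`
#'   (1 = largest component at that m).
#' @export
write_core_series <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(core) {
    if (length(core$member_genes) == 0L) return(NULL)
    data.frame(
      m = core$m,
      gene = unlist(core$components, use.names = FALSE),
      component_index = rep(seq_along(core$components),
                            lengths(core$components)),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) {
    rows <- data.frame(m = integer(0), gene = character(0),
                       component_index = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
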