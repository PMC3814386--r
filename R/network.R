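#' Build the protein-protein interaction network
#'
#' Collapses a raw physical-interaction pair list into a simple undirected
#' graph: self-loops are dropped and duplicate pairs (in either orientation)
#' are merged. The number of pairs removed by each rule is recorded as graph
#' attributes `n_self_loops_removed` and `n_duplicates_removed`.
#'
#' @param pairs Data.frame with character columns `from` and `to` (as
#'   returned by [read_edge_list()]), or a two-column character matrix.
#' @return An undirected simple [igraph::igraph] graph whose vertex names are
#'   gene IDs, vertices in lexicographic order.
#' @export
build_ppi <- function(pairs) {
  if (is.matrix(pairs)) {
    pairs <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pairs), all(c("from", "to") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no interaction pairs supplied")
  from <- as.character(pairs$from)
  to <- as.character(pairs$to)
  self <- from == to
  from <- from[!self]
  to <- to[!self]
  if (length(from) == 0L) {
    stop("all interaction pairs are self-loops; network would be empty")
  }
  # canonical orientation so (a,b) and (b,a) collapse to the same key
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]
  b <- b[!dup]
  verts <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = verts
  )
  g <- igraph::set_graph_attr(g, "n_self_loops_removed", sum(self))
  g <- igraph::set_graph_attr(g, "n_duplicates_removed", sum(dup))
  g
}

#' Build the perturbation sensitivity network (PSN)
#'
#' Thresholds a gene-by-mutant p-value matrix at `alpha` (strictly: an edge
#' mutant j -> gene i exists iff `p[i, j]` is present and `p[i, j] < alpha`)
#' to obtain a directed bipartite response graph. Genes never significantly
#' affected and mutants affecting no gene are excluded from the node sets,
#' so every retained gene has in-degree (perturbation sensitivity S_i, also
#' written K_PSN) at least 1. Missing p-values mean "no evidence" and never
#' produce an edge.
#'
#' @param p Numeric matrix, genes as rownames, mutants as colnames.
#' @param alpha Significance threshold in (0, 1); default 0.01.
#' @return An object of class `response_graph`: a list with `genes`,
#'   `mutants` (both sorted), `edges` (data.frame `mutant`, `gene`),
#'   `in_degree` (named integer vector over `genes`) and `alpha`.
#' @export
build_response_graph <- function(p, alpha = 0.01) {
  stopifnot(is.matrix(p), !is.null(rownames(p)), !is.null(colnames(p)))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must be a single value in (0, 1)")
  }
  hit <- which(!is.na(p) & p < alpha, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    stop("no p-value below alpha = ", alpha, "; response graph would be empty")
  }
  edges <- data.frame(
    mutant = colnames(p)[hit[, 2L]],
    gene = rownames(p)[hit[, 1L]],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$mutant, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  genes <- sort(unique(edges$gene))
  mutants <- sort(unique(edges$mutant))
  in_degree <- table(factor(edges$gene, levels = genes))
  in_degree <- stats::setNames(as.integer(in_degree), genes)
  structure(
    list(genes = genes, mutants = mutants, edges = edges,
         in_degree = in_degree, alpha = alpha),
    class = "response_graph"
  )
}

#' @export
print.response_graph <- function(x, ...) {
  cat("Perturbation sensitivity network (directed bipartite)\n")
  cat("  genes:", length(x$genes), " mutants:", length(x$mutants),
      " edges:", nrow(x$edges), "\n")
  cat("  alpha:", x$alpha,
      " in-degree range:", min(x$in_degree), "-", max(x$in_degree), "\n")
  invisible(x)
}

#' Assemble the per-gene joint degree table
#'
#' One row per gene in the union of the PPI vertex set and the PSN gene set
#' (mutant IDs count only through their gene role: a mutant that is not also
#' a PPI gene or an affected gene contributes no row). `in_ppi`/`in_psn`
#' flag network membership; the degree in a network the gene does not belong
#' to is 0.
#'
#' @param ppi Undirected igraph graph from [build_ppi()], or `NULL`.
#' @param psn A `response_graph` from [build_response_graph()], or `NULL`.
#' @return Data.frame with columns `gene`, `k_ppi`, `k_psn`, `in_ppi`,
#'   `in_psn`, rows in lexicographic gene order.
#' @export
joint_degrees <- function(ppi = NULL, psn = NULL) {
  if (is.null(ppi) && is.null(psn)) stop("supply at least one network")
  ppi_deg <- if (!is.null(ppi)) {
    stats::setNames(as.integer(igraph::degree(ppi)),
                    igraph::V(ppi)$name)
  } else {
    stats::setNames(integer(0), character(0))
  }
  psn_deg <- if (!is.null(psn)) psn$in_degree else {
    stats::setNames(integer(0), character(0))
  }
  genes <- sort(unique(c(names(ppi_deg), names(psn_deg))))
  k_ppi <- ifelse(genes %in% names(ppi_deg), ppi_deg[genes], 0L)
  k_psn <- ifelse(genes %in% names(psn_deg), psn_deg[genes], 0L)
  data.frame(
    gene = genes,
    k_ppi = as.integer(k_ppi),
    k_psn = as.integer(k_psn),
    in_ppi = genes %in% names(ppi_deg),
    in_psn = genes %in% names(psn_deg),
    stringsAsFactors = FALSE
  )
}

#' Write a joint degree table summary
#'
#' @param t Joint degree table from [joint_degrees()].
#' @param path Output path.
#' @export
write_joint_degrees <- function(t, path) {
  out <- t
  out$in_ppi <- as.integer(out$in_ppi)
  out$in_psn <- as.integer(out$in_psn)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
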