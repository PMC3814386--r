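#' Excess retention of an annotated gene class in an m-core
#'
#' ER = (n_m_A / n_m) / (N_A / N): the fraction of annotation-positive genes
#' inside the m-core relative to their fraction in the whole group (the
#' 1-core). ER = 1 means no enrichment; > 1 over-representation; < 1
#' under-representation. At m = 1 with the universe equal to the 1-core the
#' two fractions coincide and ER is exactly 1.
#'
#' @param N Universe size (genes with known annotation), >= 1.
#' @param N_A Annotation-positive genes in the universe, >= 1 (a zero
#'   baseline leaves ER undefined and is an error).
#' @param n_m Genes of the universe inside the m-core.
#' @param n_m_A Annotation-positive universe genes inside the m-core.
#' @return The excess retention, or `NA_real_` when `n_m` is 0 (an empty
#'   core has no defined fraction; signalled as missing, never as 0).
#' @export
excess_retention <- function(N, N_A, n_m, n_m_A) {
  if (N < 1L) stop("universe size N must be >= 1")
  if (N_A < 1L) stop("baseline fraction undefined: N_A must be >= 1")
  if (N_A > N) stop("N_A cannot exceed N")
  if (n_m > N || n_m_A > n_m || n_m_A < 0L) {
    stop("core counts inconsistent: need 0 <= n_m_A <= n_m <= N")
  }
  if (n_m == 0L) return(NA_real_)
  (n_m_A / n_m) / (N_A / N)
}

#' Excess-retention curve over a core series
#'
#' Evaluates [excess_retention()] at every m of a nested core series, over
#' the genes with a known (non-missing) annotation value. The universe must
#' be the known-annotation genes of the relevant network's 1-core so that
#' the curve is anchored at ER = 1 for m = 1.
#'
#' @param series List of `m_core` results (from [core_series()]).
#' @param annotation Named logical vector (gene -> flag, `NA` = unknown).
#' @param universe Character vector of gene IDs defining the 1-core scope;
#'   genes with unknown annotation are dropped from it internally.
#' @return Data.frame with columns `m`, `n_m`, `n_m_A`, `er`.
#' @export
er_curve <- function(series, annotation, universe) {
  known <- names(annotation)[!is.na(annotation)]
  universe <- intersect(universe, known)
  if (length(universe) == 0L) stop("empty universe: no gene with known annotation")
  N <- length(universe)
  N_A <- sum(annotation[universe], na.rm = TRUE)
  if (N_A == 0L) stop("no annotation-positive gene in the universe")
  rows <- lapply(series, function(core) {
    in_core <- intersect(core$member_genes, universe)
    n_m <- length(in_core)
    n_m_A <- if (n_m) sum(annotation[in_core]) else 0L
    data.frame(m = core$m, n_m = n_m, n_m_A = as.integer(n_m_A),
               er = excess_retention(N, N_A, n_m, n_m_A))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a random
#' n-subset of an N-gene universe contains at least k of the K category
#' members. This is the classical over-representation test for gene-set
#' enrichment.
#'
#' @param N Universe size.
#' @param K Category size within the universe.
#' @param n Query subset size.
#' @param k Observed overlap.
#' @return The p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K)) {
    stop("inconsistent hypergeometric parameters: need 0 <= k <= min(n, K) <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (p_(i) * m / i, then a cumulative minimum from
#' the largest p down, clipped at 1), returned in input order.
#'
#' @param p_values Numeric vector with all values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must all lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric category enrichment with FDR control
#'
#' Tests each functional category for over-representation in a gene subset
#' (e.g. an m-core) against a universe, with BH-adjusted q-values. Only the
#' upper tail is tested (enrichment, not depletion). Categories with no
#' member inside the universe are omitted.
#'
#' @param subset Character vector of gene IDs, a subset of `universe`.
#' @param categories Named list of member vectors (from [read_categories()]).
#' @param universe Character vector of gene IDs.
#' @param q_threshold Significance threshold on the q-value (default 0.01).
#' @return Data.frame with one row per retained category: `category_id`,
#'   `category_name`, `k` (overlap), `n` (subset size), `K` (category size),
#'   `N` (universe size), `p_value`, `q_value`, `significant`; sorted by
#'   p-value.
#' @export
enrich_categories <- function(subset, categories, universe,
                              q_threshold = 0.01) {
  universe <- unique(universe)
  subset <- unique(subset)
  if (length(universe) == 0L) stop("empty universe")
  if (length(subset) == 0L) stop("empty subset")
  if (!all(subset %in% universe)) {
    stop("subset contains genes outside the universe")
  }
  members <- lapply(categories, intersect, universe)
  keep <- lengths(members) >= 1L
  members <- members[keep]
  if (length(members) == 0L) stop("no category overlaps the universe")
  cat_names <- attr(categories, "category_names")
  if (is.null(cat_names)) {
    cat_names <- stats::setNames(names(categories), names(categories))
  }
  N <- length(universe)
  n <- length(subset)
  K <- lengths(members)
  k <- vapply(members, function(g) length(intersect(g, subset)), integer(1))
  p <- vapply(seq_along(members),
              function(i) hypergeom_pvalue(N, K[[i]], n, k[[i]]), numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(
    category_id = names(members),
    category_name = unname(cat_names[names(members)]),
    k = unname(k), n = n, K = unname(K), N = N,
    p_value = p, q_value = q,
    significant = q < q_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of annotation-positive genes per degree bin
#'
#' The Fig-2-style curve: genes of the chosen network are grouped into
#' degree bins `[e1, e2), [e2, e3), ..., [e_last-1, e_last]` and within each
#' bin the fraction of annotation-positive genes among known-annotation
#' genes is reported. Empty bins are kept with `n_known = 0` and a missing
#' proportion.
#'
#' @param t Joint degree table from [joint_degrees()].
#' @param annotation Named logical vector (gene -> flag, `NA` = unknown).
#' @param which_degree `"ppi"` or `"psn"`.
#' @param bin_edges Strictly increasing integer vector covering the degree
#'   range, e.g. `c(1, 2, 4, 8, 16, ...)`.
#' @return Data.frame with `bin_lo`, `bin_hi`, `n_known`, `n_positive`,
#'   `proportion`.
#' @export
proportion_by_degree_bin <- function(t, annotation,
                                     which_degree = c("ppi", "psn"),
                                     bin_edges) {
  which_degree <- match.arg(which_degree)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing with >= 2 values")
  }
  member <- if (which_degree == "ppi") t$in_ppi else t$in_psn
  deg <- if (which_degree == "ppi") t$k_ppi else t$k_psn
  flag <- annotation[t$gene]
  keep <- member & !is.na(flag)
  deg <- deg[keep]
  flag <- flag[keep]
  if (length(deg) && (min(deg) < bin_edges[1L] || max(deg) > bin_edges[length(bin_edges)])) {
    stop("bin_edges do not cover the degree range [", min(deg), ", ",
         max(deg), "]")
  }
  idx <- findInterval(deg, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  n_known <- tabulate(idx, nbins = n_bins)
  n_pos <- vapply(seq_len(n_bins), function(b) sum(flag[idx == b]), integer(1))
  data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1L],
    n_known = n_known,
    n_positive = n_pos,
    proportion = ifelse(n_known > 0L, n_pos / n_known, NA_real_)
  )
}

#' Four-class lethal-by-disease grid over joint degree bins
#'
#' Cross-tabulates genes belonging to both networks, with known lethal and
#' known disease annotation, into (K_PPI bin) x (K_PSN bin) cells and counts
#' the four exclusive classes: lethal disease, lethal non-disease, non-lethal
#' disease and non-lethal non-disease. Marginal rows/columns (whole-axis
#' bins, labelled with bin index 0) are appended, mirroring the marginal
#' pie-chart arrays of the grid diagram.
#'
#' @param t Joint degree table from [joint_degrees()].
#' @param catalog Annotation data.frame (from [read_annotations()] or
#'   [annotate_genes()]), with `gene`, `lethal`, `disease` columns.
#' @param ppi_edges,psn_edges Strictly increasing bin edges for the two axes.
#' @return Data.frame with `ppi_bin`, `psn_bin` (integer bin index, 0 = the
#'   marginal "all" bin), the bin intervals, the four class counts and
#'   `total`.
#' @export
four_class_grid <- function(t, catalog, ppi_edges, psn_edges) {
  for (e in list(ppi_edges, psn_edges)) {
    if (length(e) < 2L || any(diff(e) <= 0)) {
      stop("bin edges must be strictly increasing with >= 2 values")
    }
  }
  lethal <- stats::setNames(catalog$lethal, catalog$gene)[t$gene]
  disease <- stats::setNames(catalog$disease, catalog$gene)[t$gene]
  keep <- t$in_ppi & t$in_psn & !is.na(lethal) & !is.na(disease)
  if (!any(keep)) stop("no gene with both memberships and known lethal/disease")
  kp <- t$k_ppi[keep]
  ks <- t$k_psn[keep]
  lethal <- lethal[keep]
  disease <- disease[keep]
  if (min(kp) < ppi_edges[1L] || max(kp) > ppi_edges[length(ppi_edges)] ||
      min(ks) < psn_edges[1L] || max(ks) > psn_edges[length(psn_edges)]) {
    stop("bin edges do not cover the joint degree range")
  }
  ip <- findInterval(kp, ppi_edges, rightmost.closed = TRUE)
  is_ <- findInterval(ks, psn_edges, rightmost.closed = TRUE)
  cell_counts <- function(sel) {
    c(lethal_disease = sum(sel & lethal & disease),
      lethal_only = sum(sel & lethal & !disease),
      disease_only = sum(sel & !lethal & disease),
      neither = sum(sel & !lethal & !disease))
  }
  np <- length(ppi_edges) - 1L
  ns <- length(psn_edges) - 1L
  rows <- list()
  for (a in seq_len(np)) {
    for (b in seq_len(ns)) {
      cc <- cell_counts(ip == a & is_ == b)
      rows[[length(rows) + 1L]] <- data.frame(
        ppi_bin = a, psn_bin = b,
        ppi_lo = ppi_edges[a], ppi_hi = ppi_edges[a + 1L],
        psn_lo = psn_edges[b], psn_hi = psn_edges[b + 1L],
        t(cc), total = sum(cc))
    }
  }
  for (a in seq_len(np)) {  # PPI-axis marginals (all PSN bins pooled)
    cc <- cell_counts(ip == a)
    rows[[length(rows) + 1L]] <- data.frame(
      ppi_bin = a, psn_bin = 0L,
      ppi_lo = ppi_edges[a], ppi_hi = ppi_edges[a + 1L],
      psn_lo = psn_edges[1L], psn_hi = psn_edges[ns + 1L],
      t(cc), total = sum(cc))
  }
  for (b in seq_len(ns)) {  # PSN-axis marginals
    cc <- cell_counts(is_ == b)
    rows[[length(rows) + 1L]] <- data.frame(
      ppi_bin = 0L, psn_bin = b,
      ppi_lo = ppi_edges[1L], ppi_hi = ppi_edges[np + 1L],
      psn_lo = psn_edges[b], psn_hi = psn_edges[b + 1L],
      t(cc), total = sum(cc))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power-of-two degree bin edges covering a degree range
#'
#' @param max_degree Largest degree to cover.
#' @param from First edge (default 1).
#' @return Integer vector `c(from, 2*from, 4*from, ...)`, extended until the
#'   last edge is >= `max_degree`.
#' @export
dyadic_bin_edges <- function(max_degree, from = 1L) {
  stopifnot(max_degree >= from, from >= 1L)
  edges <- from
  while (edges[length(edges)] < max_degree) {
    edges <- c(edges, edges[length(edges)] * 2L)
  }
  if (length(edges) < 2L) edges <- c(edges, edges * 2L)
  as.integer(edges)
}
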