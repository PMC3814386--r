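#' Read a two-column gene interaction edge list
#'
#' Parses a tab-separated file of gene pairs, one interaction per line.
#' Lines starting with `#` are skipped. Pairs are returned exactly as read,
#' in file order, without deduplication or self-loop removal: that cleanup is
#' the contract of [build_ppi()].
#'
#' @param path Path to a TSV file with exactly two columns of gene IDs.
#' @return A data.frame with character columns `from` and `to`, one row per
#'   non-comment line, in file order.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("edge list '", path, "' contains no data rows")
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    stop("edge list '", path, "': line ", bad, " has ", nf[which(nf != 2L)[1L]],
         " column(s), expected 2")
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  .check_gene_ids(c(from, to), "edge list")
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Write an edge list in the input dialect
#'
#' @param edges Data.frame with columns `from` and `to`.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-mutant p-value matrix
#'
#' The file has one header row naming the deletion mutants, then one row per
#' gene: the gene ID followed by one p-value per mutant. Cells are reals in
#' \[0, 1\] or the literal `NA` (a pair that was not measured). Missing cells
#' stay missing; they are never coerced to 0 or 1, and downstream they mean
#' "no evidence", hence no edge.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with genes as rownames and mutants as colnames.
#' @export
read_pvalue_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("p-value matrix '", path, "' needs a gene column plus >=1 mutant column")
  }
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    stop("p-value matrix '", path, "': duplicate gene row '",
         genes[duplicated(genes)][1L], "'")
  }
  .check_gene_ids(genes, "p-value matrix")
  p <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(p) <- "double"
  rownames(p) <- genes
  bad <- which(!is.na(p) & (p < 0 | p > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("p-value matrix '", path, "': value ", p[bad[1L, , drop = FALSE]],
         " outside [0, 1] for gene '", rownames(p)[bad[1L, 1L]],
         "', mutant '", colnames(p)[bad[1L, 2L]], "'")
  }
  p
}

#' Write a p-value matrix
#'
#' @param p Numeric matrix with gene rownames and mutant colnames.
#' @param path Output path.
#' @export
write_pvalue_matrix <- function(p, path) {
  stopifnot(is.matrix(p), !is.null(rownames(p)), !is.null(colnames(p)))
  chr <- matrix(.format_real(p), nrow = nrow(p), dimnames = dimnames(p))
  tab <- data.frame(gene = rownames(p), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 17 significant digits: every finite double round-trips exactly through text.
.format_real <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.annotation_cols <- c("gene", "lethal", "disease", "drug_target", "tata",
                      "tfbs_count", "dnds", "cai", "human_homolog")

#' Read a per-gene annotation catalog
#'
#' Nine fixed tab-separated columns: `gene`, `lethal`, `disease`,
#' `drug_target`, `tata`, `tfbs_count`, `dnds`, `cai`, `human_homolog`.
#' Flag columns are `1`, `0` or `NA` (unknown); `tfbs_count` is a
#' non-negative integer or `NA`; `dnds` is a non-negative real or `NA`;
#' `cai` is in \[0, 1\] or `NA`. Unknown flags later exclude the gene from
#' both numerator and denominator of any proportion or excess-retention
#' computation for that annotation.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with logical flag columns (`NA` = unknown), integer
#'   `tfbs_count`, numeric `dnds` and `cai`, one row per gene.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(names(tab), .annotation_cols)) {
    stop("annotation table '", path, "': header must be exactly: ",
         paste(.annotation_cols, collapse = ", "))
  }
  genes <- tab$gene
  if (anyDuplicated(genes)) {
    stop("annotation table '", path, "': duplicate gene '",
         genes[duplicated(genes)][1L], "'")
  }
  .check_gene_ids(genes, "annotation table")
  parse_flag <- function(x, col) {
    x[x == "NA"] <- NA_character_
    ok <- is.na(x) | x %in% c("0", "1")
    if (!all(ok)) {
      stop("annotation table '", path, "': column '", col, "' has value '",
           x[!ok][1L], "', expected 1, 0 or NA")
    }
    as.logical(as.integer(x))
  }
  out <- data.frame(
    gene = genes,
    lethal = parse_flag(tab$lethal, "lethal"),
    disease = parse_flag(tab$disease, "disease"),
    drug_target = parse_flag(tab$drug_target, "drug_target"),
    tata = parse_flag(tab$tata, "tata"),
    tfbs_count = suppressWarnings(as.integer(ifelse(tab$tfbs_count == "NA",
                                                    NA, tab$tfbs_count))),
    dnds = suppressWarnings(as.numeric(ifelse(tab$dnds == "NA", NA, tab$dnds))),
    cai = suppressWarnings(as.numeric(ifelse(tab$cai == "NA", NA, tab$cai))),
    human_homolog = parse_flag(tab$human_homolog, "human_homolog"),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$tfbs_count) & out$tfbs_count < 0L)) {
    stop("annotation table '", path, "': negative tfbs_count")
  }
  if (any(!is.na(out$dnds) & out$dnds < 0)) {
    stop("annotation table '", path, "': negative dnds")
  }
  if (any(!is.na(out$cai) & (out$cai < 0 | out$cai > 1))) {
    stop("annotation table '", path, "': cai outside [0, 1]")
  }
  out
}

#' Write an annotation catalog
#'
#' @param catalog Data.frame as returned by [read_annotations()].
#' @param path Output path.
#' @export
write_annotations <- function(catalog, path) {
  stopifnot(identical(names(catalog), .annotation_cols))
  out <- catalog
  for (col in c("lethal", "disease", "drug_target", "tata", "human_homolog")) {
    out[[col]] <- ifelse(is.na(catalog[[col]]), "NA",
                         as.character(as.integer(catalog[[col]])))
  }
  out$tfbs_count <- ifelse(is.na(catalog$tfbs_count), "NA",
                           as.character(catalog$tfbs_count))
  out$dnds <- .format_real(catalog$dnds)
  out$cai <- .format_real(catalog$cai)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read functional category membership
#'
#' Accepts either a two-column TSV (`category_id<TAB>gene`, one membership
#' per line) or the GMT dialect (`category<TAB>description<TAB>gene1<TAB>...`).
#' A file is treated as GMT when any line has more than two fields. Members
#' are deduplicated; set semantics, so member order is not preserved.
#'
#' @param path Path to the category file.
#' @return A named list of character vectors (category id -> members), with a
#'   `category_names` attribute carrying the descriptions (GMT) or the ids.
#' @export
read_categories <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("category file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("category file '", path, "': line with fewer than 2 fields")
  }
  if (any(nf > 2L)) {
    ids <- vapply(fields, `[[`, character(1), 1L)
    descs <- vapply(fields, `[[`, character(1), 2L)
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
  } else {
    ids_raw <- vapply(fields, `[[`, character(1), 1L)
    genes_raw <- vapply(fields, `[[`, character(1), 2L)
    ids <- unique(ids_raw)
    descs <- ids
    members <- lapply(ids, function(id) unique(genes_raw[ids_raw == id]))
  }
  if (anyDuplicated(ids)) {
    stop("category file '", path, "': duplicate category '",
         ids[duplicated(ids)][1L], "'")
  }
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stop("category file '", path, "': category '", ids[empty][1L],
         "' has no members")
  }
  names(members) <- ids
  names(descs) <- ids
  attr(members, "category_names") <- descs
  members
}

#' Write category membership as two-column TSV
#'
#' @param categories Named list of member vectors.
#' @param path Output path.
#' @export
write_categories <- function(categories, path) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  tab <- data.frame(
    category = rep(names(categories), lengths(categories)),
    gene = unlist(lapply(categories, sort), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Gene IDs: non-empty, no whitespace; comparison is exact and case-sensitive.
.check_gene_ids <- function(ids, what) {
  bad <- !nzchar(ids) | grepl("\\s", ids)
  if (any(bad)) {
    stop(what, ": invalid gene ID '", ids[bad][1L],
         "' (must be non-empty, no whitespace)")
  }
  invisible(TRUE)
}
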