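#' Configuration for a synthetic input bundle
#'
#' Bundles every planted parameter of the generator. Defaults emulate the
#' yeast study conditions: power-law exponents 2.48 (PPI) and 2.24 (PSN), a
#' significance threshold of 0.01 on the perturbation p-values, 212 deletion
#' mutants, a moderately negative latent copula correlation between the two
#' degree sequences, and lethal/disease annotation probabilities that move
#' monotonically (and in opposite directions) along the PPI-minus-PSN
#' log-degree contrast.
#'
#' @param n_genes Number of genes (all carry a PPI degree).
#' @param n_mutants Number of deletion mutants in the p-value matrix.
#' @param gamma_ppi,gamma_psn Planted power-law exponents (> 1).
#' @param rho Latent Gaussian-copula correlation between the two degree
#'   sequences, in (-1, 1); negative = reciprocal topology.
#' @param alpha Significance threshold planted in the p-value matrix.
#' @param frac_psn_members Fraction of genes that belong to the PSN
#'   (draw a positive in-degree), in (0, 1].
#' @param kmin Smallest degree (both networks).
#' @param kmax_ppi,kmax_psn Truncation of the two degree laws. The PPI
#'   default n_genes/10 keeps the configuration model realisable as a simple
#'   graph; the PSN default 50 mirrors an in-degree range capped by the
#'   mutant panel.
#' @param lethal_base,lethal_slope Log-odds intercept/slope of lethality on
#'   z = standardized log(1+k_ppi) - standardized log(1+k_psn).
#' @param disease_base,disease_slope Same for disease, on -z, sampled among
#'   non-lethal homolog-bearing genes (lethal homolog genes are recorded as
#'   non-disease; the four classes are exclusive).
#' @param dnds_scale,cai_scale Strength of the monotone trait effects on the
#'   mean standardized log-degree (z1+z2)/2.
#' @param noise_sd Gaussian noise SD on the log/logit trait scales.
#' @param homolog_frac Fraction of genes with a human homolog.
#' @param n_categories Number of random functional categories (one extra
#'   degree-biased category is always added).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 5000L,
                             n_mutants = 212L,
                             gamma_ppi = 2.48,
                             gamma_psn = 2.24,
                             rho = -0.5,
                             alpha = 0.01,
                             frac_psn_members = 0.75,
                             kmin = 1L,
                             kmax_ppi = min(n_genes - 1L,
                                            max(50L, round(n_genes / 10))),
                             kmax_psn = min(50L, n_mutants),
                             lethal_base = -1.6,
                             lethal_slope = 0.8,
                             disease_base = -1.5,
                             disease_slope = 0.8,
                             dnds_scale = 0.5,
                             cai_scale = 0.5,
                             noise_sd = 0.5,
                             homolog_frac = 0.25,
                             n_categories = 20L,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    n_genes = as.integer(n_genes), n_mutants = as.integer(n_mutants),
    gamma_ppi = gamma_ppi, gamma_psn = gamma_psn, rho = rho, alpha = alpha,
    frac_psn_members = frac_psn_members, kmin = as.integer(kmin),
    kmax_ppi = as.integer(kmax_ppi), kmax_psn = as.integer(kmax_psn),
    lethal_base = lethal_base, lethal_slope = lethal_slope,
    disease_base = disease_base, disease_slope = disease_slope,
    dnds_scale = dnds_scale, cai_scale = cai_scale, noise_sd = noise_sd,
    homolog_frac = homolog_frac, n_categories = as.integer(n_categories),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 10L, cfg$n_mutants >= 2L,
    cfg$gamma_ppi > 1, cfg$gamma_psn > 1,
    abs(cfg$rho) < 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$frac_psn_members > 0, cfg$frac_psn_members <= 1,
    cfg$kmin >= 1L, cfg$kmax_ppi > cfg$kmin, cfg$kmax_psn > cfg$kmin,
    cfg$kmax_ppi < cfg$n_genes, cfg$kmax_psn <= cfg$n_mutants,
    cfg$homolog_frac > 0, cfg$homolog_frac <= 1,
    !is.na(cfg$seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# Independent per-stage seeds derived deterministically from the master seed.
.stage_seeds <- function(seed, n = 10L) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample degrees from a truncated discrete power law
#'
#' i.i.d. draws from P(k) proportional to k^-gamma on `kmin:kmax`, via
#' inverse-CDF on the exactly normalised mass function.
#'
#' @param n Number of draws.
#' @param gamma Exponent (> 1).
#' @param kmin,kmax Integer support bounds, `kmin < kmax`.
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_powerlaw_degrees <- function(n, gamma, kmin = 1L, kmax, seed) {
  if (!(gamma > 1)) stop("gamma must be > 1")
  if (!(kmin >= 1L && kmax > kmin)) stop("need 1 <= kmin < kmax")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  .powerlaw_quantile(stats::runif(n), gamma, kmin, kmax)
}

# Exact pmf of the truncated discrete power law.
.powerlaw_pmf <- function(gamma, kmin, kmax) {
  k <- kmin:kmax
  w <- k^(-gamma)
  w / sum(w)
}

# Quantile function: smallest k with CDF(k) >= u.
.powerlaw_quantile <- function(u, gamma, kmin, kmax) {
  cum <- cumsum(.powerlaw_pmf(gamma, kmin, kmax))
  idx <- findInterval(u, cum) + 1L
  idx[idx > length(cum)] <- length(cum)
  as.integer(kmin:kmax)[idx]
}

#' Sample a coupled pair of power-law degree sequences
#'
#' Gaussian copula: latent standard bivariate normal pairs with correlation
#' `rho` are pushed through the two truncated power-law inverse CDFs, so
#' each margin is exactly the distribution of [sample_powerlaw_degrees()]
#' while the rank dependence carries the sign (and, attenuated by
#' discreteness, the strength) of `rho`.
#'
#' @param n Number of gene pairs.
#' @param gamma_ppi,gamma_psn Marginal exponents.
#' @param rho Latent correlation in (-1, 1).
#' @param kmin,kmax_ppi,kmax_psn Support bounds of the two margins.
#' @param seed Integer seed.
#' @return Data.frame with integer columns `k_ppi`, `k_psn`.
#' @export
coupled_degree_pair <- function(n, gamma_ppi, gamma_psn, rho,
                                kmin = 1L, kmax_ppi, kmax_psn, seed) {
  if (!(abs(rho) < 1)) stop("|rho| must be < 1")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    k_ppi = .powerlaw_quantile(stats::pnorm(z1), gamma_ppi, kmin, kmax_ppi),
    k_psn = .powerlaw_quantile(stats::pnorm(z2), gamma_psn, kmin, kmax_psn)
  )
}

#' Realise a degree sequence as a simple graph (configuration model)
#'
#' Random stub matching, then self-loops and multi-edges are discarded, so
#' realised degrees can fall slightly below their targets (heavily for the
#' largest hubs if `kmax` is too close to n). If the degree sum is odd one
#' randomly chosen gene gets an extra stub; this is recorded in the
#' `stub_incremented` graph attribute. Target degrees are kept in the vertex
#' attribute `target_degree`.
#'
#' @param degrees Integer vector of target degrees; names become gene IDs
#'   (default `g00001`, ...).
#' @param seed Integer seed.
#' @return Undirected simple igraph graph.
#' @export
ppi_from_degrees <- function(degrees, seed) {
  if (length(degrees) < 2L) stop("need at least 2 genes")
  if (any(degrees < 0L)) stop("degrees must be non-negative")
  ids <- names(degrees)
  if (is.null(ids)) {
    ids <- sprintf("g%05d", seq_along(degrees))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  degrees <- as.integer(degrees)
  bumped <- NA_character_
  if (sum(degrees) %% 2L == 1L) {
    i <- sample.int(length(degrees), 1L)
    degrees[i] <- degrees[i] + 1L
    bumped <- ids[i]
  }
  g <- igraph::sample_degseq(degrees, method = "configuration")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "target_degree", value = degrees)
  g <- igraph::set_graph_attr(g, "stub_incremented", bumped)
  g
}

#' Plant a p-value matrix realising given perturbation in-degrees
#'
#' For each gene, `k_psn` distinct mutants are chosen uniformly and their
#' cells drawn from Uniform(0, alpha); every other cell is drawn from
#' Uniform(alpha, 1). Thresholding the matrix strictly below `alpha`
#' therefore recovers the planted bipartite mutant-to-gene edge set exactly.
#'
#' @param k_psn Integer vector of in-degrees; names become gene IDs.
#' @param n_mutants Number of mutant columns (IDs `mut001`, ...).
#' @param alpha Planted threshold.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x mutants, with the planted edge list in
#'   attribute `planted_edges` (data.frame `mutant`, `gene`).
#' @export
pmatrix_from_indegrees <- function(k_psn, n_mutants, alpha = 0.01, seed) {
  if (any(k_psn > n_mutants)) stop("in-degree exceeds number of mutants")
  if (any(k_psn < 0L)) stop("in-degrees must be non-negative")
  ids <- names(k_psn)
  if (is.null(ids)) ids <- sprintf("g%05d", seq_along(k_psn))
  muts <- sprintf("mut%03d", seq_len(n_mutants))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- length(k_psn)
  p <- matrix(stats::runif(n * n_mutants, min = alpha, max = 1),
              nrow = n, dimnames = list(ids, muts))
  hits <- lapply(seq_len(n), function(i) {
    if (k_psn[i] == 0L) return(integer(0))
    sample.int(n_mutants, k_psn[i])
  })
  n_sig <- sum(lengths(hits))
  if (n_sig > 0L) {
    rows <- rep(seq_len(n), lengths(hits))
    cols <- unlist(hits, use.names = FALSE)
    p[cbind(rows, cols)] <- stats::runif(n_sig, min = 0, max = alpha)
    planted <- data.frame(mutant = muts[cols], gene = ids[rows],
                          stringsAsFactors = FALSE)
    planted <- planted[order(planted$mutant, planted$gene), , drop = FALSE]
    rownames(planted) <- NULL
  } else {
    planted <- data.frame(mutant = character(0), gene = character(0))
  }
  attr(p, "planted_edges") <- planted
  p
}

#' Generate per-gene annotations with planted degree effects
#'
#' Lethality follows a logistic model on the degree contrast
#' z = standardized log(1+k_ppi) - standardized log(1+k_psn): a positive
#' `lethal_slope` concentrates lethal genes among PPI hubs. Disease is the
#' mirror image on -z, sampled only among non-lethal homolog-bearing genes
#' (lethal homolog genes are recorded as known non-disease; genes without a
#' homolog have unknown disease status). Drug-target and TATA flags follow
#' the disease direction; the TFBS count is Poisson with a log-link on -z.
#' dN/dS decreases and CAI increases with the mean standardized log-degree,
#' so that hubs of either network look evolutionarily constrained. A share
#' of dnds/cai values is masked as missing to exercise the known-annotation
#' exclusion rules downstream.
#'
#' @param joint Data.frame with columns `gene`, `k_ppi`, `k_psn`.
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return Annotation data.frame in the [read_annotations()] layout.
#' @export
annotate_genes <- function(joint, config, seed) {
  stopifnot(all(c("gene", "k_ppi", "k_psn") %in% names(joint)))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(joint)
  z1 <- as.numeric(scale(log1p(joint$k_ppi)))
  z2 <- as.numeric(scale(log1p(joint$k_psn)))
  if (any(is.na(z1))) z1 <- rep(0, n)  # degenerate: constant degrees
  if (any(is.na(z2))) z2 <- rep(0, n)
  z <- z1 - z2
  zbar <- (z1 + z2) / 2
  lethal <- stats::rbinom(n, 1L,
                          stats::plogis(config$lethal_base +
                                        config$lethal_slope * z)) == 1L
  homolog <- stats::rbinom(n, 1L, config$homolog_frac) == 1L
  disease <- rep(NA, n)
  disease[homolog & lethal] <- FALSE
  idx <- which(homolog & !lethal)
  disease[idx] <- stats::rbinom(length(idx), 1L,
                                stats::plogis(config$disease_base -
                                              config$disease_slope * z[idx])) == 1L
  drug <- rep(NA, n)
  drug[homolog] <- stats::rbinom(sum(homolog), 1L,
                                 stats::plogis(-1.8 - 0.6 * z[homolog])) == 1L
  tata <- stats::rbinom(n, 1L, stats::plogis(-1.2 - 0.4 * z)) == 1L
  tfbs <- stats::rpois(n, exp(1.0 - 0.3 * pmax(pmin(z, 3), -3)))
  dnds <- 0.15 * exp(-config$dnds_scale * zbar +
                     stats::rnorm(n, sd = config$noise_sd))
  cai <- stats::plogis(config$cai_scale * zbar +
                       stats::rnorm(n, sd = config$noise_sd))
  dnds[stats::runif(n) < 0.3] <- NA
  cai[stats::runif(n) < 0.05] <- NA
  data.frame(
    gene = joint$gene,
    lethal = lethal,
    disease = disease,
    drug_target = drug,
    tata = tata,
    tfbs_count = tfbs,
    dnds = round(dnds, 6),
    cai = round(cai, 6),
    human_homolog = homolog,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete input bundle in memory
#'
#' Draws the coupled degree pair, realises the PPI by configuration model,
#' plants the p-value matrix, annotates genes and samples functional
#' categories (random gene sets plus one PPI-degree-biased set). All
#' randomness is derived from `config$seed` through fixed per-stage
#' substreams, so identical configs give identical bundles.
#'
#' @param config A `synthetic_config`.
#' @return List with `edges` (data.frame), `pvalues` (matrix),
#'   `annotations` (data.frame), `categories` (named list), `truth` (planted
#'   joint degrees, PSN membership, planted response edges) and `config`.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ss <- .stage_seeds(config$seed, 6L)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  joint <- coupled_degree_pair(
    config$n_genes, config$gamma_ppi, config$gamma_psn, config$rho,
    kmin = config$kmin, kmax_ppi = config$kmax_ppi,
    kmax_psn = config$kmax_psn, seed = ss[1L]
  )
  joint <- data.frame(gene = genes, joint, stringsAsFactors = FALSE)
  # genes outside the PSN never respond: in-degree 0 in the planted matrix
  old <- .save_rng(); set.seed(ss[2L])
  in_psn <- stats::runif(config$n_genes) < config$frac_psn_members
  .restore_rng(old)
  joint$k_psn[!in_psn] <- 0L
  ppi <- ppi_from_degrees(stats::setNames(joint$k_ppi, genes), seed = ss[3L])
  p <- pmatrix_from_indegrees(stats::setNames(joint$k_psn, genes),
                              config$n_mutants, config$alpha, seed = ss[4L])
  ann <- annotate_genes(joint, config, seed = ss[5L])
  categories <- .sample_categories(joint, config, seed = ss[6L])
  edges <- igraph::as_data_frame(ppi, what = "edges")
  names(edges) <- c("from", "to")
  list(
    edges = edges,
    pvalues = p,
    annotations = ann,
    categories = categories,
    truth = list(
      joint = joint,
      in_psn = stats::setNames(in_psn, genes),
      planted_edges = attr(p, "planted_edges"),
      realized_k_ppi = stats::setNames(as.integer(igraph::degree(ppi)),
                                       igraph::V(ppi)$name)
    ),
    config = config
  )
}

.sample_categories <- function(joint, config, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(joint)
  sizes <- pmax(5L, pmin(n, stats::rpois(config$n_categories,
                                         lambda = max(10, n / 50))))
  cats <- lapply(sizes, function(s) sort(sample(joint$gene, s)))
  names(cats) <- sprintf("CAT%03d", seq_along(cats))
  # one category biased toward PPI hubs: membership odds rise with k_ppi
  w <- joint$k_ppi / sum(joint$k_ppi)
  hub_size <- max(10L, round(n / 25))
  cats[["CAT_HUB"]] <- sort(sample(joint$gene, hub_size, prob = w))
  attr(cats, "category_names") <- stats::setNames(
    c(sprintf("random set %d", seq_len(config$n_categories)),
      "PPI-degree-biased set"),
    names(cats))
  cats
}

#' Write a synthetic bundle to disk
#'
#' Emits the four pipeline input files in their canonical dialects
#' (`edges.tsv`, `pvalues.tsv`, `annotations.tsv`, `categories.tsv`) plus a
#' `manifest.json` echoing every planted parameter, the file names and the
#' planted PSN edge count. Byte-identical across runs with the same config.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle from [simulate_bundle()] with a
#'   `paths` element appended.
#' @export
generate_bundle <- function(config, dir) {
  bundle <- simulate_bundle(config)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory '", dir, "'")
  }
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    pvalues = file.path(dir, "pvalues.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    categories = file.path(dir, "categories.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_edge_list(bundle$edges, paths$edges)
  write_pvalue_matrix(bundle$pvalues, paths$pvalues)
  write_annotations(bundle$annotations, paths$annotations)
  write_categories(bundle$categories, paths$categories)
  manifest <- c(
    unclass(bundle$config),
    list(
      files = lapply(paths[1:4], basename),
      n_planted_psn_edges = nrow(bundle$truth$planted_edges),
      n_ppi_edges = nrow(bundle$edges)
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  bundle$paths <- paths
  invisible(bundle)
}
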