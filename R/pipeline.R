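#' Run configuration for the full pipeline
#'
#' Either four input file paths or a [synthetic_config()] must be supplied
#' (not neither). All thresholds and bin schemes live here so that one
#' config object fully determines a run.
#'
#' @param edges,pvalues,annotations,categories Input file paths, or `NULL`
#'   when `synthetic` is given.
#' @param synthetic Optional `synthetic_config`; the bundle is generated
#'   under `out_dir/bundle` and then consumed like real inputs.
#' @param alpha PSN significance threshold.
#' @param m_ppi,m_psn Strictly increasing m values for the two core series
#'   (`NULL` = 1 up to the largest non-empty core, log-spaced).
#' @param ppi_bin_edges,psn_bin_edges Degree bin edges (`NULL` = powers of 2
#'   covering the observed range).
#' @param q_threshold FDR threshold for category enrichment.
#' @param fit_binning Power-law fit mode, `"raw"` or `"log"`.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (only used when
#'   `synthetic` is given without its own seed).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(edges = NULL, pvalues = NULL, annotations = NULL,
                       categories = NULL, synthetic = NULL,
                       alpha = 0.01, m_ppi = NULL, m_psn = NULL,
                       ppi_bin_edges = NULL, psn_bin_edges = NULL,
                       q_threshold = 0.01, fit_binning = "log",
                       out_dir, seed = 1L) {
  have_files <- !is.null(edges)
  if (!have_files && is.null(synthetic)) {
    stop("config error: supply input file paths or a synthetic_config")
  }
  if (have_files) {
    for (p in c(edges, pvalues, annotations, categories)) {
      if (!file.exists(p)) stop("config error: input file not found: ", p)
    }
  }
  structure(
    list(edges = edges, pvalues = pvalues, annotations = annotations,
         categories = categories, synthetic = synthetic, alpha = alpha,
         m_ppi = m_ppi, m_psn = m_psn, ppi_bin_edges = ppi_bin_edges,
         psn_bin_edges = psn_bin_edges, q_threshold = q_threshold,
         fit_binning = match.arg(fit_binning, c("raw", "log")),
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Execute the full analysis pipeline
#'
#' Stages: (1) read or simulate the inputs; (2) build the PPI and PSN and
#' the joint degree table; (3) topology — marginal power-law fits, the joint
#' regression plane, degree reciprocity, degree-trait correlations; (4)
#' m-core series of both networks; (5) excess-retention curves for lethal,
#' disease and drug-target classes, proportion-by-degree-bin tables and the
#' four-class grid; (6) hypergeometric category enrichment of both top
#' cores. Every output table is written as TSV under `out_dir` and listed,
#' with md5 checksums and all parameters, in `manifest.json`. A failure in
#' any stage aborts with the stage name.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with all in-memory results (`networks`,
#'   `topology`, `cores`, `retention`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      bundle <- generate_bundle(config$synthetic, file.path(out_dir, "bundle"))
      list(edges = bundle$edges, pvalues = bundle$pvalues,
           annotations = bundle$annotations, categories = bundle$categories,
           paths = bundle$paths)
    } else {
      list(edges = read_edge_list(config$edges),
           pvalues = read_pvalue_matrix(config$pvalues),
           annotations = read_annotations(config$annotations),
           categories = read_categories(config$categories),
           paths = list(edges = config$edges, pvalues = config$pvalues,
                        annotations = config$annotations,
                        categories = config$categories))
    }
  })

  networks <- stage("network_build", {
    ppi <- build_ppi(inputs$edges)
    psn <- build_response_graph(inputs$pvalues, config$alpha)
    list(ppi = ppi, psn = psn, joint = joint_degrees(ppi, psn))
  })
  joint <- networks$joint
  written <- character(0)
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(out_dir, name)
    if (is.null(writer)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      writer(obj, path)
    }
    written <<- c(written, path)
    path
  }
  emit(joint, "joint_degrees.tsv", write_joint_degrees)

  topo <- stage("topology", {
    ann <- inputs$annotations
    trait <- function(col) stats::setNames(ann[[col]], ann$gene)
    list(
      fit_ppi = fit_power_law(
        degree_histogram(joint$k_ppi[joint$in_ppi]),
        binning = config$fit_binning),
      fit_psn = fit_power_law(
        degree_histogram(joint$k_psn[joint$in_psn]),
        binning = config$fit_binning),
      plane = fit_joint_plane(joint),
      reciprocity = degree_reciprocity(joint, scope = "intersection"),
      dnds_ppi = degree_trait_association(joint, trait("dnds"), "ppi"),
      dnds_psn = degree_trait_association(joint, trait("dnds"), "psn"),
      cai_ppi = degree_trait_association(joint, trait("cai"), "ppi"),
      cai_psn = degree_trait_association(joint, trait("cai"), "psn")
    )
  })
  jsonlite::write_json(
    lapply(topo, unclass),
    file.path(out_dir, "topology.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(out_dir, "topology.json"))

  cores <- stage("core_decomposition", {
    m_ppi <- config$m_ppi
    if (is.null(m_ppi)) m_ppi <- .default_m_values(joint$k_ppi[joint$in_ppi])
    m_psn <- config$m_psn
    if (is.null(m_psn)) m_psn <- .default_m_values(joint$k_psn[joint$in_psn])
    list(ppi = core_series(networks$ppi, m_ppi),
         psn = core_series(networks$psn, m_psn))
  })
  emit(cores$ppi, "cores_ppi.tsv", write_core_series)
  emit(cores$psn, "cores_psn.tsv", write_core_series)

  retention <- stage("retention", {
    ann <- inputs$annotations
    flag <- function(col) stats::setNames(ann[[col]], ann$gene)
    # disease/drug-target analyses are restricted to homolog-bearing genes
    restrict <- function(f) {
      f[!(ann$human_homolog %in% TRUE)] <- NA
      f
    }
    ppi_genes <- joint$gene[joint$in_ppi]
    psn_genes <- joint$gene[joint$in_psn]
    ppi_edges <- config$ppi_bin_edges
    if (is.null(ppi_edges)) ppi_edges <- dyadic_bin_edges(max(joint$k_ppi))
    psn_edges <- config$psn_bin_edges
    if (is.null(psn_edges)) psn_edges <- dyadic_bin_edges(max(joint$k_psn))
    ers <- list(
      lethal_ppi = er_curve(cores$ppi, flag("lethal"), ppi_genes),
      lethal_psn = er_curve(cores$psn, flag("lethal"), psn_genes),
      disease_ppi = er_curve(cores$ppi, restrict(flag("disease")), ppi_genes),
      disease_psn = er_curve(cores$psn, restrict(flag("disease")), psn_genes),
      drug_ppi = er_curve(cores$ppi, restrict(flag("drug_target")), ppi_genes),
      drug_psn = er_curve(cores$psn, restrict(flag("drug_target")), psn_genes)
    )
    props <- list(
      lethal_ppi = proportion_by_degree_bin(joint, flag("lethal"), "ppi",
                                            ppi_edges),
      lethal_psn = proportion_by_degree_bin(joint, flag("lethal"), "psn",
                                            psn_edges),
      disease_ppi = proportion_by_degree_bin(joint, restrict(flag("disease")),
                                             "ppi", ppi_edges),
      disease_psn = proportion_by_degree_bin(joint, restrict(flag("disease")),
                                             "psn", psn_edges)
    )
    grid <- four_class_grid(joint, ann, ppi_edges, psn_edges)
    list(er = ers, proportions = props, grid = grid,
         ppi_bin_edges = ppi_edges, psn_bin_edges = psn_edges)
  })
  for (nm in names(retention$er)) {
    emit(retention$er[[nm]], paste0("er_", nm, ".tsv"))
  }
  for (nm in names(retention$proportions)) {
    emit(retention$proportions[[nm]], paste0("proportion_", nm, ".tsv"))
  }
  emit(retention$grid, "four_class_grid.tsv")

  enrichment <- stage("enrichment", {
    top_core <- function(series) {
      sizes <- vapply(series, function(s) length(s$member_genes), integer(1))
      series[[max(which(sizes > 0L))]]
    }
    ppi_universe <- joint$gene[joint$in_ppi]
    psn_universe <- joint$gene[joint$in_psn]
    list(
      ppi_top = enrich_categories(
        intersect(top_core(cores$ppi)$member_genes, ppi_universe),
        inputs$categories, ppi_universe, config$q_threshold),
      psn_top = enrich_categories(
        intersect(top_core(cores$psn)$member_genes, psn_universe),
        inputs$categories, psn_universe, config$q_threshold)
    )
  })
  emit(enrichment$ppi_top, "enrichment_ppi_top_core.tsv")
  emit(enrichment$psn_top, "enrichment_psn_top_core.tsv")

  manifest <- list(
    package = "reciprocore",
    version = as.character(utils::packageVersion("reciprocore")),
    parameters = list(
      alpha = config$alpha,
      q_threshold = config$q_threshold,
      fit_binning = config$fit_binning,
      ppi_bin_edges = retention$ppi_bin_edges,
      psn_bin_edges = retention$psn_bin_edges,
      m_ppi = vapply(cores$ppi, `[[`, integer(1), "m"),
      m_psn = vapply(cores$psn, `[[`, integer(1), "m"),
      seed = config$seed,
      synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic)
    ),
    inputs = lapply(inputs$paths, function(p) {
      if (is.character(p) && file.exists(p)) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      } else p
    }),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(inputs = inputs, networks = networks, topology = topo,
                 cores = cores, retention = retention,
                 enrichment = enrichment, manifest = manifest))
}

# Log-spaced m values from 1 to the maximum degree, deduplicated.
.default_m_values <- function(degrees) {
  kmax <- max(degrees)
  m <- unique(round(exp(seq(0, log(kmax), length.out = 12L))))
  as.integer(m[m >= 1L])
}
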