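#!/usr/bin/env Rscript
# Topology of the joint network: marginal power-law exponents (log-binned
# OLS), the joint log-log-log regression plane, degree reciprocity between
# K_PPI and K_PSN, and the degree-trait correlations (dN/dS down, CAI up)
# that mark both hubs as evolutionarily constrained.

suppressPackageStartupMessages(library(reciprocore))

bundle_dir <- "scratch/bundle"
ppi <- build_ppi(read_edge_list(file.path(bundle_dir, "edges.tsv")))
psn <- build_response_graph(read_pvalue_matrix(file.path(bundle_dir, "pvalues.tsv")),
                            alpha = 0.01)
joint <- joint_degrees(ppi, psn)
ann <- read_annotations(file.path(bundle_dir, "annotations.tsv"))
trait <- function(col) setNames(ann[[col]], ann$gene)

fit_ppi <- fit_power_law(degree_histogram(joint$k_ppi[joint$in_ppi]),
                         binning = "log")
fit_psn <- fit_power_law(degree_histogram(joint$k_psn[joint$in_psn]),
                         binning = "log")
plane <- fit_joint_plane(joint)
rec <- degree_reciprocity(joint, scope = "intersection")
print(fit_ppi); print(fit_psn); print(plane); print(rec)

assoc <- list(
  dnds_ppi = degree_trait_association(joint, trait("dnds"), "ppi"),
  dnds_psn = degree_trait_association(joint, trait("dnds"), "psn"),
  cai_ppi = degree_trait_association(joint, trait("cai"), "ppi"),
  cai_psn = degree_trait_association(joint, trait("cai"), "psn")
)
for (nm in names(assoc)) { cat(nm, ": "); print(assoc[[nm]]) }

out <- c(list(fit_ppi = fit_ppi, fit_psn = fit_psn, plane = plane,
              reciprocity = rec), assoc)
jsonlite::write_json(lapply(out, unclass), "results/topology.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("fits and correlations -> results/topology.json\n")
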