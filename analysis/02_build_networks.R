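#!/usr/bin/env Rscript
# Build both networks from the bundle files: collapse the raw interaction
# pairs into a simple undirected PPI graph, threshold the p-value matrix at
# alpha = 0.01 into the directed bipartite PSN, and assemble the per-gene
# joint degree table that every later analysis works from.

suppressPackageStartupMessages(library(reciprocore))

bundle_dir <- "scratch/bundle"
dir.create("results", showWarnings = FALSE)

ppi <- build_ppi(read_edge_list(file.path(bundle_dir, "edges.tsv")))
psn <- build_response_graph(read_pvalue_matrix(file.path(bundle_dir, "pvalues.tsv")),
                            alpha = 0.01)
joint <- joint_degrees(ppi, psn)
write_joint_degrees(joint, "scratch/joint_degrees.tsv")

summary_tab <- data.frame(
  network = c("PPI", "PSN"),
  genes = c(sum(joint$in_ppi), sum(joint$in_psn)),
  edges = c(igraph::ecount(ppi), nrow(psn$edges)),
  k_min = c(min(joint$k_ppi[joint$in_ppi]), min(joint$k_psn[joint$in_psn])),
  k_max = c(max(joint$k_ppi[joint$in_ppi]), max(joint$k_psn[joint$in_psn]))
)
write.table(summary_tab, "results/network_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("PPI:", summary_tab$genes[1], "genes,", summary_tab$edges[1], "edges,",
    "degree range", summary_tab$k_min[1], "-", summary_tab$k_max[1], "\n")
cat("PSN:", summary_tab$genes[2], "genes,", summary_tab$edges[2], "edges,",
    "in-degree range", summary_tab$k_min[2], "-", summary_tab$k_max[2], "\n")
cat("genes in both networks:", sum(joint$in_ppi & joint$in_psn), "\n")
cat("joint degree table -> scratch/joint_degrees.tsv\n")
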