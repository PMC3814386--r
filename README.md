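# reciprocore

Joint analysis of two reciprocally scale-free yeast gene networks: a
protein–protein interaction network (PPI) and a perturbation sensitivity
network (PSN).

## The problem

Essential ("lethal") genes concentrate in the hubs of the protein
interactome, while disease genes famously do not — they sit in its
periphery. That looks like a paradox only if the interactome is treated as
*the* biological network. The PSN offers a second axis: a directed
bipartite graph from deletion mutants to the genes whose expression each
mutant significantly alters (p < 0.01 per gene–mutant pair), where a gene's
in-degree S_i = K_PSN measures its transcriptional sensitivity to genetic
perturbation. Both networks have power-law degree distributions,
P(k) ∝ k^−γ, but their degree vectors are *negatively* correlated: PPI hubs
are PSN periphery and vice versa. Along those two opposed core hierarchies,
lethal genes enrich toward the PPI core while disease and drug-target genes
enrich toward the PSN core.

`reciprocore` is for computational biologists who want to run or scrutinise
this style of analysis end to end: build both networks from tabular inputs,
fit the marginal exponents γ_PPI and γ_PSN and the joint "regression plane"
of the log joint-degree distribution, decompose both networks into m-cores
by iterative peeling, and quantify annotation classes across cores with the
excess-retention statistic

    ER_A(m) = (n_m^A / n_m) / (N^A / N)

plus hypergeometric category enrichment under Benjamini–Hochberg FDR
control. A synthetic-data generator with planted exponents, a signed
Gaussian copula between the two degree sequences and monotone annotation
effects makes every stage verifiable against a known ground truth — no
external downloads, no live databases.

## Worked example

```r
library(reciprocore)

cfg    <- synthetic_config(n_genes = 2000, n_mutants = 120, seed = 42)
bundle <- simulate_bundle(cfg)

ppi   <- build_ppi(bundle$edges)
psn   <- build_response_graph(bundle$pvalues, alpha = 0.01)
joint <- joint_degrees(ppi, psn)
psn
#> Perturbation sensitivity network (directed bipartite)
#>   genes: 1504  mutants: 120  edges: 3148
#>   alpha: 0.01  in-degree range: 1 - 35

fit_power_law(degree_histogram(joint$k_ppi[joint$in_ppi]), binning = "log")
#> Power-law fit (log, kmin=1): gamma = 2.350, R^2 = 0.996, 5 points

degree_reciprocity(joint)
#> pearson r = -0.0585, two-sided p = 0.0233, n = 1504

series <- core_series(ppi, 1:10)
lethal <- setNames(bundle$annotations$lethal, bundle$annotations$gene)
er     <- er_curve(series, lethal, joint$gene[joint$in_ppi])
er[er$n_m > 0, ]
#>   m  n_m n_m_A       er
#> 1 1 2000   442 1.000000
#> 2 2  288   149 2.341001
#> 3 3   84    64 3.447533
#> 4 4   21    20 4.309416
```

Reading the output: the planted exponent (2.48) is recovered as 2.35 from
2000 genes; the two degree vectors are negatively correlated (r = −0.06,
the weak-but-significant signature of reciprocal topology on heavy-tailed
margins); and lethal genes, planted to favour PPI hubs, climb from the
baseline ER = 1 in the full network to ER ≈ 4.3 in the 4-core. Running the
same curve over `core_series(psn, ...)` shows the mirrored depletion.

The same machinery consumes real data via `read_edge_list()`,
`read_pvalue_matrix()`, `read_annotations()` and `read_categories()`, or
one call to `run_pipeline(run_config(...))` which writes every table plus a
checksummed run manifest.

## Analysis workflow

The `analysis/` directory holds the full study as numbered drivers over the
package (`01_simulate.R` … `06_enrichment.R`): generate the bundle, build
both networks, fit the topology, peel the cores, trace excess retention and
the four-class lethal × disease grid, and test category enrichment of both
deep cores. Small summary tables land in `results/`, bulky intermediates in
`scratch/`. Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

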