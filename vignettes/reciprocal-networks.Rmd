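---
title: "Reciprocal scale-free networks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal scale-free networks: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciprocore)
```

## The two networks and why they are analysed jointly

`reciprocore` analyses two yeast gene networks built over (largely) the same
genes but encoding unrelated kinds of biology:

* the **protein–protein interaction network (PPI)** — an undirected simple
  graph of physical binding between gene products; a gene's degree
  $K_{PPI}$ counts its distinct interaction partners;
* the **perturbation sensitivity network (PSN)** — a directed bipartite
  graph from deletion mutants to genes. An edge $j \to i$ exists when the
  expression of gene $i$ is significantly altered in deletion mutant $j$,
  as judged by a per-pair p-value thresholded strictly at
  $\alpha = 0.01$. A gene's in-degree $S_i$ (written $K_{PSN}$) measures
  how sensitive its transcription is to random genetic perturbation.

Both degree distributions are approximately power laws,
$P(k) \propto k^{-\gamma}$, and the interesting structure is *joint*: the
two degree vectors are negatively correlated, so hubs of one network tend
to sit in the periphery of the other. The package quantifies that
reciprocity three ways — a Pearson correlation between $K_{PPI}$ and
$K_{PSN}$, a regression plane through the log joint-degree distribution,
and the opposing excess-retention profiles of lethal versus disease genes
across the two core hierarchies.

## Statistics implemented

**Power-law exponent.** `fit_power_law()` performs ordinary least squares
of $\log_{10}$ frequency on $\log_{10}$ degree, the classical read-off used
for "approximate exponents" of degree-distribution plots. Maximum-likelihood
(Clauset-style) estimation and goodness-of-fit testing of the power-law
hypothesis are deliberately out of scope. Two binning modes exist:

* `raw` (default): one point per distinct degree. Faithful to the plotted
  distribution but biased toward shallow slopes on sampled data, because
  the sparse tail contributes many low-count points.
* `log`: factor-2 geometric bins; each contributes
  (geometric centre, pooled count / bin width). Bins pooling fewer than
  `min_bin_count = 10` nodes are excluded. The cut-off matters: a
  near-empty bin has enormous relative noise in log space and the fact that
  only *occupied* bins can enter the fit inflates the far tail, flattening
  the slope. With the cut-off, planted exponents $\gamma \in \{2, 2.5, 3\}$
  are recovered within $\pm 0.15$ from 20 000 sampled degrees; without it,
  errors exceed 0.5 at $\gamma = 3$.

**Joint plane.** `fit_joint_plane()` tabulates genes belonging to both
networks into raw integer $(K_{PPI}, K_{PSN})$ cells and fits
$\log_{10} f = a_0 + b_{PPI}\log_{10}k_{PPI} + b_{PSN}\log_{10}k_{PSN}$
over occupied cells. For a reciprocal pair of scale-free networks both
slopes are negative. Cells are not binned for the fit (binned variants are
for display only).

**Degree reciprocity.** `degree_reciprocity()` computes Pearson's $r$
between the two degree vectors with a two-sided t-test. The `scope`
parameter chooses between genes present in both networks
(`"intersection"`, default) and all genes with absence counted as degree 0
(`"union"`). The scope is exposed rather than fixed because published
analyses of this kind are often ambiguous about it, and the two choices
give visibly different $n$; we make no claim that one of them reproduces
any particular printed p-value. Two-sided p-values are used throughout the
package.

**m-cores.** The $m$-core of the PPI is the standard k-core: the maximal
vertex set in which every member keeps at least $m$ neighbours, computed by
iteratively peeling lower-degree vertices (`peel_core()`; the result is
order-independent, which the tests verify against an order-randomised
exhaustive oracle and against `igraph::coreness()`). Some definitions take
"the" m-core to be a single maximal connected subgraph; `peel_core()`
reports the component partition and `largest_component` for that reading,
but `member_genes` is the union of components. The union preserves
nestedness ($m{+}1$-core $\subseteq$ $m$-core), which the excess-retention
curves implicitly assume. In the PSN only genes carry the degree condition
($S_i \ge m$); mutants are scaffolding. Because every edge runs
mutant$\to$gene, peeling genes cannot change another gene's in-degree, so
`peel_core_psn()` needs no iteration — a property asserted against an
iterative reference implementation.

**Excess retention.** For an annotation class $A$,
$$ER_A(m) = \frac{n_m^A / n_m}{N^A / N},$$
the representation of $A$ inside the $m$-core relative to the whole group
(the 1-core). `er_curve()` evaluates it along a core series. Conventions:

* the universe is the set of genes with *known* annotation inside the
  relevant network's 1-core, so $ER(1) = 1$ identically; genes with
  unknown annotation are excluded from numerator and denominator alike;
* disease and drug-target universes are additionally restricted to genes
  with a human homolog, because those annotations are only defined through
  the homolog;
* an empty core yields an undefined ER, reported as `NA`, never as 0;
  a zero baseline ($N^A = 0$) is an error.

When a single "deep core" number is needed (analysis scripts, acceptance
summaries), it is taken at the largest $m$ whose core still holds at least
30 annotation-known genes — a stability rule fixed a priori, since the very
top of a core hierarchy may hold a handful of genes whose ER is mostly
noise.

**Enrichment.** `enrich_categories()` tests each flat functional category
for over-representation in a gene subset by the upper-tail hypergeometric
probability $P(X \ge k)$, BH-adjusts across categories (`bh_adjust()`,
`stats::p.adjust` under the hood) and flags categories at $q < 0.01$. Only
enrichment is tested, not depletion. Degree-bin tables
(`proportion_by_degree_bin()`) and the four-class lethal-by-disease grid
(`four_class_grid()`, with whole-axis marginal cells) complete the
annotation analyses. Degree bins default to powers of two
(`dyadic_bin_edges()`): the bin scheme is a recorded configuration value,
not a hard-coded constant, because heavy-tailed degrees make linear bins
useless and any published figure of this kind depends on the chosen edges.

## The synthetic-data generator

`simulate_bundle()` / `generate_bundle()` produce a complete, fully
labelled input bundle so that every stage of the pipeline can be verified
against a planted ground truth without any external data:

1. **Coupled degrees.** A latent standard bivariate normal with correlation
   $\rho$ is pushed through the inverse CDFs of two truncated discrete
   power laws (Gaussian copula, `coupled_degree_pair()`). Margins are exact
   by construction; the rank dependence keeps the sign of $\rho$ but is
   attenuated by discreteness — with the default margins roughly 60% of
   genes have $k = 1$, and the measured Spearman correlation at
   $\rho = -0.9$ is about $-0.39$. The attenuation is measured, never
   assumed. A copula was preferred over degree-targeted rewiring because it
   controls margins and dependence independently.
2. **PPI realisation.** Configuration-model stub matching with self-loops
   and multi-edges discarded (`ppi_from_degrees()`). Realised degrees can
   fall below target (the mean relative deficit is under 5% at the default
   truncation $k_{max} = n/10$, which keeps the sequence realisable as a
   simple graph); targets are stored per vertex for diagnosis.
3. **Planted PSN.** For each gene, $k_{PSN}$ distinct mutants get p-values
   from $U(0, \alpha)$ and all other cells from $U(\alpha, 1)$
   (`pmatrix_from_indegrees()`), so thresholding at $\alpha$ recovers the
   planted bipartite graph *exactly* — the identity the network-build tests
   and the acceptance checks rely on.
4. **Annotations.** With $z$ the standardised $\log(1+k_{PPI})$ minus the
   standardised $\log(1+k_{PSN})$ ($\log(1+k)$ rather than $\log k$ because
   genes outside one network carry $k = 0$), lethality is
   Bernoulli-logistic in $+z$ and disease in $-z$. Disease is sampled only
   among non-lethal homolog-bearing genes; lethal homolog genes are
   recorded as known non-disease (the four grid classes are exclusive, so
   the lethal-disease cell is structurally empty in synthetic data) and
   genes without a homolog have unknown disease status. dN/dS falls and CAI
   rises with the mean standardised log-degree, with log-normal/logit-normal
   noise; a share of trait values is masked missing to exercise the
   known-annotation exclusion rules.
5. **Categories.** Random gene sets plus one PPI-degree-biased set, so the
   enrichment machinery has one true positive and a calibrated null.

Default parameters are the study conditions: $n = 5000$ genes, 212
mutants, $\gamma_{PPI} = 2.48$, $\gamma_{PSN} = 2.24$, $\alpha = 0.01$,
$\rho = -0.5$, 75% PSN membership, $k_{max}^{PSN} = 50$, logistic
intercepts $-1.6$/$-1.5$ (about 18–19% positive classes, matching the
lethal and disease base rates of the yeast annotation corpus this emulates)
and slopes $0.8$, strong enough that the planted reciprocal enrichment is
unambiguous at $n = 5000$ (the field's rule of thumb that hub deletions are
roughly three times as often lethal as peripheral ones lands in this
range). All randomness flows from one mandatory seed through fixed
per-stage substreams; identical configs give byte-identical bundles.

What the generator does **not** emulate: the error model behind real
perturbation p-values (only the threshold interface is planted), dependence
between annotations beyond the planted degree effects, any community or
motif structure in the PPI beyond what the configuration model induces, and
identifier aliasing (IDs are taken as given). Passing tests therefore
demonstrate the correctness and power of the *pipeline*, not biological
conclusions about real data.

## Numerical conventions and degenerate inputs

* Thresholding is strict (`p < alpha`); a cell exactly at `alpha` makes no
  edge. Missing p-values mean "no evidence", never an edge, never 0 or 1.
* Genes never significantly perturbed are *excluded from* the PSN (they are
  not members with $K_{PSN} = 0$); membership flags in the joint degree
  table record this, and a minimum in-degree is simply $m = 1$ of the core
  series.
* All tabular outputs order genes lexicographically; components are sorted
  largest-first with lexicographic tie-break on the first member.
* Reals are serialised with 17 significant digits, so every table
  round-trips through disk bit-exactly.
* Correlations require $n \ge 3$ and non-zero variance; power-law fits
  require three positive-count points; the joint plane requires four
  occupied cells. Violations raise errors rather than returning NaN.
* Degenerate generator inputs (constant degrees, zero slopes, odd stub
  sums) are handled explicitly: standardisation of a constant vector falls
  back to 0, an odd degree sum increments one random stub and records it.

## Problem sizes

The default test-and-verification scales are 20 000 degree draws for
exponent recovery, $n = 5000$ genes for the end-to-end bundle, 200 random
graphs (with at most 60 vertices) for the peeling oracle, a full
enumeration sweep at $N \le 12$ for the hypergeometric tail, and 1000
replicates for the BH null calibration — sizes at which every check runs in
seconds while leaving no parameter of interest unexercised.

## Known limitations

* OLS on log-log frequencies, while the field's classic, is a biased
  estimator of $\gamma$ compared to discrete maximum likelihood; it is kept
  because it is the method the "approximate exponent" tradition defines,
  and its accuracy at the study scales is quantified in the tests.
* The configuration model yields slightly sub-target hub degrees; analyses
  are always run on *realised* degrees, so this is a property of the
  simulated world, not an inconsistency.
* ER has no attached inferential measure here (no confidence band); the
  hypergeometric/FDR machinery covers the category analyses, and the
  binomial-band property test covers ER's null behaviour.
* The PSN core's component structure depends on mutants shared between
  retained genes; alternative readings that peel mutants by out-degree are
  not implemented (only genes carry the degree condition).
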