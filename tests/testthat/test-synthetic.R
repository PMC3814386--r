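test_that("truncated power-law sampler matches its exact pmf", {
  expect_error(sample_powerlaw_degrees(10, 2.5, 5, 5, seed = 1), "kmin < kmax")
  expect_error(sample_powerlaw_degrees(10, 0.9, 1, 10, seed = 1), "gamma")

  # mass concentrates at kmin for a steep exponent
  d <- sample_powerlaw_degrees(2000, 50, 1, 100, seed = 2)
  expect_gt(mean(d == 1), 0.99)

  # chi-square against the exact pmf, tail pooled so expected counts >= 5
  n <- 20000
  d <- sample_powerlaw_degrees(n, 2.5, 1, 1000, seed = 3)
  pmf <- (1:1000)^-2.5
  pmf <- pmf / sum(pmf)
  expected <- n * pmf
  cut <- max(which(expected >= 5))
  obs <- c(tabulate(d, nbins = 1000)[1:cut], sum(d > cut))
  expc <- c(expected[1:cut], sum(expected[-(1:cut)]))
  chisq <- sum((obs - expc)^2 / expc)
  p <- pchisq(chisq, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("copula coupling preserves margins and carries the sign of rho", {
  expect_error(coupled_degree_pair(10, 2.5, 2.5, 1.0, 1, 50, 20, seed = 1),
               "rho")

  cp0 <- coupled_degree_pair(10000, 2.48, 2.24, 0, 1, 500, 50, seed = 2)
  expect_lt(abs(cor(cp0$k_ppi, cp0$k_psn, method = "spearman")), 0.03)

  # strong negative latent correlation survives discretisation with the
  # right sign; the magnitude is attenuated by the ties at k = 1
  # (measured ~ -0.385 at these margins across seeds)
  cpn <- coupled_degree_pair(10000, 2.48, 2.24, -0.9, 1, 500, 50, seed = 2)
  expect_lt(cor(cpn$k_ppi, cpn$k_psn, method = "spearman"), -0.3)

  # margins are not disturbed by the coupling: compare against independent
  # draws from the same margin with a chi-square on pooled bins
  margin_chisq <- function(k, gamma, kmax) {
    pmf <- (1:kmax)^-gamma
    pmf <- pmf / sum(pmf)
    expected <- length(k) * pmf
    cut <- max(which(expected >= 5))
    obs <- c(tabulate(k, nbins = kmax)[1:cut], sum(k > cut))
    expc <- c(expected[1:cut], sum(expected[-(1:cut)]))
    pchisq(sum((obs - expc)^2 / expc), df = length(obs) - 1,
           lower.tail = FALSE)
  }
  expect_gt(margin_chisq(cpn$k_ppi, 2.48, 500), 0.01)
  expect_gt(margin_chisq(cpn$k_psn, 2.24, 50), 0.01)
})

test_that("configuration model realises degree sequences with small deficit", {
  g <- ppi_from_degrees(c(a = 1L, b = 1L), seed = 1)
  expect_equal(igraph::ecount(g), 1)

  # a simple stub pairing of (2,2,2) is the triangle; non-simple pairings
  # lose edges to the discard rule, so fix a seed whose pairing is simple
  g3 <- ppi_from_degrees(c(x = 2L, y = 2L, z = 2L), seed = 1)
  expect_equal(sort(as.integer(igraph::degree(g3))), c(2L, 2L, 2L))

  # odd degree sum: one stub is incremented and recorded
  godd <- ppi_from_degrees(c(a = 1L, b = 1L, c = 1L), seed = 3)
  expect_false(is.na(igraph::graph_attr(godd, "stub_incremented")))

  deg <- sample_powerlaw_degrees(5000, 2.5, 1, 500, seed = 9)
  gl <- ppi_from_degrees(deg, seed = 10)
  tgt <- igraph::V(gl)$target_degree
  realized <- as.integer(igraph::degree(gl))
  expect_lt(mean((tgt - realized) / pmax(tgt, 1)), 0.05)
  expect_error(ppi_from_degrees(c(a = 2L), seed = 1), "at least 2")
})

test_that("planted p-value matrix thresholds back to the planted edges", {
  p <- pmatrix_from_indegrees(c(g1 = 2L, g2 = 0L), 3, 0.01, seed = 4)
  rg <- build_response_graph(p, 0.01)
  expect_equal(unname(rg$in_degree["g1"]), 2L)
  expect_false("g2" %in% rg$genes)
  expect_true(all(p != 0.01))

  expect_error(pmatrix_from_indegrees(c(g1 = 5L), 3, 0.01, seed = 1),
               "exceeds")
})

test_that("annotation effects vanish when slopes are zero and appear when planted", {
  cfg0 <- tiny_config(seed = 71, n_genes = 2000L, n_mutants = 100L,
                      lethal_slope = 0)
  joint <- data.frame(gene = sprintf("g%05d", 1:2000),
                      coupled_degree_pair(2000, 2.48, 2.24, -0.5, 1, 200, 50,
                                          seed = 72))
  ann0 <- annotate_genes(joint, cfg0, seed = 73)
  # no planted effect: lethality is independent of the degree contrast
  z <- scale(log1p(joint$k_ppi)) - scale(log1p(joint$k_psn))
  trend <- cor.test(as.numeric(z), as.numeric(ann0$lethal), exact = FALSE)
  expect_gt(trend$p.value, 0.05)

  cfg1 <- tiny_config(seed = 71, n_genes = 2000L, n_mutants = 100L)
  ann1 <- annotate_genes(joint, cfg1, seed = 73)
  trend1 <- cor.test(as.numeric(z), as.numeric(ann1$lethal),
                     alternative = "greater", exact = FALSE)
  expect_lt(trend1$p.value, 1e-6)

  # disease is known only for homolog genes and exclusive with lethality
  expect_true(all(is.na(ann1$disease[!ann1$human_homolog])))
  expect_true(all(!ann1$disease[ann1$human_homolog & ann1$lethal]))
})

test_that("bundles are deterministic and recover the planted structure end to end", {
  cfg <- tiny_config(seed = 85, n_genes = 400L, n_mutants = 60L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  for (f in c("edges.tsv", "pvalues.tsv", "annotations.tsv", "categories.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  for (fld in c("n_genes", "gamma_ppi", "rho", "alpha", "seed")) {
    expect_equal(manifest[[fld]], cfg[[fld]])
  }

  # reading the files back and thresholding recovers the planted PSN exactly
  p <- read_pvalue_matrix(file.path(d1, "pvalues.tsv"))
  rg <- build_response_graph(p, cfg$alpha)
  expect_identical(rg$edges, b1$truth$planted_edges)
})
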