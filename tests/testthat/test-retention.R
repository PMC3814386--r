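test_that("excess retention computes the ratio of fractions and signals edge cases", {
  expect_equal(excess_retention(100, 10, 20, 4), 2.0)
  expect_equal(excess_retention(100, 10, 100, 10), 1.0)  # 1-core = whole set
  expect_equal(excess_retention(100, 10, 20, 0), 0.0)
  expect_true(is.na(excess_retention(100, 10, 0, 0)))    # empty core: undefined
  expect_error(excess_retention(100, 0, 20, 4), "N_A")
  expect_error(excess_retention(100, 10, 20, 25), "inconsistent")
})

test_that("er_curve equals 1 at m=1 and tracks a planted degree effect", {
  bundle <- simulate_bundle(tiny_config(seed = 61, n_genes = 1500L,
                                        n_mutants = 100L))
  nets <- bundle_networks(bundle)
  ann <- bundle$annotations
  lethal <- named_flag(ann, "lethal")

  ppi_universe <- nets$joint$gene[nets$joint$in_ppi]
  series <- core_series(nets$ppi, c(1L, 2L, 3L, 4L))
  er <- er_curve(series, lethal, ppi_universe)
  expect_equal(er$er[er$m == 1], 1.0)
  # lethality is planted to rise with k_ppi: the deepest non-empty core is
  # enriched beyond the 1-core baseline
  top <- max(which(er$n_m > 0))
  expect_gt(er$er[top], 1)
  expect_gt(er$er[top], er$er[1])

  # and to fall with k_psn: the deepest PSN core is depleted
  psn_series <- core_series(nets$psn, c(1L, 2L, 4L, 8L))
  psn_universe <- nets$joint$gene[nets$joint$in_psn]
  er_psn <- er_curve(psn_series, lethal, psn_universe)
  top_psn <- max(which(er_psn$n_m > 0))
  expect_lt(er_psn$er[top_psn], 1)

  # an all-positive annotation has ER 1 everywhere the core is non-empty
  all_pos <- stats::setNames(rep(TRUE, length(ppi_universe)), ppi_universe)
  er_all <- er_curve(series, all_pos, ppi_universe)
  expect_true(all(er_all$er[er_all$n_m > 0] == 1))

  expect_error(er_curve(series, lethal, character(0)), "empty universe")
})

test_that("a uniformly random annotation stays inside the 95% binomial band around ER = 1", {
  bundle <- simulate_bundle(tiny_config(seed = 62, n_genes = 1200L,
                                        n_mutants = 80L))
  nets <- bundle_networks(bundle)
  universe <- nets$joint$gene[nets$joint$in_ppi]
  set.seed(63)
  p0 <- 0.3
  flag <- stats::setNames(runif(length(universe)) < p0, universe)
  series <- core_series(nets$ppi, c(1L, 2L, 3L))
  er <- er_curve(series, flag, universe)
  N_A <- sum(flag)
  base <- N_A / length(universe)
  for (i in which(er$n_m > 0)) {
    lo <- qbinom(0.025, er$n_m[i], base) / er$n_m[i] / base
    hi <- qbinom(0.975, er$n_m[i], base) / er$n_m[i] / base
    expect_gte(er$er[i], lo)
    expect_lte(er$er[i], hi)
  }
})

test_that("hypergeometric p-value matches exhaustive enumeration and identities", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), hyper_oracle(10, 5, 4, 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(30, 7, 9, 0), 1.0)
  # n = N forces full overlap: p = 1 at k = K
  expect_equal(hypergeom_pvalue(8, 3, 8, 3), 1.0)
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "inconsistent")
  expect_error(hypergeom_pvalue(10, 12, 4, 2), "inconsistent")
})

test_that("BH adjustment reproduces hand-computed step-up values and is permutation-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  set.seed(9)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})

test_that("category enrichment ranks a fully recovered category first", {
  universe <- sprintf("g%03d", 1:200)
  cats <- list(A = universe[1:20], B = universe[30:60], C = universe[150:170])
  res <- enrich_categories(universe[1:20], cats, universe, q_threshold = 0.01)
  expect_equal(res$category_id[1], "A")
  expect_equal(res$k[res$category_id == "A"], 20L)
  expect_true(res$significant[1])
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # a category with no member in the universe is dropped
  cats$D <- c("zz1", "zz2")
  res2 <- enrich_categories(universe[1:20], cats, universe)
  expect_false("D" %in% res2$category_id)

  expect_error(enrich_categories(character(0), cats, universe), "empty subset")
  expect_error(enrich_categories(c("zz9"), cats, universe), "outside")
})

test_that("proportion-by-degree-bin reflects a planted monotone lethality effect", {
  bundle <- simulate_bundle(tiny_config(seed = 64, n_genes = 2000L,
                                        n_mutants = 100L))
  nets <- bundle_networks(bundle)
  lethal <- named_flag(bundle$annotations, "lethal")
  edges <- dyadic_bin_edges(max(nets$joint$k_ppi))
  tab <- proportion_by_degree_bin(nets$joint, lethal, "ppi", edges)
  expect_equal(sum(tab$n_known), sum(nets$joint$in_ppi))
  # one-sided trend: proportion rises with the bin index where estimable
  est <- tab[tab$n_known >= 20, ]
  trend <- cor.test(seq_len(nrow(est)), est$proportion, method = "spearman",
                    alternative = "greater", exact = FALSE)
  expect_lt(trend$p.value, 0.05)

  # single bin covering everything returns the global positive fraction
  all_bin <- proportion_by_degree_bin(
    nets$joint, lethal, "ppi", c(1L, max(nets$joint$k_ppi)))
  known <- lethal[nets$joint$gene[nets$joint$in_ppi]]
  expect_equal(all_bin$proportion, mean(known, na.rm = TRUE))

  # all-positive annotation: proportion 1 in every non-empty bin
  all_pos <- stats::setNames(rep(TRUE, nrow(nets$joint)), nets$joint$gene)
  tab2 <- proportion_by_degree_bin(nets$joint, all_pos, "ppi", edges)
  expect_true(all(tab2$proportion[tab2$n_known > 0] == 1))

  expect_error(proportion_by_degree_bin(nets$joint, lethal, "ppi", c(4, 2)),
               "strictly increasing")
})

test_that("four-class grid counts are conserved and mirror the planted reciprocity", {
  t <- data.frame(gene = c("a", "b", "c", "d"),
                  k_ppi = c(1L, 1L, 1L, 1L), k_psn = c(1L, 1L, 1L, 1L),
                  in_ppi = TRUE, in_psn = TRUE)
  catalog <- data.frame(gene = c("a", "b", "c", "d"),
                        lethal = c(TRUE, TRUE, FALSE, FALSE),
                        disease = c(TRUE, FALSE, TRUE, FALSE))
  grid <- four_class_grid(t, catalog, c(1L, 2L), c(1L, 2L))
  cell <- grid[grid$ppi_bin == 1 & grid$psn_bin == 1, ]
  expect_equal(unlist(cell[c("lethal_disease", "lethal_only",
                             "disease_only", "neither")]),
               c(lethal_disease = 1L, lethal_only = 1L,
                 disease_only = 1L, neither = 1L))

  bundle <- simulate_bundle(tiny_config(seed = 65, n_genes = 3000L,
                                        n_mutants = 150L))
  nets <- bundle_networks(bundle)
  ppi_edges <- dyadic_bin_edges(max(nets$joint$k_ppi))
  psn_edges <- dyadic_bin_edges(max(nets$joint$k_psn))
  grid2 <- four_class_grid(nets$joint, bundle$annotations, ppi_edges, psn_edges)
  cells <- grid2[grid2$ppi_bin > 0 & grid2$psn_bin > 0, ]
  ppi_marg <- grid2[grid2$psn_bin == 0, ]
  psn_marg <- grid2[grid2$ppi_bin == 0, ]
  for (cls in c("lethal_disease", "lethal_only", "disease_only", "neither")) {
    expect_equal(sum(cells[[cls]]), sum(ppi_marg[[cls]]))
    expect_equal(sum(cells[[cls]]), sum(psn_marg[[cls]]))
  }
  expect_equal(cells$total,
               cells$lethal_disease + cells$lethal_only +
                 cells$disease_only + cells$neither)

  # reciprocal pattern: lethal-only fraction rises along the PPI margin,
  # disease-only fraction rises along the PSN margin
  occ_p <- ppi_marg[ppi_marg$total >= 15, ]
  expect_gt(occ_p$lethal_only[nrow(occ_p)] / occ_p$total[nrow(occ_p)],
            occ_p$lethal_only[1] / occ_p$total[1])
  occ_s <- psn_marg[psn_marg$total >= 15, ]
  expect_gt(occ_s$disease_only[nrow(occ_s)] / occ_s$total[nrow(occ_s)],
            occ_s$disease_only[1] / occ_s$total[1])

  expect_error(four_class_grid(t[integer(0), ], catalog, c(1L, 2L), c(1L, 2L)),
               "no gene")
})
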