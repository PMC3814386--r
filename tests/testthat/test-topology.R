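test_that("degree_histogram tabulates and validates", {
  h <- degree_histogram(c(1, 1, 2, 3))
  expect_equal(h$k, c(1L, 2L, 3L))
  expect_equal(h$count, c(2L, 1L, 1L))
  expect_equal(attr(h, "total"), 4L)
  expect_equal(degree_histogram(c(2, 2, 2))$count, 3L)
  expect_equal(degree_histogram(5)$k, 5L)
  expect_error(degree_histogram(integer(0)), "no degrees")
  expect_error(degree_histogram(c(0, 1)), ">= 1")
})

test_that("raw OLS fit recovers an exactly log-linear distribution", {
  k <- 1:100
  h <- data.frame(k = k, count = round(1e6 * k^-2))
  f <- fit_power_law(h, binning = "raw")
  expect_equal(f$gamma, 2, tolerance = 1e-3)
  expect_gt(f$r_squared, 0.999999)

  # flat counts: slope 0
  f0 <- fit_power_law(data.frame(k = 1:10, count = 7L), binning = "raw")
  expect_equal(f0$gamma, 0)

  # exponent invariant to scaling all counts; intercept absorbs it
  h2 <- h
  h2$count <- h$count * 10L
  f2 <- fit_power_law(h2, binning = "raw")
  expect_equal(f2$gamma, f$gamma, tolerance = 1e-6)
  expect_equal(f2$intercept, f$intercept + 1, tolerance = 1e-6)

  expect_error(fit_power_law(data.frame(k = c(1, 2), count = c(5, 3))),
               ">= 3 points")
})

test_that("log-binned fit recovers planted exponents from sampled degrees", {
  # tolerance checked empirically at these seeds before freezing
  for (gamma in c(2.0, 2.5, 3.0)) {
    deg <- sample_powerlaw_degrees(20000, gamma, 1, 1000,
                                   seed = 100 + round(10 * gamma))
    f <- fit_power_law(degree_histogram(deg), binning = "log")
    expect_equal(f$gamma, gamma, tolerance = 0.2 / gamma)
  }
})

test_that("joint plane fit recovers an exactly planar cell table", {
  # 27648 / (k1 * k2^1.5) is an exact integer on this grid, so the planted
  # plane (a0 = log10 27648, b_ppi = -1, b_psn = -1.5) is exactly log-linear
  cells <- expand.grid(k_ppi = c(1L, 2L, 4L, 8L, 16L),
                       k_psn = c(1L, 4L, 9L, 16L))
  freq <- 27648 / (cells$k_ppi * cells$k_psn^1.5)
  stopifnot(all(freq == round(freq)))
  # expand back to per-gene rows so the fit re-tabulates the cells
  t <- data.frame(
    gene = sprintf("g%06d", seq_len(sum(freq))),
    k_ppi = rep(cells$k_ppi, freq),
    k_psn = rep(cells$k_psn, freq),
    in_ppi = TRUE, in_psn = TRUE
  )
  f <- fit_joint_plane(t)
  expect_equal(f$a0, log10(27648), tolerance = 1e-10)
  expect_equal(f$b_ppi, -1.0, tolerance = 1e-10)
  expect_equal(f$b_psn, -1.5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$n_cells, 20L)

  # frequencies independent of k_psn give b_psn = 0
  freq2 <- 10000 / cells$k_ppi
  t2 <- data.frame(
    gene = sprintf("h%06d", seq_len(sum(freq2))),
    k_ppi = rep(cells$k_ppi, freq2),
    k_psn = rep(cells$k_psn, freq2),
    in_ppi = TRUE, in_psn = TRUE
  )
  expect_equal(fit_joint_plane(t2)$b_psn, 0, tolerance = 1e-10)

  expect_error(fit_joint_plane(t[t$k_ppi == 1 & t$k_psn == 1, ]),
               ">= 4 occupied cells")
})

test_that("degree reciprocity handles perfect correlation and is symmetric", {
  t_neg <- data.frame(gene = c("a", "b", "c"), k_ppi = 1:3, k_psn = 3:1,
                      in_ppi = TRUE, in_psn = TRUE)
  expect_equal(degree_reciprocity(t_neg)$r, -1)
  t_pos <- data.frame(gene = c("a", "b", "c"), k_ppi = 1:3, k_psn = 1:3,
                      in_ppi = TRUE, in_psn = TRUE)
  expect_equal(degree_reciprocity(t_pos)$r, 1)

  # symmetric in the two coordinates
  set.seed(4)
  t3 <- data.frame(gene = sprintf("g%02d", 1:30),
                   k_ppi = sample(1:20, 30, TRUE),
                   k_psn = sample(1:20, 30, TRUE),
                   in_ppi = TRUE, in_psn = TRUE)
  swapped <- transform(t3, k_ppi = t3$k_psn, k_psn = t3$k_ppi)
  expect_equal(degree_reciprocity(t3)$r, degree_reciprocity(swapped)$r)

  t_const <- transform(t3, k_psn = 5L)
  expect_error(degree_reciprocity(t_const), "zero variance")
  expect_error(degree_reciprocity(t3[1:2, ]), "n >= 3")
})

test_that("degree-trait association excludes missing traits and hits identities", {
  t <- data.frame(gene = sprintf("g%02d", 1:20), k_ppi = 1:20,
                  k_psn = rep(1L, 20), in_ppi = TRUE, in_psn = TRUE)
  trait <- stats::setNames(as.numeric(1:20), t$gene)
  expect_equal(degree_trait_association(t, trait, "ppi")$r, 1)
  expect_equal(degree_trait_association(t, 100 - trait, "ppi")$r, -1)

  trait_na <- trait
  trait_na[1:5] <- NA
  expect_equal(degree_trait_association(t, trait_na, "ppi")$n, 15L)

  # spearman variant on a monotone nonlinear trait
  expect_equal(degree_trait_association(t, exp(trait), "ppi",
                                        method = "spearman")$r, 1)
})

test_that("synthetic bundle shows negative reciprocity, negative plane slopes and planted trait signs", {
  bundle <- simulate_bundle(tiny_config(seed = 92, n_genes = 2000L,
                                        n_mutants = 120L))
  nets <- bundle_networks(bundle)
  rec <- degree_reciprocity(nets$joint)
  expect_lt(rec$r, 0)

  pl <- fit_joint_plane(nets$joint)
  expect_lt(pl$b_ppi, 0)
  expect_lt(pl$b_psn, 0)

  ann <- bundle$annotations
  dnds <- stats::setNames(ann$dnds, ann$gene)
  expect_lt(degree_trait_association(nets$joint, dnds, "ppi")$r, 0)
  expect_lt(degree_trait_association(nets$joint, dnds, "psn")$r, 0)
  cai <- stats::setNames(ann$cai, ann$gene)
  expect_gt(degree_trait_association(nets$joint, cai, "ppi")$r, 0)
  expect_gt(degree_trait_association(nets$joint, cai, "psn")$r, 0)
})
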