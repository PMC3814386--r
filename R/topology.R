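#' Degree frequency table
#'
#' @param degrees Integer vector of node degrees, all >= 1.
#' @return Data.frame with columns `k` (strictly increasing) and `count`,
#'   zero-count degrees omitted; attribute `total` = number of nodes.
#' @export
degree_histogram <- function(degrees) {
  if (length(degrees) == 0L) stop("no degrees supplied")
  degrees <- as.integer(degrees)
  if (any(is.na(degrees)) || any(degrees < 1L)) {
    stop("degrees must be integers >= 1")
  }
  tab <- table(degrees)
  out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- length(degrees)
  out
}

#' Fit a power-law exponent to a degree histogram
#'
#' Ordinary least squares of log10(frequency) on log10(degree), the
#' classical way scale-free exponents were read off degree-distribution
#' plots. In `raw` mode each distinct degree with a positive count is one
#' point. In `log` mode degrees are pooled into geometric (factor-2) bins
#' starting at `kmin`; each bin contributes the point
#' (geometric bin centre, count density = pooled count / number of integer
#' degrees in the bin), which removes the noisy sparse tail that biases the
#' raw fit. Bins pooling fewer than `min_bin_count` nodes are excluded: in
#' log space the relative noise of a near-empty bin is enormous and the
#' occupied-bin selection inflates the far tail, flattening the slope. The exponent gamma is the magnitude of the slope.
#'
#' @param h Degree histogram from [degree_histogram()], or a data.frame with
#'   columns `k` and `count`.
#' @param kmin Smallest degree included in the fit (default 1).
#' @param binning `"raw"` (default) or `"log"`.
#' @param min_bin_count Minimum pooled node count for a geometric bin to
#'   enter the log-binned fit (default 10; ignored in raw mode).
#' @return List of class `power_law_fit`: `gamma`, `intercept`, `kmin`,
#'   `r_squared`, `n_points`, `binning`.
#' @export
fit_power_law <- function(h, kmin = 1L, binning = c("raw", "log"),
                          min_bin_count = 10L) {
  binning <- match.arg(binning)
  stopifnot(is.data.frame(h), all(c("k", "count") %in% names(h)))
  h <- h[h$k >= kmin & h$count > 0L, , drop = FALSE]
  if (binning == "raw") {
    x <- log10(h$k)
    y <- log10(h$count)
  } else {
    if (nrow(h) == 0L) stop("no degrees >= kmin")
    kmax <- max(h$k)
    n_bins <- ceiling(log2(kmax / kmin + 1e-9)) + 1L
    lower <- kmin * 2^(seq_len(n_bins) - 1L)
    upper <- pmin(kmin * 2^seq_len(n_bins) - 1L, kmax)
    pooled <- vapply(seq_len(n_bins), function(i) {
      sum(h$count[h$k >= lower[i] & h$k <= upper[i]])
    }, numeric(1))
    width <- upper - lower + 1L
    centre <- sqrt(lower * upper)
    keep <- pooled >= max(1L, min_bin_count) & width > 0
    x <- log10(centre[keep])
    y <- log10(pooled[keep] / width[keep])
  }
  if (length(x) < 3L) {
    stop("power-law fit needs >= 3 points with positive counts (have ",
         length(x), ")")
  }
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(
    list(
      gamma = -unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      kmin = as.integer(kmin),
      r_squared = r2,
      n_points = length(x),
      binning = binning
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s, kmin=%d): gamma = %.3f, R^2 = %.3f, %d points\n",
              x$binning, x$kmin, x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit the joint degree-distribution regression plane
#'
#' The joint counterpart of the marginal power-law fits: for genes belonging
#' to both networks, the frequency of each occupied joint degree cell
#' (k_ppi, k_psn) is regressed on the two log-degrees,
#' log10(freq) ~ log10(k_ppi) + log10(k_psn), by least squares. A pair of
#' reciprocally scale-free networks yields two negative slope coefficients:
#' the "high dimensional scale-free" plane.
#'
#' @param t Joint degree table from [joint_degrees()].
#' @return List of class `plane_fit`: `a0` (intercept), `b_ppi`, `b_psn`
#'   (slopes), `r_squared`, `n_cells`.
#' @export
fit_joint_plane <- function(t) {
  stopifnot(all(c("k_ppi", "k_psn") %in% names(t)))
  t <- t[t$k_ppi >= 1L & t$k_psn >= 1L, , drop = FALSE]
  if (nrow(t) == 0L) stop("no genes with both degrees >= 1")
  key <- paste(t$k_ppi, t$k_psn)
  tab <- table(key)
  kk <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  cells <- data.frame(
    k_ppi = as.integer(kk[, 1L]),
    k_psn = as.integer(kk[, 2L]),
    freq = as.integer(tab)
  )
  if (nrow(cells) < 4L) {
    stop("joint plane fit needs >= 4 occupied cells (have ", nrow(cells), ")")
  }
  fit <- stats::lm(log10(freq) ~ log10(k_ppi) + log10(k_psn), data = cells)
  cf <- stats::coef(fit)
  y <- log10(cells$freq)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      a0 = unname(cf[1L]),
      b_ppi = unname(cf[2L]),
      b_psn = unname(cf[3L]),
      r_squared = if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss,
      n_cells = nrow(cells)
    ),
    class = "plane_fit"
  )
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf(
    "Joint degree plane: log10 f = %.3f %+.3f log10 k_PPI %+.3f log10 k_PSN (R^2 = %.3f, %d cells)\n",
    x$a0, x$b_ppi, x$b_psn, x$r_squared, x$n_cells))
  invisible(x)
}

#' Degree reciprocity between the two networks
#'
#' Pearson correlation between K_PPI and K_PSN with a two-sided t-test.
#' A negative correlation means hubs of one network sit in the periphery of
#' the other ("reciprocal" scale-free topology). `scope = "intersection"`
#' uses genes present in both networks; `"union"` uses every gene in the
#' table, counting absence as degree 0.
#'
#' @param t Joint degree table from [joint_degrees()].
#' @param scope `"intersection"` (default) or `"union"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `association`: `statistic_name`, `r`, `p_value`, `n`.
#' @export
degree_reciprocity <- function(t, scope = c("intersection", "union"),
                               method = c("pearson", "spearman")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (scope == "intersection") {
    t <- t[t$in_ppi & t$in_psn, , drop = FALSE]
  }
  .correlate(t$k_ppi, t$k_psn, method)
}

#' Association between a network degree and a per-gene trait
#'
#' Correlates K_PPI or K_PSN with a continuous gene trait (dN/dS, CAI, TFBS
#' count, ...), excluding genes with a missing trait and genes outside the
#' chosen network.
#'
#' @param t Joint degree table from [joint_degrees()].
#' @param trait Named numeric vector (names are gene IDs) or a numeric
#'   vector aligned with `t$gene`.
#' @param which_degree `"ppi"` or `"psn"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `association`: `statistic_name`, `r`, `p_value`, `n`.
#' @export
degree_trait_association <- function(t, trait, which_degree = c("ppi", "psn"),
                                     method = c("pearson", "spearman")) {
  which_degree <- match.arg(which_degree)
  method <- match.arg(method)
  if (!is.null(names(trait))) {
    trait <- trait[t$gene]
  } else if (length(trait) != nrow(t)) {
    stop("unnamed trait vector must align with the joint degree table")
  }
  deg <- if (which_degree == "ppi") t$k_ppi else t$k_psn
  member <- if (which_degree == "ppi") t$in_ppi else t$in_psn
  keep <- member & !is.na(trait)
  .correlate(deg[keep], as.numeric(trait[keep]), method)
}

.correlate <- function(x, y, method) {
  if (length(x) < 3L) stop("association needs n >= 3 (have ", length(x), ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one coordinate; correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  structure(
    list(statistic_name = method, r = unname(ct$estimate),
         p_value = ct$p.value, n = length(x)),
    class = "association"
  )
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("%s r = %.4f, two-sided p = %.3g, n = %d\n",
              x$statistic_name, x$r, x$p_value, x$n))
  invisible(x)
}
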