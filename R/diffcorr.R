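#' Fisher's variance-stabilising z transform of a correlation
#'
#' Computes `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))` after clamping
#' `|r|` to `1 - 1e-7`, which keeps the transform finite for correlations
#' that are exactly plus or minus one.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  lim <- 1 - 1e-7
  atanh(pmin(lim, pmax(-lim, r)))
}

#' Fisher z-test for the difference of two correlations
#'
#' Tests whether a gene pair's Pearson correlation differs between two
#' independent groups:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' with a two-sided standard-normal p-value.
#'
#' @param r1,r2 Correlations in the two groups (vectorised).
#' @param n1,n2 Sample sizes (> 3) behind each correlation.
#' @return A list with vectors `z_stat` and `p_value`.
#' @export
differential_correlation_test <- function(r1, n1, r2, n2) {
  if (any(n1 <= 3) || any(n2 <= 3)) {
    stop("differential_correlation_test: need more than 3 samples per group")
  }
  z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Screen all shared gene pairs for differential correlation
#'
#' Computes the Pearson correlation of every unordered gene pair over a
#' shared gene universe separately in the sensitive and tolerant expression
#' tables, then applies the Fisher z-test to each pair. Pairs involving a
#' constant gene in either group are dropped with a warning (their
#' correlation is undefined). `delta_r = r_sensitive - r_tolerant`, so a
#' negative value means the pair is more strongly correlated in the tolerant
#' group.
#'
#' @param tbl_sensitive,tbl_tolerant Expression tibbles for the two groups.
#' @param gene_universe Genes to test; defaults to the genes present in both
#'   tables.
#' @return A tibble with one row per pair: `gene_i`, `gene_j`,
#'   `r_sensitive`, `r_tolerant`, `n_sensitive`, `n_tolerant`, `delta_r`,
#'   `z_stat`, `p_value` (and `fdr = NA` until [adjust_fdr()]).
#' @export
screen_all_pairs <- function(tbl_sensitive, tbl_tolerant,
                             gene_universe = NULL) {
  if (is.null(gene_universe)) {
    gene_universe <- intersect(tbl_sensitive$gene_id, tbl_tolerant$gene_id)
  }
  stopifnot(all(gene_universe %in% tbl_sensitive$gene_id),
            all(gene_universe %in% tbl_tolerant$gene_id))
  if (length(gene_universe) < 2L) {
    stop("screen_all_pairs: need at least 2 shared genes")
  }
  sub <- function(tbl) tbl[match(gene_universe, tbl$gene_id), , drop = FALSE]
  r_s <- correlation_matrix(sub(tbl_sensitive))
  r_t <- correlation_matrix(sub(tbl_tolerant))
  shared <- intersect(rownames(r_s), rownames(r_t))
  dropped <- setdiff(gene_universe, shared)
  if (length(dropped)) {
    warning("screen_all_pairs: dropping pair(s) with constant gene(s): ",
            paste(dropped, collapse = ", "))
  }
  shared <- gene_universe[gene_universe %in% shared]
  rs <- unclass(r_s)[shared, shared]
  rt <- unclass(r_t)[shared, shared]
  n_s <- attr(r_s, "n_samples")
  n_t <- attr(r_t, "n_samples")
  ut <- which(upper.tri(rs), arr.ind = TRUE)
  test <- differential_correlation_test(rs[upper.tri(rs)], n_s,
                                        rt[upper.tri(rt)], n_t)
  tibble::tibble(
    gene_i = shared[ut[, 1]],
    gene_j = shared[ut[, 2]],
    r_sensitive = rs[upper.tri(rs)],
    r_tolerant = rt[upper.tri(rt)],
    n_sensitive = n_s,
    n_tolerant = n_t,
    delta_r = rs[upper.tri(rs)] - rt[upper.tri(rt)],
    z_stat = test$z_stat,
    p_value = test$p_value,
    fdr = NA_real_
  )
}

# Efron-style local fdr by central matching: fit the marginal density of z
# with a Poisson GLM on a histogram (natural-spline in z), fit the empirical
# null N(mu0, sd0) and null proportion pi0 by a quadratic log-density fit to
# the central z mass, and report fdr(z) = pi0 f0(z) / f(z), capped at 1.
local_fdr <- function(z, n_bins = 120L, central_quantile = 0.25) {
  stopifnot(length(z) >= 20L)
  br <- seq(min(z) - 1e-8, max(z) + 1e-8, length.out = n_bins + 1L)
  h <- hist(z, breaks = br, plot = FALSE)
  mid <- h$mids
  cnt <- h$counts
  width <- diff(br)[1]
  df_marginal <- min(7L, max(3L, n_bins %/% 15L))
  marg <- stats::glm(cnt ~ splines::ns(mid, df = df_marginal),
                     family = stats::poisson())
  f_hat <- stats::predict(marg, type = "response") / (length(z) * width)

  qs <- stats::quantile(z, c(central_quantile, 1 - central_quantile))
  central <- mid >= qs[1] & mid <= qs[2] & cnt > 0
  if (sum(central) < 5L) central <- cnt > 0
  quad <- stats::lm(log(cnt[central] / (length(z) * width)) ~ mid[central] +
                      I(mid[central]^2))
  b <- stats::coef(quad)
  if (is.na(b[3]) || b[3] >= 0) {
    # central mass not peaked; fall back to a theoretical N(0,1) null
    mu0 <- 0
    sd0 <- 1
  } else {
    sd0 <- sqrt(-1 / (2 * b[3]))
    mu0 <- b[2] * sd0^2
  }
  log_pi0 <- unname(b[1] + mu0^2 / (2 * sd0^2) + log(sqrt(2 * pi) * sd0))
  pi0 <- min(1, exp(log_pi0))
  f0 <- stats::dnorm(mid, mu0, sd0)
  fdr_bins <- pmin(1, pi0 * f0 / pmax(f_hat, 1e-300))
  idx <- findInterval(z, br, all.inside = TRUE)
  fdr_bins[idx]
}

#' Fill the FDR column of a differential-correlation table
#'
#' `method = "bh"` applies the Benjamini-Hochberg step-up procedure over all
#' tested pairs. `method = "local"` estimates an Efron-style local false
#' discovery rate from the z-statistic histogram: the marginal density is fit
#' with a Poisson spline regression, the empirical null (mean, sd and null
#' proportion) by central matching on the middle of the z distribution, and
#' each pair's fdr is `pi0 * f0(z) / f(z)`.
#'
#' @param records Tibble from [screen_all_pairs()] (or any tibble with
#'   `p_value` and, for `"local"`, `z_stat`).
#' @param method `"bh"` (default) or `"local"`.
#' @return The records with `fdr` filled.
#' @export
adjust_fdr <- function(records, method = c("bh", "local")) {
  method <- match.arg(method)
  records$fdr <- switch(method,
    bh = stats::p.adjust(records$p_value, method = "BH"),
    local = local_fdr(records$z_stat)
  )
  records
}

#' Select significantly different gene pairs
#'
#' Applies the two-part selection rule: the absolute correlation difference
#' must reach `min_abs_delta` (default 0.7, which by design excludes pairs
#' like r_sensitive = 0 versus r_tolerant = 0.6 whose correlations are both
#' unremarkable) and the FDR must not exceed `max_fdr`. Both boundaries are
#' inclusive.
#'
#' @param records Tibble with `delta_r` and `fdr` filled.
#' @param min_abs_delta Minimum `|delta_r|` (default 0.7).
#' @param max_fdr Maximum FDR (default 0.05).
#' @return The selected subset of `records`.
#' @export
select_significant_pairs <- function(records, min_abs_delta = 0.7,
                                     max_fdr = 0.05) {
  stopifnot(!anyNA(records$fdr))
  dplyr::filter(records,
                abs(.data$delta_r) >= min_abs_delta,
                .data$fdr <= max_fdr)
}
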