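#' Pearson correlation matrix of gene expression profiles
#'
#' Computes the exact Pearson correlation between every pair of gene rows.
#' Constant gene rows (zero variance) are dropped with a warning, since their
#' correlation is undefined. The sample count is recorded for later reuse by
#' the differential-correlation test.
#'
#' @param tbl Expression tibble (>= 3 samples).
#' @return A symmetric correlation matrix of class `cor_matrix` with gene
#'   row/column names and attribute `n_samples`.
#' @export
correlation_matrix <- function(tbl) {
  x <- expression_matrix(tbl)
  if (ncol(x) < 3L) stop("correlation_matrix: need at least 3 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("correlation_matrix: dropping constant gene(s): ",
            paste(rownames(x)[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(r, class = c("cor_matrix", class(r)), n_samples = ncol(x))
}

#' Signed co-expression similarity
#'
#' Maps Pearson correlation to the signed similarity `s = (1 + r) / 2`, so
#' perfectly anti-correlated genes (r = -1) are unconnected (s = 0),
#' uncorrelated genes sit at s = 0.5, and perfectly correlated genes at s = 1.
#'
#' @param r A correlation value, vector or matrix in `[-1, 1]`.
#' @return Similarity of the same shape, in `[0, 1]`. Matrix input gains
#'   class `similarity_matrix` and keeps the `n_samples` attribute.
#' @export
signed_similarity <- function(r) {
  vals <- unclass(r)
  if (any(vals < -1 | vals > 1, na.rm = TRUE)) {
    stop("signed_similarity: correlations must lie in [-1, 1]")
  }
  s <- (1 + vals) / 2
  if (is.matrix(s)) {
    s <- structure(s, class = c("similarity_matrix", "matrix", "array"),
                   n_samples = attr(r, "n_samples"))
  }
  s
}

#' Soft-threshold power adjacency
#'
#' Raises the signed similarity elementwise to the soft-threshold power
#' `beta`, emphasising strong co-expression while shrinking weak similarity
#' toward zero. The diagonal is zeroed so row sums give the standard
#' connectivity `k_i`.
#'
#' @param s Similarity matrix in `[0, 1]`.
#' @param beta Positive integer power.
#' @return Adjacency matrix of class `adjacency_matrix` with attribute `beta`.
#' @export
soft_adjacency <- function(s, beta) {
  stopifnot(beta >= 1)
  a <- unclass(s)^beta
  diag(a) <- 0
  structure(a, class = c("adjacency_matrix", "matrix", "array"),
            beta = beta, n_samples = attr(s, "n_samples"))
}

scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L || diff(range(k)) < 1e-12) {
    warning("scale_free_fit: degenerate connectivity distribution; R^2 = 0")
    return(list(r_squared = 0, slope = NA_real_))
  }
  # equal-width bins on raw connectivity, the convention of the standard
  # soft-threshold selector: the weakly connected bulk occupies the first
  # bin(s) and the log-log fit is driven by the decreasing tail
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  freq <- freq[keep]
  mean_k <- mean_k[keep]
  if (length(freq) < 3L) {
    warning("scale_free_fit: too few occupied bins; R^2 = 0")
    return(list(r_squared = 0, slope = NA_real_))
  }
  fit <- stats::lm(log10(freq) ~ log10(mean_k))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = if (slope > 0) -r2 else r2, slope = slope)
}

#' Select the soft-threshold power by scale-free model fit
#'
#' For each candidate power, computes the soft connectivity `k_i` from the
#' powered similarity and measures how well the connectivity distribution
#' follows a power law: `k` is binned into `n_bins` equal-width bins and
#' `log10(frequency)` is regressed on
#' `log10(mean k per bin)`. The fit index is the signed R-squared (negated
#' when the slope is positive, which penalises distributions that are not
#' scale-free-decreasing). The selected power is the smallest candidate whose
#' signed R-squared reaches `r2_target`; if none qualifies, the power with
#' the best fit is selected with a warning.
#'
#' @param s Similarity matrix.
#' @param candidates Candidate powers (default 1:30).
#' @param r2_target Signed R-squared the fit must reach (default 0.5).
#' @param n_bins Number of connectivity bins for the log-log regression.
#' @return A tibble of class `sft_report` with columns `beta`, `r_squared`,
#'   `slope`, `mean_k`, `max_k` and attributes `selected_beta` and
#'   `r2_target`.
#' @export
pick_soft_threshold <- function(s, candidates = 1:30, r2_target = 0.5,
                                n_bins = 10L) {
  stopifnot(length(candidates) >= 1L, all(candidates >= 1))
  rows <- purrr::map_dfr(candidates, function(beta) {
    a <- unclass(s)^beta
    diag(a) <- 0
    k <- rowSums(a)
    if (all(k == 0)) stop("pick_soft_threshold: all genes isolated")
    fit <- scale_free_fit(k, n_bins = n_bins)
    tibble::tibble(beta = beta, r_squared = fit$r_squared, slope = fit$slope,
                   mean_k = mean(k), max_k = max(k))
  })
  qualifying <- rows$beta[rows$r_squared >= r2_target]
  if (length(qualifying) > 0L) {
    selected <- min(qualifying)
  } else {
    selected <- rows$beta[which.max(rows$r_squared)]
    warning("pick_soft_threshold: no candidate reached R^2 >= ", r2_target,
            "; selecting beta = ", selected, " with best fit")
  }
  structure(rows, class = c("sft_report", class(rows)),
            selected_beta = selected, r2_target = r2_target)
}

#' Signed topological overlap matrix
#'
#' Computes the signed TOM
#' `TOM_ij = (a_ij + sum_{u != i,j} a_iu a_uj) / (min(k_i, k_j) + 1 - a_ij)`
#' measuring both the direct connection strength and the weight of shared
#' neighbours of each gene pair. Implemented with one matrix product; since
#' the adjacency diagonal is zero, `(A %*% A)_ij` equals the shared-neighbour
#' sum with the i and j self terms already absent. The diagonal is set to 1
#' by convention.
#'
#' @param a Adjacency matrix (symmetric, zero diagonal, values in `[0, 1]`).
#' @return Matrix of class `tom_matrix` with attribute `connectivity`
#'   (the vector `k`).
#' @export
signed_tom <- function(a) {
  a <- unclass(a)
  stopifnot(isSymmetric(unname(a)), all(diag(a) == 0))
  k <- rowSums(a)
  shared <- a %*% a
  num <- a + shared
  den <- outer(k, k, pmin) + 1 - a
  den[den < 1e-12] <- 1e-12
  tom <- num / den
  diag(tom) <- 1
  structure(tom, class = c("tom_matrix", "matrix", "array"),
            connectivity = k, beta = attr(a, "beta"))
}

#' Export a thresholded co-expression network as an edge table
#'
#' Keeps every gene pair whose TOM value reaches `cutoff` as an undirected
#' edge weighted by TOM and signed by the underlying Pearson correlation.
#' Genes with no surviving edge are not part of the network (their degree is
#' reported as 0 in cross-network tables).
#'
#' @param tom TOM matrix from [signed_tom()].
#' @param cutoff Minimum TOM value for an edge (default 0.4).
#' @param cor Correlation matrix supplying edge signs; optional.
#' @return A tibble of class `gene_network` with columns `gene_a`, `gene_b`,
#'   `weight`, `sign` and attributes `nodes` (genes with >= 1 edge) and
#'   `cutoff`.
#' @export
export_edges <- function(tom, cutoff = 0.4, cor = NULL) {
  stopifnot(cutoff >= 0)
  m <- unclass(tom)
  ids <- rownames(m)
  ut <- upper.tri(m)
  keep <- ut & m >= cutoff
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = ids[idx[, 1]],
    gene_b = ids[idx[, 2]],
    weight = m[keep],
    sign = if (is.null(cor)) rep(NA_character_, nrow(idx)) else
      ifelse(unclass(cor)[keep] >= 0, "+", "-")
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  structure(edges, class = c("gene_network", class(edges)),
            nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
            cutoff = cutoff)
}

#' Build a thresholded network from an expression table in one call
#'
#' Convenience wrapper chaining [correlation_matrix()], [signed_similarity()],
#' soft-threshold selection (or a fixed `beta`), [soft_adjacency()],
#' [signed_tom()] and [export_edges()].
#'
#' @param tbl Expression tibble.
#' @param beta `"auto"` to select by [pick_soft_threshold()], or a positive
#'   integer power (the conventional choice for signed networks of this kind
#'   is 22).
#' @param tom_cutoff TOM export threshold (default 0.4).
#' @param candidates,r2_target Passed to [pick_soft_threshold()] when
#'   `beta = "auto"`.
#' @return A list with `edges` (the `gene_network`), `tom`, `adjacency`,
#'   `similarity`, `correlation` and `sft_report` (NULL for fixed beta).
#' @export
build_network <- function(tbl, beta = "auto", tom_cutoff = 0.4,
                          candidates = 1:30, r2_target = 0.5) {
  r <- correlation_matrix(tbl)
  s <- signed_similarity(r)
  sft <- NULL
  if (identical(beta, "auto")) {
    sft <- pick_soft_threshold(s, candidates = candidates, r2_target = r2_target)
    beta <- attr(sft, "selected_beta")
  }
  a <- soft_adjacency(s, beta)
  tom <- signed_tom(a)
  edges <- export_edges(tom, cutoff = tom_cutoff, cor = r)
  list(edges = edges, tom = tom, adjacency = a, similarity = s,
       correlation = r, sft_report = sft)
}
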