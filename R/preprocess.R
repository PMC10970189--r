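#' Convert between expression tibbles and matrices
#'
#' An expression table is a tibble whose first column `gene_id` holds unique
#' gene identifiers and whose remaining columns are numeric sample values.
#' These helpers move between that tidy form and the genes-by-samples matrix
#' used internally.
#'
#' @param tbl An expression tibble.
#' @param x A numeric matrix with gene row names and sample column names.
#' @return `expression_matrix()` returns a matrix; `expression_tibble()` a
#'   tibble.
#' @export
expression_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "gene_id")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$gene_id
  m
}

#' @rdname expression_matrix
#' @export
expression_tibble <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)),
                   tibble::as_tibble(x, .name_repair = "minimal"))
}

#' Average duplicate probe rows into gene rows
#'
#' Consolidates microarray probe-level rows into one row per gene by taking
#' the per-sample arithmetic mean over a probe's siblings. Rows absent from
#' the probe map are assumed to already be gene-level (e.g. RNA-seq tables)
#' and pass through unchanged.
#'
#' @param tbl Expression tibble whose `gene_id` column may contain probe IDs.
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @return Expression tibble with unique gene IDs; mapped genes keep the
#'   position of their first probe row.
#' @examples
#' tbl <- tibble::tibble(gene_id = c("p1", "p2"), s1 = c(2, 4), s2 = c(4, 8))
#' pm <- tibble::tibble(probe = c("p1", "p2"), gene = "g")
#' average_probes(tbl, pm) # g = (3, 6)
#' @export
average_probes <- function(tbl, probe_map) {
  stopifnot(is.data.frame(probe_map), all(c("probe", "gene") %in% names(probe_map)))
  multi <- probe_map |>
    dplyr::distinct(.data$probe, .data$gene) |>
    dplyr::count(.data$probe) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    stop("average_probes: probe(s) mapped to multiple genes: ",
         paste(multi$probe, collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(probe_map$gene, probe_map$probe)
  target <- ifelse(tbl$gene_id %in% names(map), map[tbl$gene_id], tbl$gene_id)
  out <- tbl |>
    dplyr::mutate(gene_id = unname(target)) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .by = "gene_id")
  if (anyDuplicated(out$gene_id)) stop("average_probes: duplicate gene IDs remain")
  out
}

#' Merge expression datasets by gene intersection
#'
#' Combines several expression tables from the same condition group into one
#' table containing only the genes present in every dataset, in the gene
#' order of the first. Sample IDs are prefixed with the dataset name to stay
#' unique.
#'
#' @param tbls A (optionally named) list of expression tibbles.
#' @return A merged expression tibble.
#' @export
merge_datasets <- function(tbls) {
  stopifnot(is.list(tbls), length(tbls) >= 1L)
  if (length(tbls) == 1L) return(tbls[[1]])
  prefixes <- names(tbls)
  if (is.null(prefixes) || any(!nzchar(prefixes))) {
    prefixes <- sprintf("ds%d", seq_along(tbls))
  }
  shared <- Reduce(intersect, lapply(tbls, function(t) t$gene_id))
  shared <- tbls[[1]]$gene_id[tbls[[1]]$gene_id %in% shared]
  if (length(shared) == 0L) stop("merge_datasets: no genes shared by all datasets")
  pieces <- purrr::map2(tbls, prefixes, function(t, p) {
    t <- t[match(shared, t$gene_id), , drop = FALSE]
    names(t)[-1] <- paste(p, names(t)[-1], sep = ".")
    t[, -1, drop = FALSE]
  })
  dplyr::bind_cols(tibble::tibble(gene_id = shared), pieces)
}

#' Rescale each sample to the 0-100 range
#'
#' Applies the per-sample min-max transform `(x - min x) / (max x - min x) * 100`
#' so every sample column spans exactly 0 to 100, making the low-expression
#' floor comparable across heterogeneous datasets.
#'
#' @param tbl Expression tibble.
#' @return Expression tibble with every column attaining 0 and 100.
#' @export
rescale_samples <- function(tbl) {
  x <- expression_matrix(tbl)
  rng <- apply(x, 2, range)
  flat <- rng[2, ] - rng[1, ] <= 0
  if (any(flat)) {
    stop("rescale_samples: constant sample column(s): ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(sweep(x, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/") * 100
  expression_tibble(scaled)
}

#' Filter genes with low expression across samples
#'
#' Keeps a gene when its expression exceeds `expression_floor` in at least
#' `min_fraction_expressed` of samples (boundary inclusive: a gene expressed
#' in exactly half the samples under the defaults is kept). Intended to run
#' after [rescale_samples()], so the default floor of 1 refers to the 0-100
#' scale.
#'
#' @param tbl Expression tibble.
#' @param expression_floor A gene counts as expressed in a sample when its
#'   value is strictly greater than this floor.
#' @param min_fraction_expressed Minimum fraction of samples in which the
#'   gene must be expressed.
#' @return Filtered expression tibble, gene order preserved.
#' @export
filter_low_expression <- function(tbl, expression_floor = 1,
                                  min_fraction_expressed = 0.5) {
  stopifnot(min_fraction_expressed >= 0, min_fraction_expressed <= 1)
  x <- expression_matrix(tbl)
  frac <- rowMeans(x > expression_floor)
  tbl[frac >= min_fraction_expressed, , drop = FALSE]
}

#' Detect outlier samples by average-linkage hierarchical clustering
#'
#' Clusters samples by average linkage on the Euclidean distance between
#' their gene-expression vectors and flags as outliers every sample outside
#' the largest cluster after cutting the dendrogram at `cut_height`. With
#' `cut_height = NULL` the cut is placed automatically at 1.5 times the
#' median merge height, a reproducible default that should be overridden
#' after inspecting the sample dendrogram for real data.
#'
#' @param tbl Expression tibble (>= 3 samples).
#' @param cut_height Dendrogram cut height, or `NULL` for the automatic cut.
#' @return A tibble with one row per sample: `sample_id`, `cluster` (integer
#'   label from the cut), `is_outlier`. The kept/removed ID vectors are
#'   attached as attributes `kept` and `removed`.
#' @export
detect_outlier_samples <- function(tbl, cut_height = NULL) {
  x <- expression_matrix(tbl)
  if (ncol(x) < 3L) stop("detect_outlier_samples: need at least 3 samples")
  hc <- stats::hclust(stats::dist(t(x)), method = "average")
  if (is.null(cut_height)) cut_height <- 1.5 * stats::median(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  out <- tibble::tibble(sample_id = colnames(x),
                        cluster = unname(cl),
                        is_outlier = unname(cl) != main)
  if (sum(out$is_outlier) > ncol(x) / 2) {
    warning("detect_outlier_samples: cut removes more than half the samples")
  }
  attr(out, "kept") <- out$sample_id[!out$is_outlier]
  attr(out, "removed") <- out$sample_id[out$is_outlier]
  out
}

#' Drop flagged outlier samples from an expression table
#'
#' @param tbl Expression tibble.
#' @param outliers Result of [detect_outlier_samples()] or a character vector
#'   of sample IDs to drop.
#' @return Expression tibble without the outlier columns.
#' @export
drop_outlier_samples <- function(tbl, outliers) {
  removed <- if (is.character(outliers)) outliers else attr(outliers, "removed")
  tbl[, !(names(tbl) %in% removed), drop = FALSE]
}
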