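#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a soft-threshold report
#'
#' @param x An `sft_report` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return One row per candidate power with the fit statistics and a
#'   `selected` flag.
#' @export
tidy.sft_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(selected = .data$beta == attr(x, "selected_beta"))
}

#' @rdname tidy.sft_report
#' @export
glance.sft_report <- function(x, ...) {
  sel <- attr(x, "selected_beta")
  row <- tibble::as_tibble(x)[tibble::as_tibble(x)$beta == sel, ]
  tibble::tibble(selected_beta = sel,
                 r_squared = row$r_squared,
                 mean_k = row$mean_k,
                 r2_target = attr(x, "r2_target"))
}

#' Tidy a square network matrix into a pair table
#'
#' Converts a correlation, similarity, adjacency or TOM matrix into a tibble
#' of unordered gene pairs with the matrix value.
#'
#' @param x A `cor_matrix`, `similarity_matrix`, `adjacency_matrix` or
#'   `tom_matrix`.
#' @param ... Unused.
#' @return A tibble with `gene_i`, `gene_j`, `value`.
#' @export
tidy.tom_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(gene_i = rownames(m)[idx[, 1]],
                 gene_j = colnames(m)[idx[, 2]],
                 value = m[upper.tri(m)])
}

#' @rdname tidy.tom_matrix
#' @export
tidy.cor_matrix <- tidy.tom_matrix

#' @rdname tidy.tom_matrix
#' @export
tidy.similarity_matrix <- tidy.tom_matrix

#' @rdname tidy.tom_matrix
#' @export
tidy.adjacency_matrix <- tidy.tom_matrix

#' Summarise a pipeline result
#'
#' @param x A `pipeline_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with the headline counts of the run: genes and
#'   edges per network, high-centrality genes, pairs tested and selected, TF
#'   genes and TF-module edges.
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    genes_sensitive = length(attr(x$networks$sensitive$edges, "nodes")),
    genes_tolerant = length(attr(x$networks$tolerant$edges, "nodes")),
    edges_sensitive = nrow(x$networks$sensitive$edges),
    edges_tolerant = nrow(x$networks$tolerant$edges),
    high_centrality_genes = length(x$high_centrality_genes),
    pairs_tested = nrow(x$pairs),
    pairs_selected = nrow(x$selected_pairs),
    tf_genes = length(x$tf_genes),
    tf_module_edges = NROW(x$tf_modules)
  )
}

#' @export
print.sft_report <- function(x, ...) {
  cat("Soft-threshold report: selected beta =", attr(x, "selected_beta"),
      "(target signed R^2 =", attr(x, "r2_target"), ")\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Co-expression network:", length(attr(x, "nodes")), "genes,",
      nrow(x), "edges (TOM cutoff", attr(x, "cutoff"), ")\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
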