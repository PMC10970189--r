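#' GO term over-representation by the hypergeometric (Fisher exact) test
#'
#' For every GO term with at least one study gene, builds the 2x2 table of
#' study/background versus term/no-term and computes the one-sided Fisher
#' exact p-value (the hypergeometric upper tail), then controls the FDR with
#' Benjamini-Hochberg across the tested terms. The annotation is taken as a
#' flat gene-to-term table; no propagation up the ontology graph is
#' performed.
#'
#' @param study_set Character vector of study gene IDs (must be contained in
#'   the background).
#' @param annotation Data frame with columns `gene` and `term` (optionally
#'   `name` for term labels).
#' @param background Background gene universe; defaults to all annotated
#'   genes.
#' @param max_p,max_fdr Significance cutoffs applied to the returned terms
#'   (both default 0.05, boundaries inclusive). Set both to 1 to see every
#'   tested term.
#' @return A tibble sorted by p-value with columns `term`, `k` (study genes
#'   with the term), `n` (study size), `K` (background genes with the term),
#'   `N` (background size), `p_value`, `fdr` (and `name` when supplied).
#' @export
go_enrichment <- function(study_set, annotation,
                          background = unique(annotation$gene),
                          max_p = 0.05, max_fdr = 0.05) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  study_set <- unique(study_set)
  if (length(study_set) == 0L) stop("go_enrichment: empty study set")
  if (!all(study_set %in% background)) {
    stop("go_enrichment: study set contains genes outside the background")
  }
  ann <- annotation |>
    dplyr::filter(.data$gene %in% background) |>
    dplyr::distinct(.data$gene, .data$term)
  n <- length(study_set)
  n_bg <- length(unique(background))
  counts <- ann |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene),
                     k = dplyr::n_distinct(.data$gene[.data$gene %in% study_set]),
                     .by = "term") |>
    dplyr::filter(.data$k >= 1L)
  res <- counts |>
    dplyr::mutate(
      n = n, N = n_bg,
      p_value = stats::phyper(.data$k - 1L, .data$K, .data$N - .data$K,
                              .data$n, lower.tail = FALSE),
      fdr = stats::p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::select("term", "k", "n", "K", "N", "p_value", "fdr") |>
    dplyr::filter(.data$p_value <= max_p, .data$fdr <= max_fdr) |>
    dplyr::arrange(.data$p_value, .data$term)
  if ("name" %in% names(annotation)) {
    res <- dplyr::left_join(res,
                            dplyr::distinct(annotation, .data$term, .data$name),
                            by = "term")
  }
  res
}

#' Map genes to marker intervals
#'
#' Assigns each gene, represented by the single coordinate `position` (its
#' transcription start), to every marker interval on the same chromosome
#' whose closed 1-based range `[start, end]` contains it.
#'
#' @param gene_positions Data frame with columns `gene_id`, `chrom`,
#'   `position`.
#' @param intervals Data frame with columns `chrom`, `start`, `end`, `name`.
#' @return A tibble with one row per (gene, interval) hit: `gene_id`,
#'   `chrom`, `position`, `interval`, `start`, `end`.
#' @export
map_genes_to_intervals <- function(gene_positions, intervals) {
  stopifnot(all(c("gene_id", "chrom", "position") %in% names(gene_positions)),
            all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (nrow(intervals) > 0L && any(intervals$start > intervals$end)) {
    stop("map_genes_to_intervals: interval with start > end")
  }
  dplyr::inner_join(
    tibble::as_tibble(gene_positions),
    dplyr::rename(tibble::as_tibble(intervals), interval = "name"),
    by = dplyr::join_by("chrom", dplyr::between("position", "start", "end"))
  ) |>
    dplyr::select("gene_id", "chrom", "position", "interval", "start", "end") |>
    dplyr::arrange(.data$gene_id, .data$interval)
}

#' Default transcription-activity GO terms
#'
#' The four GO identifiers used to call a gene transcription-related:
#' transcription, transcription regulator activity, transcription
#' (DNA-dependent), and transcription from RNA polymerase II promoter.
#' @export
TF_GO_TERMS <- c("GO:0006350", "GO:0030528", "GO:0006351", "GO:0006366")

#' Select transcription factors among high-centrality genes
#'
#' Keeps the genes annotated to at least one transcription-activity GO term.
#'
#' @param genes Character vector of candidate gene IDs (typically the union
#'   of high-degree and high-closeness genes).
#' @param annotation Data frame with columns `gene` and `term`.
#' @param tf_terms GO terms that define transcription activity
#'   (default [TF_GO_TERMS]).
#' @return Sorted character vector of selected gene IDs.
#' @export
select_transcription_factors <- function(genes, annotation,
                                         tf_terms = TF_GO_TERMS) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  tf_annotated <- unique(annotation$gene[annotation$term %in% tf_terms])
  sort(intersect(genes, tf_annotated))
}

#' Build transcription-factor-centred differential modules
#'
#' Groups the selected differentially correlated pairs around each
#' transcription factor they involve. A TF with no selected pair yields no
#' module. Each partner carries the pair's `delta_r`, its FDR, and a sign
#' label: `"positive"` when the pair is more strongly correlated in the
#' sensitive group (`r_sensitive > r_tolerant`), `"negative"` otherwise.
#'
#' @param tf_set Character vector of TF gene IDs.
#' @param selected_pairs Output of [select_significant_pairs()].
#' @return A tibble with columns `tf`, `partner`, `delta_r`, `sign`, `fdr`,
#'   one row per TF-partner edge. A pair of two TFs contributes a row to
#'   both modules.
#' @export
build_tf_modules <- function(tf_set, selected_pairs) {
  stopifnot(all(c("gene_i", "gene_j", "delta_r", "fdr") %in%
                  names(selected_pairs)))
  as_module_rows <- function(focal, partner) {
    selected_pairs |>
      dplyr::filter(.data[[focal]] %in% tf_set) |>
      dplyr::transmute(tf = .data[[focal]], partner = .data[[partner]],
                       delta_r = .data$delta_r,
                       sign = dplyr::if_else(.data$delta_r > 0,
                                             "positive", "negative"),
                       fdr = .data$fdr)
  }
  dplyr::bind_rows(as_module_rows("gene_i", "gene_j"),
                   as_module_rows("gene_j", "gene_i")) |>
    dplyr::arrange(.data$tf, .data$partner)
}
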