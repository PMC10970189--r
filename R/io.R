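#' Read and write tab-delimited expression tables
#'
#' The on-disk dialect is a UTF-8 TSV with a header row of sample IDs and a
#' first column of gene IDs (named `gene_id` on write; any first-column name
#' is accepted on read). Gzip-compressed files are read transparently.
#'
#' @param path File path.
#' @param tbl Expression tibble.
#' @return `read_expression_table()` returns an expression tibble;
#'   `write_expression_table()` invisibly returns `path`.
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) stop("read_expression_table: expected gene column plus samples")
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  bad <- which(!vapply(tbl[-1], is.numeric, logical(1)))
  if (length(bad)) {
    col <- names(tbl[-1])[bad[1]]
    row <- which(is.na(suppressWarnings(as.numeric(tbl[[bad[1] + 1L]]))))[1]
    stop("read_expression_table: non-numeric value in sample column '", col,
         "' (data row ", ifelse(is.na(row), "?", row), ")")
  }
  tbl
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(tbl, path) {
  stopifnot(names(tbl)[1] == "gene_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write network edge and node-attribute tables
#'
#' Emits Cytoscape-importable TSVs: `<prefix>_edges.tsv` with columns
#' `gene_a`, `gene_b`, `weight`, `sign`, and `<prefix>_nodes.tsv` with the
#' centrality columns. Rows are sorted lexicographically by gene ID so the
#' output is byte-deterministic for a given network.
#'
#' @param net A `gene_network` edge tibble.
#' @param centralities A `centrality_table` (optional).
#' @param path_prefix Path prefix for the output files.
#' @return Invisibly, the written file paths.
#' @export
write_network_outputs <- function(net, centralities = NULL, path_prefix) {
  edge_path <- paste0(path_prefix, "_edges.tsv")
  readr::write_tsv(dplyr::arrange(tibble::as_tibble(net),
                                  .data$gene_a, .data$gene_b),
                   edge_path, progress = FALSE)
  paths <- edge_path
  if (!is.null(centralities)) {
    node_path <- paste0(path_prefix, "_nodes.tsv")
    readr::write_tsv(dplyr::arrange(tibble::as_tibble(centralities),
                                    .data$gene_id),
                     node_path, progress = FALSE)
    paths <- c(paths, node_path)
  }
  invisible(paths)
}

#' Pipeline configuration with conventional defaults
#'
#' Bundles every threshold of the two-group analysis in one list: the 0-100
#' rescale with expression floor 1 in at least 50% of samples, automatic
#' soft-threshold selection targeting a scale-free fit of R-squared 0.5 (or
#' a fixed power), TOM export cutoff 0.4, high-degree fraction 0.5,
#' high-closeness floor 0.75, differential-correlation selection at
#' `|delta_r| >= 0.7` and FDR 0.05, and enrichment cutoffs p and FDR 0.05.
#'
#' @param sensitive,tolerant Expression inputs per group: an expression
#'   tibble, a file path, or a list of either (multiple datasets are merged
#'   by gene intersection).
#' @param probe_map Optional probe-to-gene data frame applied to both groups.
#' @param go_annotation Optional gene/term data frame for enrichment and TF
#'   selection.
#' @param gene_positions,marker_intervals Optional tables for interval
#'   mapping.
#' @param expression_floor,min_fraction_expressed Low-expression filter.
#' @param outlier_cut_height Dendrogram cut for sample outlier removal
#'   (`NULL` = automatic).
#' @param beta `"auto"` or a fixed integer soft-threshold power.
#' @param r2_target Scale-free fit target for automatic selection.
#' @param tom_cutoff TOM edge export threshold.
#' @param degree_fraction,closeness_floor High-centrality screens.
#' @param min_abs_delta,max_fdr Differential-pair selection.
#' @param fdr_method `"bh"` or `"local"`.
#' @param enrich_max_p,enrich_max_fdr GO enrichment cutoffs.
#' @param tf_terms Transcription-activity GO terms.
#' @param out_dir Output directory for the stage tables (`NULL` = no files).
#' @param seed Seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sensitive, tolerant,
                            probe_map = NULL,
                            go_annotation = NULL,
                            gene_positions = NULL,
                            marker_intervals = NULL,
                            expression_floor = 1,
                            min_fraction_expressed = 0.5,
                            outlier_cut_height = NULL,
                            beta = "auto",
                            r2_target = 0.5,
                            tom_cutoff = 0.4,
                            degree_fraction = 0.5,
                            closeness_floor = 0.75,
                            min_abs_delta = 0.7,
                            max_fdr = 0.05,
                            fdr_method = c("bh", "local"),
                            enrich_max_p = 0.05,
                            enrich_max_fdr = 0.05,
                            tf_terms = TF_GO_TERMS,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(min_fraction_expressed >= 0, min_fraction_expressed <= 1,
            tom_cutoff >= 0, tom_cutoff <= 1,
            degree_fraction >= 0, degree_fraction <= 1,
            closeness_floor >= 0, closeness_floor <= 1,
            min_abs_delta >= 0, min_abs_delta <= 2,
            max_fdr >= 0, max_fdr <= 1)
  structure(list(
    sensitive = sensitive, tolerant = tolerant, probe_map = probe_map,
    go_annotation = go_annotation, gene_positions = gene_positions,
    marker_intervals = marker_intervals,
    expression_floor = expression_floor,
    min_fraction_expressed = min_fraction_expressed,
    outlier_cut_height = outlier_cut_height,
    beta = beta, r2_target = r2_target, tom_cutoff = tom_cutoff,
    degree_fraction = degree_fraction, closeness_floor = closeness_floor,
    min_abs_delta = min_abs_delta, max_fdr = max_fdr,
    fdr_method = match.arg(fdr_method),
    enrich_max_p = enrich_max_p, enrich_max_fdr = enrich_max_fdr,
    tf_terms = tf_terms, out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

resolve_group_input <- function(input, probe_map) {
  tbls <- if (is.data.frame(input)) list(input) else as.list(input)
  tbls <- lapply(tbls, function(t) {
    if (is.character(t)) t <- read_expression_table(t)
    if (!is.null(probe_map)) t <- average_probes(t, probe_map)
    t
  })
  merge_datasets(tbls)
}

#' Run the full two-group differential co-expression pipeline
#'
#' Executes, in order: probe averaging and dataset merging, per-sample 0-100
#' rescaling, low-expression filtering and outlier-sample removal for each
#' group; signed network construction and TOM edge export per group;
#' centrality computation, high-centrality screening and cross-network
#' comparison; the Fisher z differential-correlation screen over the shared
#' genes with FDR control and pair selection; and, when annotation inputs
#' are supplied, GO enrichment of the high-centrality genes, marker-interval
#' mapping, TF selection and TF-module construction. All stage tables are
#' returned and, when `out_dir` is set, written as sorted TSVs together with
#' a JSON run manifest (configuration hash, package version, seed, per-stage
#' row counts). The run is deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `expression`,
#'   `networks`, `sft_reports`, `centralities`, `properties`, `comparison`,
#'   `pairs`, `selected_pairs`, `high_centrality_genes`, `enrichment`,
#'   `interval_hits`, `tf_genes`, `tf_modules`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_counts <- list()

  groups <- list(sensitive = config$sensitive, tolerant = config$tolerant)
  expr <- purrr::imap(groups, function(input, grp) {
    tbl <- resolve_group_input(input, config$probe_map)
    tbl <- rescale_samples(tbl)
    tbl <- filter_low_expression(tbl, config$expression_floor,
                                 config$min_fraction_expressed)
    out <- detect_outlier_samples(tbl, config$outlier_cut_height)
    drop_outlier_samples(tbl, out)
  })
  stage_counts$preprocess <- purrr::map_int(expr, nrow)

  nets <- purrr::map(expr, build_network,
                     beta = config$beta, tom_cutoff = config$tom_cutoff,
                     r2_target = config$r2_target)
  stage_counts$network <- purrr::map_int(nets, ~ nrow(.x$edges))

  cents <- purrr::imap(nets, function(nw, grp) {
    if (nrow(nw$edges) == 0L) {
      warning("run_pipeline: ", grp, " network has no edges at the TOM ",
              "cutoff; its centrality tables are empty (a high soft ",
              "threshold such as 22 is the regime the 0.4 cutoff targets)")
      return(select_high_centrality(empty_centrality_table(), n_nodes = 0L,
                                    degree_fraction = config$degree_fraction,
                                    closeness_floor = config$closeness_floor))
    }
    select_high_centrality(compute_centralities(nw$edges),
                           degree_fraction = config$degree_fraction,
                           closeness_floor = config$closeness_floor)
  })
  props <- purrr::map_dfr(nets, function(nw) {
    if (nrow(nw$edges) == 0L) {
      return(tibble::tibble(n_nodes = 0L, n_edges = 0L))
    }
    network_properties(nw$edges)
  }, .id = "group")
  comparison <- list(
    DG = cross_network_comparison(cents$sensitive, cents$tolerant, "DG"),
    CN = cross_network_comparison(cents$sensitive, cents$tolerant, "CN")
  )
  stage_counts$centrality <- purrr::map_int(cents, nrow)

  pairs <- screen_all_pairs(expr$sensitive, expr$tolerant)
  pairs <- adjust_fdr(pairs, method = config$fdr_method)
  selected <- select_significant_pairs(pairs, config$min_abs_delta,
                                       config$max_fdr)
  stage_counts$diffcorr <- c(tested = nrow(pairs), selected = nrow(selected))

  high_genes <- sort(unique(c(
    cents$sensitive$gene_id[cents$sensitive$high_degree |
                              cents$sensitive$high_closeness],
    cents$tolerant$gene_id[cents$tolerant$high_degree |
                             cents$tolerant$high_closeness]
  )))

  enrichment <- NULL
  tf_genes <- character()
  tf_modules <- NULL
  if (!is.null(config$go_annotation) && length(high_genes) > 0L) {
    study <- intersect(high_genes, unique(config$go_annotation$gene))
    enrichment <- if (length(study)) {
      go_enrichment(study, config$go_annotation,
                    max_p = config$enrich_max_p, max_fdr = config$enrich_max_fdr)
    }
    tf_genes <- select_transcription_factors(high_genes, config$go_annotation,
                                             config$tf_terms)
    tf_modules <- build_tf_modules(tf_genes, selected)
    stage_counts$annotate <- c(enriched_terms = NROW(enrichment),
                               tf_genes = length(tf_genes),
                               tf_module_edges = NROW(tf_modules))
  }
  interval_hits <- NULL
  if (!is.null(config$gene_positions) && !is.null(config$marker_intervals)) {
    interval_hits <- map_genes_to_intervals(
      dplyr::filter(config$gene_positions, .data$gene_id %in% high_genes),
      config$marker_intervals
    )
    stage_counts$intervals <- c(hits = nrow(interval_hits))
  }

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "coexdiff",
    version = as.character(utils::packageVersion("coexdiff")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    stages = stage_counts
  )

  result <- structure(list(
    expression = expr, networks = nets,
    sft_reports = purrr::map(nets, "sft_report"),
    centralities = cents, properties = props, comparison = comparison,
    pairs = pairs, selected_pairs = selected,
    high_centrality_genes = high_genes,
    enrichment = enrichment, interval_hits = interval_hits,
    tf_genes = tf_genes, tf_modules = tf_modules,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, file) {
    if (!is.null(tbl)) {
      readr::write_tsv(tibble::as_tibble(tbl), file.path(out_dir, file),
                       progress = FALSE)
    }
  }
  for (grp in names(result$expression)) {
    w(result$expression[[grp]], sprintf("expression_%s.tsv", grp))
    w(result$networks[[grp]]$edges, sprintf("edges_%s.tsv", grp))
    w(result$centralities[[grp]], sprintf("centrality_%s.tsv", grp))
    w(result$sft_reports[[grp]], sprintf("soft_threshold_%s.tsv", grp))
  }
  w(result$properties, "network_properties.tsv")
  w(result$comparison$DG, "comparison_degree.tsv")
  w(result$comparison$CN, "comparison_closeness.tsv")
  w(dplyr::arrange(result$pairs, .data$gene_i, .data$gene_j), "pairs_all.tsv")
  w(dplyr::arrange(result$selected_pairs, .data$gene_i, .data$gene_j),
    "pairs_selected.tsv")
  w(result$enrichment, "enrichment.tsv")
  w(result$interval_hits, "interval_hits.tsv")
  if (length(result$tf_genes)) {
    w(tibble::tibble(gene_id = result$tf_genes), "tf_genes.tsv")
  }
  w(result$tf_modules, "tf_modules.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
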