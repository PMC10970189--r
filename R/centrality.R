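as_igraph <- function(net) {
  stopifnot(is.data.frame(net), all(c("gene_a", "gene_b") %in% names(net)))
  igraph::graph_from_data_frame(
    net[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = attr(net, "nodes") %||%
                            sort(unique(c(net$gene_a, net$gene_b))))
  )
}

empty_centrality_table <- function() {
  out <- tibble::tibble(gene_id = character(), DG = numeric(),
                        BW = numeric(), CN = numeric(), CC = numeric())
  structure(out, class = c("centrality_table", class(out)), n_nodes = 0L)
}

#' Node centralities of a co-expression network
#'
#' Computes the four centralities used to screen genes, all on the unweighted
#' graph induced by the exported edges:
#' * `DG` — degree, the number of incident edges;
#' * `BW` — betweenness, normalised by `(N-1)(N-2)/2` over the whole graph
#'   (so the maximum attainable value is 1 even in disconnected graphs);
#' * `CN` — closeness, the reciprocal of the mean shortest-path length to the
#'   reachable nodes (1 when a node is adjacent to its entire component; 0
#'   for isolated nodes);
#' * `CC` — local clustering coefficient, `2 * triangles / (DG * (DG - 1))`,
#'   0 when `DG < 2`.
#'
#' @param net A `gene_network` edge tibble from [export_edges()].
#' @return A tibble of class `centrality_table` with columns `gene_id`, `DG`,
#'   `BW`, `CN`, `CC`, and attribute `n_nodes`.
#' @export
compute_centralities <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("compute_centralities: empty network")
  deg <- igraph::degree(g)
  bw <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  } else {
    rep(0, n)
  }
  d <- igraph::distances(g)
  cn <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0L) 0 else 1 / mean(reach)
  })
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  out <- tibble::tibble(gene_id = igraph::V(g)$name,
                        DG = unname(deg), BW = unname(bw),
                        CN = unname(cn), CC = unname(cc)) |>
    dplyr::arrange(.data$gene_id)
  structure(out, class = c("centrality_table", class(out)), n_nodes = n)
}

#' Whole-network topological properties
#'
#' Summarises a network with the properties conventionally reported for
#' co-expression networks: diameter and radius (max/min eccentricity, with
#' infinite distances between components excluded), average number of
#' neighbours `2E/N`, mean shortest path over connected pairs, density
#' `2E/(N(N-1))`, degree heterogeneity `sd(degree)/mean(degree)`, mean local
#' clustering coefficient, and the number of connected components.
#'
#' @param net A `gene_network` edge tibble.
#' @return A one-row tibble.
#' @export
network_properties <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("network_properties: empty network")
  e <- igraph::ecount(g)
  d <- igraph::distances(g)
  finite <- is.finite(d) & d > 0
  ecc <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0L) 0 else max(reach)
  })
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    diameter = max(ecc),
    radius = min(ecc),
    avg_neighbors = 2 * e / n,
    avg_shortest_path = if (any(finite)) mean(d[finite]) else 0,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    heterogeneity = if (mean(deg) > 0) stats::sd(deg) / mean(deg) else 0,
    clustering_coefficient = mean(cc),
    n_components = igraph::count_components(g)
  )
}

#' Flag high-degree and high-closeness genes
#'
#' Applies the two centrality screens: a gene is high-degree when it is
#' connected to at least `degree_fraction` of the other genes in its network
#' (`DG >= degree_fraction * (n_nodes - 1)`), and high-closeness when
#' `CN >= closeness_floor`. Both boundaries are inclusive.
#'
#' @param tab A `centrality_table`.
#' @param n_nodes Number of nodes in the network (defaults to the table's
#'   `n_nodes` attribute).
#' @param degree_fraction High-degree threshold as a fraction of other genes
#'   (default 0.5).
#' @param closeness_floor High-closeness threshold (default 0.75).
#' @return The table with logical columns `high_degree` and `high_closeness`
#'   added.
#' @export
select_high_centrality <- function(tab, n_nodes = attr(tab, "n_nodes"),
                                   degree_fraction = 0.5,
                                   closeness_floor = 0.75) {
  stopifnot(!is.null(n_nodes),
            degree_fraction >= 0, degree_fraction <= 1,
            closeness_floor >= 0, closeness_floor <= 1)
  out <- tab |>
    dplyr::mutate(high_degree = .data$DG >= degree_fraction * (n_nodes - 1),
                  high_closeness = .data$CN >= closeness_floor)
  attr(out, "n_nodes") <- n_nodes
  out
}

#' Compare high-centrality genes across two networks
#'
#' For every gene that passes the high-centrality screen in either network,
#' reports its value of `measure` in both networks (0 when the gene is not a
#' node of that network), classifies it as specific to one network or shared,
#' and flags genes that are present in the other network but only weakly
#' connected (degree at most 10% of the other genes for `DG`; closeness at
#' most 0.5 for `CN`).
#'
#' @param tab_a,tab_b `centrality_table`s with screen flags from
#'   [select_high_centrality()]. `tab_a` is conventionally the sensitive
#'   network, `tab_b` the tolerant one.
#' @param measure `"DG"` or `"CN"`.
#' @param weak_fraction Weak-connectivity threshold for `DG` (default 0.1).
#' @param weak_closeness Weak threshold for `CN` (default 0.5).
#' @return A tibble with columns `gene_id`, `value_a`, `value_b`, `class`
#'   (`"A-only"`, `"B-only"`, `"shared"`) and `weak_in_other`.
#' @export
cross_network_comparison <- function(tab_a, tab_b, measure = c("DG", "CN"),
                                     weak_fraction = 0.1, weak_closeness = 0.5) {
  measure <- match.arg(measure)
  flag <- if (measure == "DG") "high_degree" else "high_closeness"
  stopifnot(flag %in% names(tab_a), flag %in% names(tab_b))
  n_a <- attr(tab_a, "n_nodes")
  n_b <- attr(tab_b, "n_nodes")
  high_a <- tab_a$gene_id[tab_a[[flag]]]
  high_b <- tab_b$gene_id[tab_b[[flag]]]
  genes <- sort(union(high_a, high_b))
  val <- function(tab, g) {
    v <- tab[[measure]][match(g, tab$gene_id)]
    ifelse(is.na(v), 0, v)
  }
  weak_thr <- function(n) if (measure == "DG") weak_fraction * (n - 1) else weak_closeness
  tibble::tibble(
    gene_id = genes,
    value_a = val(tab_a, genes),
    value_b = val(tab_b, genes)
  ) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$gene_id %in% high_a & .data$gene_id %in% high_b ~ "shared",
        .data$gene_id %in% high_a ~ "A-only",
        TRUE ~ "B-only"
      ),
      weak_in_other = dplyr::case_when(
        .data$class == "A-only" ~ .data$value_b > 0 & .data$value_b <= weak_thr(n_b),
        .data$class == "B-only" ~ .data$value_a > 0 & .data$value_a <= weak_thr(n_a),
        TRUE ~ FALSE
      )
    )
}
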