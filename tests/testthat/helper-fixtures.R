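# Shared fixtures: tiny graphs as gene_network edge tibbles, small
# expression tables, and random-graph builders. Everything is generated in
# code under fixed seeds.

net_from_edges <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"sign" %in% names(edges)) edges$sign <- "+"
  structure(edges,
            class = c("gene_network", class(tibble::tibble())),
            nodes = nodes %||% sort(unique(c(edges$gene_a, edges$gene_b))),
            cutoff = 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

path3_net <- function() {
  net_from_edges(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c")))
}

triangle_net <- function(ids = c("a", "b", "c")) {
  net_from_edges(data.frame(gene_a = ids[c(1, 1, 2)], gene_b = ids[c(2, 3, 3)]))
}

k4_net <- function() {
  ids <- letters[1:4]
  pairs <- t(utils::combn(ids, 2))
  net_from_edges(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2]))
}

star_net <- function(n_leaves = 4) {
  net_from_edges(data.frame(gene_a = "hub",
                            gene_b = paste0("leaf", seq_len(n_leaves))))
}

# Erdos-Renyi graph as adjacency matrix + matching gene_network
random_graph <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- stats::runif(1) < p
    }
  }
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  net <- net_from_edges(data.frame(gene_a = ids[idx[, 1]],
                                   gene_b = ids[idx[, 2]]),
                        nodes = ids)
  list(adj = adj, net = net, ids = ids)
}

# random symmetric adjacency in [0,1] with zero diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  a
}

small_expression <- function(n_genes = 10, n_samples = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rexp(n_genes * n_samples, rate = 0.02),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_tibble(x)
}

# small simulated dataset shared by several test files
small_sim <- function(seed = 42) {
  simulate_two_group_expression(sim_config(
    n_genes = 80, n_samples_per_group = c(40, 50), n_modules = 2,
    module_size = 15, n_hub_genes = 5, n_diff_pairs = 5, seed = seed
  ))
}
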