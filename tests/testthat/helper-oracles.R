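# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops and textbook formulas, never the code
# paths (or igraph routines) they are checking.

# two-pass Pearson correlation of two vectors
oracle_cor <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- 0
  dx <- 0
  dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# triple-loop signed TOM
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      tom[i, j] <- (a[i, j] + shared) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# BFS distances and shortest-path counts from one source on a logical
# adjacency matrix
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  sigma <- numeric(n)
  d[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(adj[v, ])) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

# all four centralities by brute force: BFS distances, shortest-path counting
# for betweenness, direct triangle counting for the clustering coefficient
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  d <- do.call(rbind, lapply(bfs, `[[`, "d"))
  sigma <- do.call(rbind, lapply(bfs, `[[`, "sigma"))
  dg <- rowSums(adj)
  cn <- vapply(seq_len(n), function(v) {
    reach <- d[v, ][is.finite(d[v, ]) & d[v, ] > 0]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  }, numeric(1))
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    if (length(nb) < 2) return(0)
    tri <- 0
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (i < j && adj[nb[i], nb[j]]) tri <- tri + 1
      }
    }
    2 * tri / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  bw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t || is.infinite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) bw <- bw / ((n - 1) * (n - 2) / 2)
  list(DG = dg, BW = bw, CN = cn, CC = cc)
}

# upper hypergeometric tail P(X >= k) by direct summation of the density
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) stats::dhyper(x, K, N - K, n), numeric(1)))
}

# strip class and bookkeeping attributes, keep only the bare matrix
bare_matrix <- function(m) {
  m <- unclass(m)
  matrix(as.numeric(m), nrow = nrow(m))
}
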