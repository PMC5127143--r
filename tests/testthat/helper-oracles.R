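# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: shortest paths by Floyd-Warshall, components by
# union-find, hierarchical structure by stats::hclust single linkage.

# Brute-force all-pairs shortest paths on a binary adjacency matrix.
floyd_warshall <- function(adj, cap = nrow(adj)) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[is.infinite(D)] <- cap
  dimnames(D) <- dimnames(adj)
  D
}

# Connected components by union-find; returns a membership vector.
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (adj[i, j] == 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Random symmetric similarity matrix, one decimal place (keeps values off
# the integer sigma grid so threshold comparisons are unambiguous).
rand_sim <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- round(runif(sum(upper.tri(v)), 0.1, 99.9), 1)
  v <- v + t(v)
  diag(v) <- 100
  dimnames(v) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  similarity_matrix(v)
}

# Random Erdos-Renyi-ish binary graph as a threshold_network object.
rand_net <- function(n, p, seed, sigma = 50) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(sum(upper.tri(adj))) < p)
  adj <- adj + t(adj)
  labels <- paste0("v", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  structure(list(sigma = sigma, labels = labels, adjacency = adj),
            class = "threshold_network")
}

# Canonical form of a partition (list of label vectors) for set equality.
canon_partition <- function(blocks) {
  sort(vapply(blocks, function(b) paste(sort(b), collapse = "|"), character(1)))
}

# Partition implied by a membership vector over labels.
membership_blocks <- function(membership, labels) {
  unname(split(labels, membership))
}

# Single-linkage partition at threshold sigma via the hclust oracle on
# dissimilarity 100 - s (merge heights <= 100 - sigma stay together).
single_linkage_partition <- function(S, sigma) {
  hc <- stats::hclust(stats::as.dist(100 - S$values), method = "single")
  membership_blocks(stats::cutree(hc, h = 100 - sigma), S$labels)
}

# All blocks of a community_partition, singletons included.
blocks_of <- function(p) c(p$communities, as.list(p$isolates))

edge_set <- function(net) {
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency), arr.ind = TRUE)
  paste(net$labels[idx[, 1]], net$labels[idx[, 2]], sep = "--")
}
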