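# Shared fixture builders; all synthetic, generated at test time.

# Weighted network with exactly the positive entries of `adj` as edges.
net_from_adj <- function(adj) {
  suppressWarnings(threshold_by_density(corr_matrix(adj), density = 1))
}

# Unit-weight adjacency from an edge list on n nodes.
adj_from_edges <- function(n, edges, w = 1) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- w
    a[e[2], e[1]] <- w
  }
  a
}

# Independent brute-force oracle for the edge graph: all O(E^2) edge pairs,
# profiles computed directly from the definition.
brute_edge_graph <- function(net) {
  adj <- net$adjacency
  n <- nrow(adj)
  prof <- function(i) {
    v <- adj[i, ]
    k <- sum(adj[i, ] > 0)
    v[i] <- if (k > 0) sum(adj[i, ]) / k else 0
    v
  }
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  e <- nrow(edges)
  s <- matrix(0, e, e)
  for (a in seq_len(e)) {
    for (b in seq_len(e)) {
      if (a == b) next
      shared <- intersect(edges[a, ], edges[b, ])
      if (length(shared) != 1) next
      ia <- setdiff(edges[a, ], shared)
      ib <- setdiff(edges[b, ], shared)
      pa <- prof(ia); pb <- prof(ib)
      dot <- sum(pa * pb)
      s[a, b] <- dot / (sum(pa^2) + sum(pb^2) - dot)
    }
  }
  s
}

# Brute-force Newman-Girvan weighted modularity (double loop).
brute_modularity <- function(w, labels) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (labels[i] == labels[j]) {
        q <- q + w[i, j] - s[i] * s[j] / two_m
      }
    }
  }
  q / two_m
}

# Random weighted network on n nodes with edge probability p.
random_net <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a), arr.ind = TRUE)
    on <- runif(nrow(ut)) < p
    a[ut[on, , drop = FALSE]] <- runif(sum(on), 0.1, 0.9)
    a <- a + t(a)
  })
  net_from_adj(a)
}

# Planted block edge-similarity matrix: `sizes` block sizes, within/between
# similarities plus symmetric truncated Gaussian noise.
planted_block_similarity <- function(sizes, within = 0.9, between = 0.05,
                                     noise_sd = 0.05, seed = 1) {
  labels <- rep(seq_along(sizes), times = sizes)
  base <- ifelse(outer(labels, labels, "=="), within, between)
  withr::with_seed(seed, {
    z <- matrix(rnorm(length(labels)^2, sd = noise_sd), length(labels))
    z <- (z + t(z)) / 2
    m <- pmin(pmax(base + z, 0), 1)
  })
  diag(m) <- 0
  list(similarity = m, labels = labels)
}

# Agreement up to label permutation.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
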