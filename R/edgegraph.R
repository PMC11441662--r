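# Edge (line) graph construction: modified connectivity profiles and
# Tanimoto interedge similarity for edge pairs sharing a node.

#' Modified connectivity profiles of all nodes
#'
#' For node i the profile is its row of the thresholded adjacency matrix
#' with the diagonal entry replaced by the mean weight of its retained
#' edges (sum of weights / edge count).  The nonzero diagonal keeps the
#' Tanimoto similarity well defined when the two profile owners are
#' directly connected.  Disconnected nodes get an all-zero profile.
#'
#' @param net A `weighted_network`.
#' @return N x N matrix whose rows are the profiles; attribute
#'   `disconnected` marks all-zero rows.
#' @export
modified_profiles <- function(net) {
  a <- net$adjacency
  k <- colSums(a > 0)
  p <- a
  diag(p) <- ifelse(k > 0, rowSums(a) / pmax(k, 1), 0)
  attr(p, "disconnected") <- k == 0
  p
}

#' Modified connectivity profile of one node
#'
#' @param net A `weighted_network`.
#' @param i Node index (1-based).
#' @return Numeric length-N profile vector; attribute `disconnected` is
#'   `TRUE` for an edgeless node (zero vector).
#' @export
modified_profile <- function(net, i) {
  n <- length(net$node_ids)
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > n || i != round(i)) {
    abort(sprintf("node index %s out of range 1..%d", as.character(i), n),
          class = "overlapnet_index_error")
  }
  p <- modified_profiles(net)
  v <- p[i, ]
  attr(v, "disconnected") <- attr(p, "disconnected")[i]
  v
}

#' Tanimoto similarity of two connectivity profiles
#'
#' `S(a, b) = (a . b) / (|a|^2 + |b|^2 - a . b)`, with the dot products
#' running over all N coordinates including the modified diagonal entries.
#' Equals 1 for identical nonzero profiles and 0 for disjoint supports.
#'
#' @param a,b Numeric profile vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop_domain("profiles must have equal length")
  dot <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - dot
  if (denom == 0) {
    abort("similarity undefined: both profiles are zero vectors",
          class = "overlapnet_undefined_similarity")
  }
  dot / denom
}

#' Build the weighted edge graph of a network
#'
#' Vertices are the network's retained edges (sorted by node pair); two
#' edge-vertices are linked iff the edges share exactly one node, with
#' weight equal to the Tanimoto similarity of the modified connectivity
#' profiles of their non-shared endpoints.  Edge pairs without a common
#' node have similarity zero (absent).
#'
#' Construction enumerates, for every node, the pairs of its incident
#' edges (O(sum k_i^2)) and reads the needed profile similarities from a
#' precomputed Gram matrix, rather than scanning all edge pairs.
#'
#' @param net A `weighted_network` with at least 2 edges.
#' @return An `edge_graph`: list with `edges` (tibble `edge_id, i, j`),
#'   `similarity` (sparse symmetric E x E matrix, zero diagonal),
#'   `n_nodes`, `node_ids`.
#' @export
build_edge_graph <- function(net) {
  edges <- network_edges(net)
  e <- nrow(edges)
  if (e < 2) {
    abort("edge graph needs a network with at least 2 edges",
          class = "overlapnet_degenerate_error")
  }
  p <- modified_profiles(net)
  g <- tcrossprod(p)                     # g[i, j] = a_i . a_j
  nrm <- diag(g)

  # incident edge ids per node
  n <- length(net$node_ids)
  incid <- vector("list", n)
  for (nd in seq_len(n)) incid[[nd]] <- integer(0)
  for (r in seq_len(e)) {
    incid[[edges$i[r]]] <- c(incid[[edges$i[r]]], r)
    incid[[edges$j[r]]] <- c(incid[[edges$j[r]]], r)
  }
  other <- function(eid, nd) ifelse(edges$i[eid] == nd, edges$j[eid], edges$i[eid])

  ii <- jj <- xx <- vector("list", n)
  for (nd in seq_len(n)) {
    eids <- incid[[nd]]
    d <- length(eids)
    if (d < 2) next
    prs <- combn(d, 2)
    e1 <- eids[prs[1, ]]
    e2 <- eids[prs[2, ]]
    o1 <- other(e1, nd)
    o2 <- other(e2, nd)
    dot <- g[cbind(o1, o2)]
    sim <- dot / (nrm[o1] + nrm[o2] - dot)
    ii[[nd]] <- pmin(e1, e2)
    jj[[nd]] <- pmax(e1, e2)
    xx[[nd]] <- sim
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  sim <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(e, e),
                              symmetric = TRUE)
  structure(list(edges = edges, similarity = sim,
                 n_nodes = length(net$node_ids), node_ids = net$node_ids),
            class = "edge_graph")
}

#' Construct an edge graph directly from a similarity matrix
#'
#' Used for consensus iterations (the co-occurrence matrix becomes the
#' weighted graph of the next detection round) and for synthetic planted
#' edge graphs in validation.
#'
#' @param similarity Square symmetric nonnegative matrix over edge indices.
#' @param edges Optional tibble `(edge_id, i, j)`; synthesized placeholder
#'   pairs if omitted.
#' @return An `edge_graph`.
#' @export
edge_graph_from_similarity <- function(similarity, edges = NULL) {
  similarity <- as.matrix(similarity)
  check_square_symmetric(similarity, tol = 1e-8, what = "edge similarity")
  e <- nrow(similarity)
  diag(similarity) <- 0
  if (is.null(edges)) {
    edges <- tibble(edge_id = seq_len(e), i = seq_len(e), j = seq_len(e) + e)
  }
  structure(list(edges = edges,
                 similarity = Matrix::Matrix(similarity, sparse = TRUE),
                 n_nodes = NA_integer_, node_ids = NULL),
            class = "edge_graph")
}

#' @export
print.edge_graph <- function(x, ...) {
  nz <- Matrix::nnzero(x$similarity) / 2
  cat(sprintf("<edge_graph> %d edge-vertices, %d similarity links\n",
              nrow(x$edges), as.integer(nz)))
  invisible(x)
}

#' Write an edge graph as two TSV tables
#'
#' `path` receives the similarity triplets `(edge_a, edge_b, similarity)`;
#' `<path>.index.tsv` the edge-index table `(edge_id, i, j)` with 0-based
#' node indices.
#'
#' @param eg An `edge_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_graph <- function(eg, path) {
  s <- methods::as(methods::as(eg$similarity, "generalMatrix"), "TsparseMatrix")
  keep <- s@i < s@j
  readr::write_tsv(tibble(edge_a = s@i[keep] + 1L, edge_b = s@j[keep] + 1L,
                          similarity = s@x[keep]), path)
  readr::write_tsv(tibble(edge_id = eg$edges$edge_id,
                          i = eg$edges$i - 1L, j = eg$edges$j - 1L),
                   paste0(path, ".index.tsv"))
  invisible(path)
}
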