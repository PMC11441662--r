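# Edge-level module detection: seeded Louvain, instance ensembles,
# co-occurrence consensus.

as_igraph_edge_graph <- function(eg) {
  igraph::graph_from_adjacency_matrix(eg$similarity, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Canonical labels: modules renumbered 1..n in order of first appearance,
# which makes partition comparison label-permutation invariant.
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

#' Louvain module detection on an edge graph
#'
#' Runs greedy weighted-modularity (Louvain) optimization on the edge
#' graph.  The vertex visiting order is shuffled under the given seed, so a
#' fixed seed gives identical output and different seeds explore different
#' local optima of the heuristic.
#'
#' @param eg An `edge_graph` (or square similarity matrix).
#' @param seed Integer seed controlling the vertex shuffle.
#' @param resolution Louvain resolution parameter (default 1, the classic
#'   Newman-Girvan objective).
#' @return An `edge_partition`: list with `labels` (edge index to module id,
#'   contiguous 1..n in order of first appearance), `n_modules`,
#'   `modularity` (Q at resolution 1 on the input graph) and `seed`.
#' @export
louvain_partition <- function(eg, seed = 1L, resolution = 1) {
  if (!inherits(eg, "edge_graph")) eg <- edge_graph_from_similarity(eg)
  if (nrow(eg$edges) == 0 || Matrix::nnzero(eg$similarity) == 0) {
    abort("cannot partition an empty edge graph",
          class = "overlapnet_degenerate_error")
  }
  g <- as_igraph_edge_graph(eg)
  nv <- igraph::vcount(g)
  labels <- withr::with_seed(seed, {
    perm <- sample.int(nv)
    gp <- igraph::permute(g, perm)
    memb <- igraph::membership(igraph::cluster_louvain(gp, resolution = resolution))
    as.integer(memb[perm])
  })
  labels <- canonical_labels(labels)
  structure(list(labels = labels,
                 n_modules = max(labels),
                 modularity = graph_modularity(eg, labels),
                 seed = as.integer(seed)),
            class = "edge_partition")
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("<edge_partition> %d edges, %d modules, Q = %.4f (seed %d)\n",
              length(x$labels), x$n_modules, x$modularity, x$seed))
  invisible(x)
}

#' Newman-Girvan weighted modularity of an edge partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / (2m)) * delta(c_i, c_j)` with
#' `s` vertex strengths and `m` the total weight.
#'
#' @param eg An `edge_graph` (or square similarity matrix).
#' @param partition An `edge_partition` or an integer label vector over the
#'   graph's vertices.
#' @return Modularity Q.
#' @export
graph_modularity <- function(eg, partition) {
  if (!inherits(eg, "edge_graph")) eg <- edge_graph_from_similarity(eg)
  labels <- if (inherits(partition, "edge_partition")) partition$labels else partition
  if (length(labels) != nrow(eg$edges)) {
    stop_domain("partition labels must cover every edge-graph vertex")
  }
  if (sum(eg$similarity) == 0) {
    abort("modularity undefined on a graph with zero total weight",
          class = "overlapnet_undefined_error")
  }
  g <- as_igraph_edge_graph(eg)
  igraph::modularity(g, membership = labels, weights = igraph::E(g)$weight)
}

#' Run an ensemble of Louvain instances
#'
#' Repeats [louvain_partition()] with seeds `base_seed .. base_seed + n - 1`.
#' The ensemble's module number is the modal count over instances (ties
#' broken toward the smaller number); modularity is averaged over
#' instances.
#'
#' @param eg An `edge_graph`.
#' @param n_instances Number of detection instances (default 100).
#' @param base_seed First instance seed.
#' @param resolution Louvain resolution.
#' @return An `instance_ensemble`: list with `partitions`, `modal_n`,
#'   `mean_modularity`, `n_per_instance`, `q_per_instance`, `seeds`.
#' @export
run_instances <- function(eg, n_instances = 100L, base_seed = 1L, resolution = 1) {
  if (n_instances < 1) stop_domain("n_instances must be >= 1")
  seeds <- as.integer(base_seed) + seq_len(n_instances) - 1L
  partitions <- lapply(seeds, function(s) louvain_partition(eg, seed = s,
                                                            resolution = resolution))
  ns <- vapply(partitions, function(p) p$n_modules, integer(1))
  qs <- vapply(partitions, function(p) p$modularity, numeric(1))
  structure(list(partitions = partitions,
                 modal_n = modal_count(ns),
                 mean_modularity = mean(qs),
                 n_per_instance = ns,
                 q_per_instance = qs,
                 seeds = seeds),
            class = "instance_ensemble")
}

# Most frequent value; ties broken toward the smaller count (parsimony).
modal_count <- function(ns) {
  tab <- table(ns)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' @export
print.instance_ensemble <- function(x, ...) {
  cat(sprintf("<instance_ensemble> %d instances, modal module number %d, mean Q = %.4f\n",
              length(x$partitions), x$modal_n, x$mean_modularity))
  invisible(x)
}

#' Module co-occurrence matrix of an ensemble
#'
#' Entry (a, b) is the fraction of instances assigning edges a and b to the
#' same module; the diagonal is 1.
#'
#' @param ens An `instance_ensemble`.
#' @return Dense symmetric E x E matrix in `[0, 1]`.
#' @export
cooccurrence <- function(ens) {
  e <- length(ens$partitions[[1]]$labels)
  co <- matrix(0, e, e)
  for (p in ens$partitions) {
    for (mod in seq_len(p$n_modules)) {
      idx <- which(p$labels == mod)
      co[idx, idx] <- co[idx, idx] + 1
    }
  }
  co <- co / length(ens$partitions)
  diag(co) <- 1
  co
}

#' Consensus partition by iterated co-occurrence clustering
#'
#' Runs an instance ensemble on the edge graph, builds the module
#' co-occurrence matrix, treats it as a weighted graph and repeats, until
#' every instance of an iteration returns the same partition (up to module
#' relabelling).  The stable partition's modularity is evaluated on the
#' original edge graph.
#'
#' @param eg An `edge_graph`.
#' @param n_instances Instances per iteration (default 100).
#' @param max_iter Iteration cap (default 20).
#' @param base_seed Master seed; each iteration uses a derived seed block.
#' @param resolution Louvain resolution.
#' @return An `edge_partition` with extra fields `converged` (logical) and
#'   `iterations`; on non-convergence the most frequent partition of the
#'   last iteration is returned with `converged = FALSE` and a warning.
#' @export
consensus_partition <- function(eg, n_instances = 100L, max_iter = 20L,
                                base_seed = 1L, resolution = 1) {
  if (!inherits(eg, "edge_graph")) eg <- edge_graph_from_similarity(eg)
  current <- eg
  iter_seeds <- derive_seeds(base_seed, max_iter)
  last_ens <- NULL
  for (it in seq_len(max_iter)) {
    ens <- run_instances(current, n_instances = n_instances,
                         base_seed = iter_seeds[it], resolution = resolution)
    last_ens <- ens
    canon <- lapply(ens$partitions, function(p) p$labels)  # already canonical
    if (all(vapply(canon[-1], identical, logical(1), canon[[1]]))) {
      labels <- canon[[1]]
      return(structure(list(labels = labels, n_modules = max(labels),
                            modularity = graph_modularity(eg, labels),
                            seed = as.integer(base_seed),
                            converged = TRUE, iterations = it),
                       class = "edge_partition"))
    }
    co <- cooccurrence(ens)
    current <- edge_graph_from_similarity(co, edges = eg$edges)
  }
  warn(sprintf("consensus did not converge within %d iterations; returning the most frequent partition", max_iter))
  keys <- vapply(last_ens$partitions, function(p) paste(p$labels, collapse = ","),
                 character(1))
  best <- names(sort(table(keys), decreasing = TRUE))[1]
  labels <- as.integer(strsplit(best, ",", fixed = TRUE)[[1]])
  structure(list(labels = labels, n_modules = max(labels),
                 modularity = graph_modularity(eg, labels),
                 seed = as.integer(base_seed),
                 converged = FALSE, iterations = max_iter),
            class = "edge_partition")
}

#' Write an edge partition and ensemble summaries
#'
#' @param partition An `edge_partition`.
#' @param path Output TSV path (`edge_id`, `module`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(tibble(edge_id = seq_along(partition$labels),
                          module = partition$labels), path)
  invisible(path)
}

#' @param ens An `instance_ensemble`.
#' @param path Output JSON path.
#' @rdname write_partition
#' @export
write_ensemble_summary <- function(ens, path) {
  jsonlite::write_json(list(
    modal_n = ens$modal_n,
    mean_modularity = ens$mean_modularity,
    n_per_instance = ens$n_per_instance,
    q_per_instance = ens$q_per_instance,
    seeds = ens$seeds
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
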