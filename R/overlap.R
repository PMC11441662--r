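# Node-level overlap quantities derived from an edge partition:
# module-affiliation proportions, normalized entropy, involved-module
# counts, module maps, module matching, system summaries.

#' Per-node module-affiliation proportions
#'
#' For each node, the proportion of its incident edges assigned to each
#' module (`p_ik = edges of i in module k / k_i`).  Edgeless nodes are
#' reported as missing rather than zero-filled.
#'
#' @param partition An `edge_partition` covering the network's edges.
#' @param net The `weighted_network` the partition refers to.
#' @return Tibble `(node, module, proportion)` over modules actually
#'   touched by each node; attribute `missing_nodes` lists edgeless node
#'   indices.
#' @export
node_distribution <- function(partition, net) {
  edges <- network_edges(net)
  if (length(partition$labels) != nrow(edges)) {
    abort("partition does not cover the network's edges",
          class = "overlapnet_consistency_error")
  }
  long <- tibble(
    node = c(edges$i, edges$j),
    module = rep(partition$labels, 2)
  )
  out <- long |>
    dplyr::count(.data$node, .data$module, name = "n_edges") |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(proportion = .data$n_edges / sum(.data$n_edges)) |>
    dplyr::ungroup() |>
    dplyr::select("node", "module", "proportion")
  missing_nodes <- setdiff(seq_along(net$node_ids), unique(out$node))
  attr(out, "missing_nodes") <- missing_nodes
  out
}

#' Normalized Shannon entropy of a module-affiliation distribution
#'
#' `H = -sum_k p_k log2 p_k / log2 n`, where n is the number of modules
#' with `p_k > 0`.  A node whose edges sit in a single module has entropy 0
#' by convention (0/0 := 0); a uniform spread over its modules gives 1.
#'
#' @param p Numeric vector of proportions summing to 1.
#' @return Normalized entropy in `[0, 1]`.
#' @export
nodal_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_domain("proportions must be nonnegative and sum to 1")
  }
  p <- p[p > 0]
  n <- length(p)
  if (n <= 1) return(0)
  h <- -sum(p * log2(p))
  h / log2(n)
}

#' Number of modules a node's edges participate in
#'
#' A node is an overlapping region when the count is 2 or more.
#'
#' @param p Numeric vector of proportions summing to 1.
#' @return Integer count of modules with positive proportion.
#' @export
involved_number <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_domain("proportions must be nonnegative and sum to 1")
  }
  sum(p > 0)
}

#' Node overlap profile of a single partition
#'
#' @param partition An `edge_partition`.
#' @param net The matching `weighted_network`.
#' @return A `node_overlap` tibble `(node, node_id, entropy, n_involved,
#'   missing)` over all network nodes; edgeless nodes have `missing = TRUE`
#'   and `NA` measures.
#' @export
node_overlap <- function(partition, net) {
  dist <- node_distribution(partition, net)
  per <- dist |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(entropy = nodal_entropy(.data$proportion),
                     n_involved = involved_number(.data$proportion),
                     .groups = "drop")
  out <- tibble(node = seq_along(net$node_ids),
                node_id = net$node_ids) |>
    dplyr::left_join(per, by = "node") |>
    dplyr::mutate(missing = is.na(.data$entropy))
  class(out) <- c("node_overlap", class(out))
  out
}

#' Average overlap measures across detection instances
#'
#' Normalized entropy is computed per instance and then averaged per node;
#' the global entropy is the mean of the averaged map over non-missing
#' nodes; modularity is averaged over instances.
#'
#' @param ens An `instance_ensemble`.
#' @param net The matching `weighted_network`.
#' @return List with `node_summary` (a `node_overlap` tibble of averaged
#'   entropy and mean involved-module number), `global_entropy`, `mean_q`
#'   and `modal_n`.
#' @export
summarize_instances <- function(ens, net) {
  per_instance <- lapply(ens$partitions, node_overlap, net = net)
  ent <- vapply(per_instance, function(x) x$entropy, numeric(nrow(per_instance[[1]])))
  ninv <- vapply(per_instance, function(x) as.numeric(x$n_involved),
                 numeric(nrow(per_instance[[1]])))
  if (is.null(dim(ent))) { ent <- matrix(ent, nrow = 1); ninv <- matrix(ninv, nrow = 1) }
  summary <- per_instance[[1]]
  summary$entropy <- rowMeans(ent)
  summary$n_involved <- rowMeans(ninv)
  list(node_summary = summary,
       global_entropy = mean(summary$entropy[!summary$missing]),
       mean_q = ens$mean_modularity,
       modal_n = ens$modal_n)
}

#' Spatial maps of each module
#'
#' Map k holds, for every node, the proportion of that node's edges
#' assigned to module k; across modules the values of a non-missing node
#' sum to 1.
#'
#' @param partition An `edge_partition`.
#' @param net The matching `weighted_network`.
#' @return Wide tibble: `node`, `node_id`, then one `M<k>` column per
#'   module.  Missing (edgeless) nodes carry `NA`.
#' @export
module_maps <- function(partition, net) {
  dist <- node_distribution(partition, net)
  wide <- dist |>
    dplyr::mutate(module = paste0("M", .data$module)) |>
    tidyr::pivot_wider(names_from = "module", values_from = "proportion",
                       values_fill = 0, names_sort = TRUE)
  base <- tibble(node = seq_along(net$node_ids), node_id = net$node_ids)
  out <- dplyr::left_join(base, wide, by = "node")
  # nodes absent from dist (edgeless) keep NA across module columns
  out
}

map_columns <- function(maps) {
  grep("^M[0-9]+$", names(maps), value = TRUE)
}

#' Match module maps between two partitions or groups
#'
#' For each map in `maps_a` (e.g., an adult group's modules), finds the map
#' in `maps_b` with maximal Pearson spatial correlation across nodes.
#' Many-to-one matches are allowed.
#'
#' @param maps_a,maps_b Wide module-map tibbles from [module_maps()] over
#'   the same node set.
#' @return Tibble `(map_a, map_b, r)`; a constant map yields `NA`.
#' @export
match_modules <- function(maps_a, maps_b) {
  ca <- map_columns(maps_a); cb <- map_columns(maps_b)
  if (nrow(maps_a) != nrow(maps_b)) {
    stop_domain("module maps must share the same node set")
  }
  purrr::map_dfr(ca, function(a) {
    va <- maps_a[[a]]
    rs <- vapply(cb, function(b) {
      vb <- maps_b[[b]]
      ok <- !is.na(va) & !is.na(vb)
      if (sd(va[ok]) == 0 || sd(vb[ok]) == 0) return(NA_real_)
      cor(va[ok], vb[ok])
    }, numeric(1))
    if (all(is.na(rs))) return(tibble(map_a = a, map_b = NA_character_, r = NA_real_))
    best <- which.max(rs)
    tibble(map_a = a, map_b = cb[best], r = unname(rs[best]))
  })
}

#' Functional-system composition of a module
#'
#' Percentage of a module's member nodes falling in each functional
#' system.  A node is a member when its proportion in the module exceeds
#' `threshold` (default 0: any incident edge in the module).
#'
#' @param map_values Numeric per-node proportions for one module (a column
#'   of [module_maps()]), aligned with `parc`.
#' @param parc Parcellation tibble with a `system` column, one row per
#'   node in map order.
#' @param threshold Membership threshold on the proportion.
#' @return Tibble `(system, n_nodes, pct)`; percentages sum to 100.
#' @export
system_composition <- function(map_values, parc, threshold = 0) {
  if (length(map_values) != nrow(parc)) {
    abort("parcellation does not cover the map's nodes",
          class = "overlapnet_labeling_error")
  }
  member <- !is.na(map_values) & map_values > threshold
  if (!any(member)) return(tibble(system = character(), n_nodes = integer(), pct = numeric()))
  tibble(system = parc$system[member]) |>
    dplyr::count(.data$system, name = "n_nodes") |>
    dplyr::mutate(pct = 100 * .data$n_nodes / sum(.data$n_nodes))
}

#' System-level summary of a nodal entropy map
#'
#' @param entropy_map Numeric per-node entropies aligned with `parc`
#'   (`NA` for missing nodes).
#' @param parc Parcellation tibble with a `system` column.
#' @return Tibble `(system, mean_entropy, n_nodes)`; the grand mean over
#'   all non-missing nodes is attached as attribute `global_mean`.
#' @export
system_entropy <- function(entropy_map, parc) {
  if (length(entropy_map) != nrow(parc)) {
    abort("parcellation does not cover the map's nodes",
          class = "overlapnet_labeling_error")
  }
  out <- tibble(system = parc$system, entropy = entropy_map) |>
    dplyr::filter(!is.na(.data$entropy)) |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(mean_entropy = mean(.data$entropy),
                     n_nodes = dplyr::n(), .groups = "drop")
  attr(out, "global_mean") <- mean(entropy_map, na.rm = TRUE)
  out
}

#' Write a nodal entropy map as TSV
#'
#' @param overlap A `node_overlap` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_map <- function(overlap, path) {
  readr::write_tsv(overlap, path)
  invisible(path)
}
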