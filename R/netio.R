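#' Construct a correlation matrix object
#'
#' Wraps a square symmetric matrix of Pearson correlations between node
#' time series.  The matrix is symmetrized as `(M + t(M)) / 2` and the
#' diagonal is forced to 1, mirroring how per-scan functional connectivity
#' matrices are normalized on load.
#'
#' @param values Square numeric matrix with entries in `[-1, 1]`.
#' @param node_ids Optional character vector of node labels; defaults to
#'   the matrix dimnames or 0-based ordinals.
#' @return A `corr_matrix`: the symmetrized matrix with unit diagonal and a
#'   `node_ids` attribute.
#' @export
corr_matrix <- function(values, node_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("correlation values must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    stop_format(sprintf("correlation matrix must be square, got %d x %d",
                        nrow(values), ncol(values)))
  }
  if (nrow(values) < 3) stop_format("correlation matrix needs dimension >= 3")
  if (anyNA(values)) stop_format("correlation matrix contains missing values")
  m <- (values + t(values)) / 2
  diag(m) <- 1
  ids <- node_ids %||% colnames(values) %||% default_node_ids(nrow(m))
  if (length(ids) != nrow(m)) stop_format("node_ids length does not match matrix dimension")
  dimnames(m) <- list(ids, ids)
  structure(m, node_ids = as.character(ids), class = c("corr_matrix", "matrix", "array"))
}

#' Read a dense correlation matrix from delimited text
#'
#' Accepts comma- or whitespace-delimited numeric text with an optional
#' single header row of node labels.  The matrix is symmetrized and the
#' diagonal forced to 1 (see [corr_matrix()]).
#'
#' @param path Path to the text file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects comma vs
#'   whitespace from the first line.
#' @return A `corr_matrix`.
#' @export
load_correlation_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_parse("empty matrix file")
  delimiter <- delimiter %||% (if (grepl(",", lines[[1]], fixed = TRUE)) "," else "")
  split_row <- function(l) {
    if (delimiter == "") strsplit(trimws(l), "\\s+")[[1]]
    else trimws(strsplit(l, delimiter, fixed = TRUE)[[1]])
  }
  first <- split_row(lines[[1]])
  # a header row is entirely non-numeric; a single bad cell is a parse error
  has_header <- all(is.na(suppressWarnings(as.numeric(first))))
  header <- if (has_header) first else NULL
  body <- if (has_header) lines[-1] else lines
  rows <- lapply(body, split_row)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop_parse(sprintf("ragged rows: %d columns in row 1 vs %d later",
                       ncols[[1]], ncols[which(ncols != ncols[[1]])[1]]))
  }
  n <- length(rows)
  if (ncols[[1]] != n) {
    stop_format(sprintf("non-square matrix: %d rows x %d columns", n, ncols[[1]]))
  }
  m <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) {
    v <- suppressWarnings(as.numeric(rows[[r]]))
    if (anyNA(v)) {
      cbad <- which(is.na(v))[1]
      stop_parse(sprintf("non-numeric cell at row %d, column %d: '%s'",
                         r, cbad, rows[[r]][cbad]))
    }
    m[r, ] <- v
  }
  corr_matrix(m, node_ids = header)
}

#' Threshold a correlation matrix to a weighted network at fixed density
#'
#' Retains the `E = ceiling(density * N * (N - 1) / 2)` strongest positive
#' off-diagonal correlations as edge weights; everything else (including
#' all negative correlations) is set to zero.  Ties at the cut are broken
#' by stable lexicographic `(i, j)` order.  If fewer than `E` positive
#' correlations exist, all positives are kept and the network is flagged as
#' falling short of the requested density.
#'
#' @param corr A `corr_matrix` (or plain symmetric matrix).
#' @param density Target connection density in `(0, 1]`, the retained
#'   fraction of all `N(N-1)/2` node pairs.
#' @return A `weighted_network`: list with `adjacency` (symmetric
#'   nonnegative matrix, zero diagonal), `node_ids`, `density` (requested),
#'   `achieved_density`, `n_edges` and `shortfall` flag.
#' @export
threshold_by_density <- function(corr, density) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    stop_domain("density must be a single value in (0, 1]")
  }
  if (!inherits(corr, "corr_matrix")) corr <- corr_matrix(corr)
  n <- nrow(corr)
  ids <- attr(corr, "node_ids")
  n_pairs <- n * (n - 1) / 2
  target_e <- as.integer(ceiling(density * n_pairs))

  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[ut]
  pos <- vals > 0
  ut <- ut[pos, , drop = FALSE]
  vals <- vals[pos]
  shortfall <- length(vals) < target_e
  if (shortfall) {
    warn(sprintf("only %d positive correlations available for %d requested edges",
                 length(vals), target_e))
  }
  keep_n <- min(target_e, length(vals))
  # stable tie-break: value desc, then (i, j) lexicographic
  ord <- order(-vals, ut[, 1], ut[, 2])
  if (keep_n < length(vals) && keep_n > 0 &&
      vals[ord[keep_n]] == vals[ord[keep_n + 1]]) {
    message("ties span the density cut; broken by (i, j) order")
  }
  keep <- ord[seq_len(keep_n)]
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  adj[ut[keep, , drop = FALSE]] <- vals[keep]
  adj <- adj + t(adj)

  structure(list(
    adjacency = adj,
    node_ids = ids,
    density = density,
    achieved_density = keep_n / n_pairs,
    n_edges = keep_n,
    shortfall = shortfall
  ), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges (density %.3f%s)\n",
              length(x$node_ids), x$n_edges, x$achieved_density,
              if (x$shortfall) ", shortfall" else ""))
  invisible(x)
}

#' Edge list of a weighted network
#'
#' @param net A `weighted_network`.
#' @return Tibble `(edge_id, i, j, weight)` with 1-based node indices,
#'   `i < j`, sorted by `(i, j)`.
#' @export
network_edges <- function(net) {
  adj <- net$adjacency
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  tibble(edge_id = seq_len(nrow(ut)), i = ut[, 1], j = ut[, 2],
         weight = adj[ut])
}

#' Nodal degrees of a weighted network
#' @param net A `weighted_network`.
#' @return Integer vector of edge counts per node.
#' @export
node_degrees <- function(net) {
  as.integer(colSums(net$adjacency > 0))
}

#' Build a group-level network by averaging correlation matrices
#'
#' Individual correlation matrices are averaged elementwise (raw, no
#' Fisher transform) and the mean matrix thresholded at the given density.
#'
#' @param matrices List of `corr_matrix` objects sharing node ids and order.
#' @param density Target density passed to [threshold_by_density()].
#' @return A `weighted_network` for the group.
#' @export
build_group_network <- function(matrices, density) {
  if (length(matrices) == 0) stop_domain("need at least one matrix")
  matrices <- lapply(matrices, function(m) {
    if (inherits(m, "corr_matrix")) m else corr_matrix(m)
  })
  ids <- attr(matrices[[1]], "node_ids")
  for (m in matrices) {
    if (!identical(attr(m, "node_ids"), ids)) {
      abort("matrices have mismatched node ids/order",
            class = "overlapnet_alignment_error")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  threshold_by_density(corr_matrix(avg, node_ids = ids), density)
}

#' Read a parcellation table
#'
#' Tab-separated table with columns `node_id`, `name`, `system` and
#' optionally `x`, `y`, `z` coordinates (mm).  Systems follow the 7
#' cortical functional systems plus subcortex: VIS, SM, DA, VA, LIM, FP,
#' DM, SUB.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per node.
#' @export
read_parcellation <- function(path) {
  parc <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("node_id", "system")
  missing_cols <- setdiff(required, names(parc))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("parcellation missing columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  known <- c("VIS", "SM", "DA", "VA", "LIM", "FP", "DM", "SUB")
  bad <- setdiff(unique(parc$system), known)
  if (length(bad) > 0) {
    stop_format(sprintf("unknown system labels: %s", paste(bad, collapse = ", ")))
  }
  if (all(c("x", "y", "z") %in% names(parc)) &&
      !all(is.finite(as.matrix(parc[, c("x", "y", "z")])))) {
    stop_format("non-finite parcellation coordinates")
  }
  parc$node_id <- as.character(parc$node_id)
  parc
}

#' Write / read a weighted network as edge-list TSV plus JSON sidecar
#'
#' The edge list holds 0-based node indices and weights; the sidecar
#' records node count, edge count, density and node ids so the network can
#' be reconstructed exactly.
#'
#' @param net A `weighted_network`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  edges <- network_edges(net)
  out <- tibble(i = edges$i - 1L, j = edges$j - 1L, weight = edges$weight)
  readr::write_tsv(out, path)
  meta <- list(n_nodes = length(net$node_ids), n_edges = net$n_edges,
               density = net$density, achieved_density = net$achieved_density,
               shortfall = net$shortfall, node_ids = net$node_ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  n <- meta$n_nodes
  adj <- matrix(0, n, n, dimnames = list(meta$node_ids, meta$node_ids))
  idx <- cbind(edges$i + 1L, edges$j + 1L)
  adj[idx] <- edges$weight
  adj <- adj + t(adj)
  structure(list(adjacency = adj, node_ids = as.character(meta$node_ids),
                 density = meta$density, achieved_density = meta$achieved_density,
                 n_edges = nrow(edges), shortfall = isTRUE(meta$shortfall)),
            class = "weighted_network")
}
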