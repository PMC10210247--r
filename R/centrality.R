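#' Shortest-path hop counts from one node
#'
#' Breadth-first distances on the unweighted RIN: the integer number of edges
#' on the shortest path from `source` to every node. Unreachable nodes are
#' flagged `NA`.
#'
#' @param graph a [residue_graph()]
#' @param source node index (1-based)
#' @return numeric vector of length N; `0` at the source, `NA` where
#'   unreachable
#' @export
shortest_path_lengths <- function(graph, source) {
  source <- as.integer(source)
  if (length(source) != 1L || is.na(source) || source < 1L ||
      source > graph$n_nodes) {
    stop("index error: invalid source node")
  }
  d <- igraph::distances(as_igraph(graph), v = source, algorithm = "unweighted")
  d <- as.numeric(d)
  d[is.infinite(d)] <- NA_real_
  d
}

# full N x N hop-count matrix, NA where unreachable
all_pairs_hops <- function(graph) {
  d <- igraph::distances(as_igraph(graph), algorithm = "unweighted")
  d[is.infinite(d)] <- NA_real_
  dimnames(d) <- NULL
  d
}

#' Closeness centrality of every node
#'
#' For a connected graph, `c_i = (N - 1) / sum_j d(i, j)`: the reciprocal of
#' the mean shortest-path length from node i to all other nodes. Values lie in
#' (0, 1]; `c_i = 1` iff node i is adjacent to every other node.
#'
#' Residue interaction networks of open/unfolded conformations can transiently
#' disconnect. By default (`disconnected = "wf"`) the Wasserman-Faust
#' component-scaled closeness is used:
#' `c_i = ((r_i - 1) / (N - 1)) * ((r_i - 1) / sum_{reachable} d)`,
#' with `r_i` the size of node i's reachable set (including itself). On a
#' connected graph this reduces exactly to the standard formula. Isolated
#' nodes receive closeness 0. `disconnected = "error"` raises instead.
#'
#' `scale` switches between the reachability normalization `(N - 1)/sum d`
#' (`"standard"`, the convention of the common network toolkits) and an
#' additional global `1/N` prefactor (`"per_node"`). The two differ by a
#' constant factor only, which the subsequent fingerprint max-normalization
#' cancels.
#'
#' @param graph a [residue_graph()] with `n_nodes >= 2`
#' @param disconnected `"wf"` (Wasserman-Faust, default) or `"error"`
#' @param scale `"standard"` or `"per_node"`
#' @return numeric vector of length N, entries in `[0, 1]`
#' @export
closeness_centrality <- function(graph, disconnected = c("wf", "error"),
                                 scale = c("standard", "per_node")) {
  disconnected <- match.arg(disconnected)
  scale <- match.arg(scale)
  n <- graph$n_nodes
  if (n < 2L) stop("input error: closeness needs at least 2 nodes")
  d <- all_pairs_hops(graph)
  if (anyNA(d) && disconnected == "error") {
    stop("input error: graph is disconnected (strict mode)")
  }
  reach <- rowSums(!is.na(d))        # r_i, includes self
  dsum <- rowSums(d, na.rm = TRUE)   # sum over reachable j != i (d(i,i)=0)
  cc <- ifelse(reach > 1L, ((reach - 1) / (n - 1)) * ((reach - 1) / dsum), 0)
  if (scale == "per_node") cc <- cc / n
  as.numeric(cc)
}

#' Assemble the closeness fingerprint matrix of a graph series
#'
#' Row t holds the N closeness centralities of frame t, ordered by the
#' protein's amino acid sequence. The result is unnormalized; see
#' [normalize_fingerprints()].
#'
#' @param graphs list of [residue_graph()] objects sharing the same N
#' @param residue_labels optional length-N labels used as column names
#' @inheritParams closeness_centrality
#' @return a `fingerprint_matrix`: list with `values` (m x N matrix),
#'   `normalized` (FALSE), `residue_labels`
#' @export
fingerprint_matrix <- function(graphs, residue_labels = NULL,
                               disconnected = "wf", scale = "standard") {
  if (length(graphs) == 0L) stop("input error: no graphs")
  ns <- vapply(graphs, function(g) g$n_nodes, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("input error: graphs disagree on node count: ",
         paste(unique(ns), collapse = ", "))
  }
  vals <- t(vapply(graphs, closeness_centrality, numeric(ns[1]),
                   disconnected = disconnected, scale = scale))
  new_fingerprint_matrix(vals, normalized = FALSE,
                         residue_labels = residue_labels)
}

new_fingerprint_matrix <- function(values, normalized, residue_labels = NULL,
                                   cutoff = NA_real_) {
  values <- as.matrix(values)
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("input error: fingerprint entries must be finite and non-negative")
  }
  if (is.null(residue_labels)) residue_labels <- paste0("RES", seq_len(ncol(values)))
  if (length(residue_labels) != ncol(values)) {
    stop("input error: residue_labels length mismatch")
  }
  colnames(values) <- residue_labels
  structure(list(values = values, normalized = isTRUE(normalized),
                 residue_labels = as.character(residue_labels),
                 cutoff = cutoff),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d frames x %d residues (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Max-normalize a fingerprint matrix to the range 0-1
#'
#' Every entry is divided by the single global maximum over all frames and
#' residues, so the largest entry becomes exactly 1. Idempotent. Pool all
#' trajectories to be embedded together before normalizing, so they share one
#' scale; per-trajectory normalization is simply this function applied to each
#' trajectory's matrix separately.
#'
#' @param fp a `fingerprint_matrix` with at least one strictly positive entry
#' @return a normalized `fingerprint_matrix`
#' @export
normalize_fingerprints <- function(fp) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  gmax <- max(fp$values)
  if (gmax <= 0) {
    stop("input error: all-zero fingerprint matrix (degenerate/disconnected graphs)")
  }
  new_fingerprint_matrix(fp$values / gmax, normalized = TRUE,
                         residue_labels = fp$residue_labels, cutoff = fp$cutoff)
}

#' One-call featurization: trajectory to closeness fingerprints
#'
#' Convenience wrapper chaining [rin_series()], [fingerprint_matrix()] and
#' optionally [normalize_fingerprints()].
#'
#' @inheritParams rin_series
#' @param normalize max-normalize the result (default TRUE)
#' @inheritParams closeness_centrality
#' @return a `fingerprint_matrix`
#' @export
featurize_trajectory <- function(trajectory, topology, cutoff = 6.0,
                                 neighbor_exclusion = 1L, heavy_only = FALSE,
                                 normalize = TRUE, disconnected = "wf",
                                 scale = "standard") {
  graphs <- rin_series(trajectory, topology, cutoff = cutoff,
                       neighbor_exclusion = neighbor_exclusion,
                       heavy_only = heavy_only)
  fp <- fingerprint_matrix(graphs, residue_labels = topology$residue_labels,
                           disconnected = disconnected, scale = scale)
  fp$cutoff <- cutoff
  if (normalize) fp <- normalize_fingerprints(fp)
  fp
}
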