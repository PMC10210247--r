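#' Residue interaction graphs
#'
#' A `residue_graph` is the per-frame residue interaction network (RIN): an
#' undirected, unweighted graph whose N nodes are the residues of the topology
#' (in sequence order) and whose edges are geometric contacts. Edges are stored
#' as a two-column integer matrix of unordered pairs with `i < j`; no
#' self-loops, no multi-edges.
#'
#' @param n_nodes number of residues N
#' @param edges two-column integer matrix (or empty) of node index pairs
#' @return object of class `residue_graph`
#' @export
residue_graph <- function(n_nodes, edges = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("input error: n_nodes must be >= 1")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L | edges > n_nodes)) stop("index error: edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("input error: self-loop in edge set")
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("residue_graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a residue graph
#' @param graph a [residue_graph()]
#' @return integer edge count M
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Convert a residue graph to an igraph object
#' @param graph a [residue_graph()]
#' @return an [igraph::graph] with `n_nodes` vertices
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  if (nrow(graph$edges) > 0L) g <- igraph::add_edges(g, t(graph$edges))
  g
}

#' Minimum inter-residue atomic distance
#'
#' The smallest Euclidean distance between any atom of residue `i` and any
#' atom of residue `j`, in Angstrom. This is the geometric quantity the RIN
#' contact criterion thresholds.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom)
#' @param topology a [molecular_topology()]
#' @param i,j residue indices (1-based)
#' @param heavy_only drop hydrogens (atom names starting with H, or numbered
#'   hydrogens like "1H...") from the search. Default keeps all atoms.
#' @return distance in Angstrom; `0` when `i == j`
#' @export
min_residue_distance <- function(frame, topology, i, j, heavy_only = FALSE) {
  check_frame(frame, topology)
  check_residue_index(topology, i)
  check_residue_index(topology, j)
  if (i == j) {
    if (length(atoms_of(topology, i, heavy_only)) == 0L) {
      stop("topology error: residue with zero (selected) atoms")
    }
    return(0)  # identical atom sets share a zero-distance pair
  }
  ai <- atoms_of(topology, i, heavy_only)
  aj <- atoms_of(topology, j, heavy_only)
  if (length(ai) == 0L || length(aj) == 0L) {
    stop("topology error: residue with zero (selected) atoms")
  }
  xi <- frame[ai, , drop = FALSE]
  xj <- frame[aj, , drop = FALSE]
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * tcrossprod(xi, xj)
  sqrt(max(0, min(d2)))
}

atoms_of <- function(topology, i, heavy_only = FALSE) {
  idx <- which(topology$atom_res == i)
  if (heavy_only) idx <- idx[!is_hydrogen(topology$atom_names[idx])]
  idx
}

is_hydrogen <- function(name) grepl("^[0-9]*H", name)

#' Build the residue interaction network of one frame
#'
#' An edge connects residues i, j iff they are not directly neighboring in
#' sequence (|i - j| > `neighbor_exclusion` within a chain; chain breaks never
#' count as neighbors) and the minimum distance between any atoms of the two
#' residues is strictly below `cutoff`. The criterion is purely distance
#' based, hence invariant under rigid motion, and deterministic.
#'
#' Periodic boundary conditions are not unwrapped: frames must contain whole,
#' centered molecules.
#'
#' @inheritParams min_residue_distance
#' @param cutoff contact cutoff in Angstrom (default 6.0)
#' @param neighbor_exclusion exclude |i - j| <= this many sequence neighbors
#'   (default 1: only directly neighboring residues)
#' @return a [residue_graph()]
#' @export
build_rin <- function(frame, topology, cutoff = 6.0, neighbor_exclusion = 1L,
                      heavy_only = FALSE) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("input error: cutoff must be > 0")
  check_frame(frame, topology)
  dmin <- residue_min_distance_matrix(frame, topology, heavy_only)
  n <- topology$n_residues
  excl <- sequence_exclusion_mask(topology, neighbor_exclusion)
  contact <- dmin < cutoff & !excl
  contact[lower.tri(contact, diag = TRUE)] <- FALSE
  idx <- which(contact, arr.ind = TRUE)
  residue_graph(n, idx)
}

# full N x N matrix of minimum inter-residue atomic distances (diagonal 0)
residue_min_distance_matrix <- function(frame, topology, heavy_only = FALSE) {
  sel <- seq_len(topology$n_atoms)
  if (heavy_only) sel <- sel[!is_hydrogen(topology$atom_names)]
  res <- topology$atom_res[sel]
  x <- frame[sel, , drop = FALSE]
  if (any(tabulate(res, nbins = topology$n_residues) == 0L)) {
    stop("topology error: residue with zero (selected) atoms")
  }
  n <- topology$n_residues
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  if (length(sel) == n && all(res == seq_len(n))) {
    # single-atom-per-residue fast path (toy chains)
    return(sqrt(d2))
  }
  # group-wise min over atom rows, then over atom columns
  groups <- split(seq_along(res), res)
  rowmin <- do.call(rbind, lapply(groups, function(ii) {
    suppressWarnings(apply(d2[ii, , drop = FALSE], 2L, min))
  }))
  out <- do.call(cbind, lapply(groups, function(jj) {
    suppressWarnings(apply(rowmin[, jj, drop = FALSE], 1L, min))
  }))
  dimnames(out) <- NULL
  sqrt(out)
}

# logical N x N mask of pairs excluded as sequence neighbors (incl. diagonal)
sequence_exclusion_mask <- function(topology, neighbor_exclusion = 1L) {
  n <- topology$n_residues
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  same_chain <- outer(topology$chain, topology$chain, "==")
  (abs(i - j) <= neighbor_exclusion & same_chain) | i == j
}

#' Translate every trajectory frame into a residue interaction network
#'
#' @param trajectory list of coordinate frames (`n_atoms x 3` matrices) or a
#'   3-d array `n_atoms x 3 x n_frames`
#' @inheritParams build_rin
#' @return list of [residue_graph()] objects, one per frame, order preserved
#' @export
rin_series <- function(trajectory, topology, cutoff = 6.0,
                       neighbor_exclusion = 1L, heavy_only = FALSE) {
  frames <- as_frame_list(trajectory)
  if (length(frames) == 0L) stop("input error: empty trajectory")
  lapply(frames, build_rin, topology = topology, cutoff = cutoff,
         neighbor_exclusion = neighbor_exclusion, heavy_only = heavy_only)
}

as_frame_list <- function(trajectory) {
  if (is.array(trajectory) && length(dim(trajectory)) == 3L) {
    return(lapply(seq_len(dim(trajectory)[3L]),
                  function(t) trajectory[, , t, drop = TRUE]))
  }
  if (is.matrix(trajectory)) return(list(trajectory))
  if (is.list(trajectory)) return(trajectory)
  stop("input error: trajectory must be a list of frames or a 3-d array")
}

#' Export a residue graph as an edge-list text file or GraphML
#'
#' @param graph a [residue_graph()]
#' @param path output file
#' @param format `"edgelist"` (two whitespace-separated columns) or
#'   `"graphml"`
#' @return `path`, invisibly
#' @export
write_graph_file <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(graph$edges, path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}
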