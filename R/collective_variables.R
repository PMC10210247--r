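#' Radius of gyration
#'
#' `Rg = sqrt( sum_k w_k |x_k - xbar|^2 / sum_k w_k )` with `xbar` the
#' weighted centroid. Weights are atomic masses by default; `mass_weighted =
#' FALSE` uses unit weights (appropriate for topologies without masses, e.g.
#' toy chains).
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom)
#' @param topology a [molecular_topology()]
#' @param selection atom indices to include (default: all atoms)
#' @param mass_weighted use topology masses as weights (default TRUE)
#' @return radius of gyration in Angstrom
#' @export
radius_of_gyration <- function(frame, topology, selection = NULL,
                               mass_weighted = TRUE) {
  check_frame(frame, topology)
  if (is.null(selection)) selection <- seq_len(topology$n_atoms)
  if (length(selection) == 0L) stop("input error: empty atom selection")
  x <- frame[selection, , drop = FALSE]
  w <- if (mass_weighted) topology$masses[selection] else rep(1, nrow(x))
  ctr <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)) / sum(w))
}

# Kabsch: optimal proper rotation aligning centered y onto centered x
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(y, x))       # 3x3
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps y-frame into x-frame
}

#' Minimal RMSD after optimal rigid superposition
#'
#' Translates both point sets to their centroids, finds the proper rotation
#' minimizing the residual (Kabsch, via singular value decomposition) and
#' returns the root-mean-square deviation of the superposed sets. Zero for
#' congruent sets; invariant under rigid motion of either argument.
#'
#' Degenerate sets (< 3 non-collinear points, e.g. a straight chain) admit no
#' *unique* optimal rotation; the minimal RMSD value itself is still well
#' defined (the rotational freedom lies in the zero-residual null space) and
#' is returned, flagged with a warning.
#'
#' @param x,y `n x 3` coordinate matrices with equal row counts
#' @return RMSD in Angstrom
#' @export
superposed_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)) || ncol(x) != 3L) {
    stop("input error: coordinate sets must be equal-size n x 3 matrices")
  }
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  # rank of the centered cloud: < 2 means all points (near-)collinear
  if (nrow(x) < 3L || qr(xc, tol = 1e-9)$rank < 2L || qr(yc, tol = 1e-9)$rank < 2L) {
    warning("degenerate point set (< 3 non-collinear points): ",
            "optimal rotation is not unique")
  }
  R <- kabsch_rotation(xc, yc)
  sqrt(mean(rowSums((xc - yc %*% t(R))^2)))
}

#' RMSD of a frame to a reference conformation
#'
#' @param frame,reference `n_atoms x 3` coordinate matrices over the same
#'   topology
#' @param topology a [molecular_topology()]
#' @param selection atom indices used both for fitting and for the deviation;
#'   default: backbone atoms (N, CA, C, O) when present, else all atoms
#' @return RMSD in Angstrom
#' @export
rmsd_to_reference <- function(frame, reference, topology, selection = NULL) {
  check_frame(frame, topology)
  check_frame(reference, topology)
  if (is.null(selection)) {
    selection <- select_atoms(topology, atom_names = BACKBONE_ATOMS)
    if (length(selection) == 0L) selection <- seq_len(topology$n_atoms)
  }
  superposed_rmsd(frame[selection, , drop = FALSE],
                  reference[selection, , drop = FALSE])
}

#' Helix RMSD: local RMSD over a residue range
#'
#' RMSD restricted to the backbone atoms of `residue_range` (author
#' numbering), superposed on that same selection (a local fit), so helix
#' formation is detected independent of global orientation. The default range
#' 2-8 targets the N-terminal alpha helix of a 20-residue mini-protein.
#'
#' @inheritParams rmsd_to_reference
#' @param residue_range author residue numbers of the helix (default `2:8`)
#' @return RMSD in Angstrom
#' @export
helix_rmsd <- function(frame, reference, topology, residue_range = 2:8) {
  if (!all(residue_range %in% topology$resno)) {
    stop("input error: residues ", paste(residue_range, collapse = ","),
         " not all present in topology")
  }
  sel <- select_atoms(topology, residues = residue_range,
                      atom_names = BACKBONE_ATOMS, author = TRUE)
  if (length(sel) == 0L) {
    sel <- select_atoms(topology, residues = residue_range, author = TRUE)
  }
  rmsd_to_reference(frame, reference, topology, selection = sel)
}

#' Vertical shift: signed difference of two C-alpha distances
#'
#' `|CA_i - CA_j| - |CA_j - CA_k|` with residues given in author numbering.
#' The default (1, 11, 20) is the classic topology descriptor of a 20-residue
#' mini-protein: the distance from residue 1 to 11 minus the distance from 11
#' to 20, sign preserved.
#'
#' @inheritParams radius_of_gyration
#' @param i,j,k author residue numbers (defaults 1, 11, 20)
#' @return signed distance difference in Angstrom
#' @export
vertical_shift <- function(frame, topology, i = 1, j = 11, k = 20) {
  check_frame(frame, topology)
  ca <- function(res) {
    sel <- select_atoms(topology, residues = res, atom_names = "CA",
                        author = TRUE)
    if (length(sel) != 1L) {
      stop("input error: residue ", res, " has no unique CA atom")
    }
    frame[sel, ]
  }
  pi_ <- ca(i); pj <- ca(j); pk <- ca(k)
  sqrt(sum((pi_ - pj)^2)) - sqrt(sum((pj - pk)^2))
}

#' Signed inter-domain contact score
#'
#' Counts residue-residue contacts (per the RIN criterion of [build_rin()])
#' between a probe domain and two sections of a second domain, scoring
#' contacts with the `red` section `+1` and with the `blue` section `-1`.
#' Used to locate a mobile domain relative to a reference domain split at a
#' hinge residue (e.g. sections on either side of residue 124 of a
#' two-domain protein's conserved domain).
#'
#' Accepts either a coordinate frame (contacts computed via [build_rin()])
#' or an already-built [residue_graph()]; the two pathways agree by
#' construction.
#'
#' @param x a coordinate frame (`n_atoms x 3` matrix) or a [residue_graph()]
#' @param topology a [molecular_topology()]
#' @param probe_domain,red_section,blue_section disjoint sets of residue
#'   indices (1-based sequence positions)
#' @param ... passed to [build_rin()] when `x` is a frame (cutoff etc.)
#' @return integer: (probe-red contacts) - (probe-blue contacts)
#' @export
domain_contact_score <- function(x, topology, probe_domain, red_section,
                                 blue_section, ...) {
  probe <- as.integer(probe_domain)
  red <- as.integer(red_section)
  blue <- as.integer(blue_section)
  if (length(intersect(red, blue)) || length(intersect(probe, red)) ||
      length(intersect(probe, blue))) {
    stop("input error: probe/red/blue residue sets must be disjoint")
  }
  graph <- if (inherits(x, "residue_graph")) x else
    build_rin(x, topology, ...)
  check_residue_index(topology, c(probe, red, blue))
  e <- graph$edges
  in_probe_red <- (e[, 1L] %in% probe & e[, 2L] %in% red) |
    (e[, 2L] %in% probe & e[, 1L] %in% red)
  in_probe_blue <- (e[, 1L] %in% probe & e[, 2L] %in% blue) |
    (e[, 2L] %in% probe & e[, 1L] %in% blue)
  as.integer(sum(in_probe_red) - sum(in_probe_blue))
}

#' 2-d histogram density of map coordinates
#'
#' Bins the m x 2 map coordinates on a regular grid over their bounding box.
#' Counts sum to m; with `normalize = TRUE` the grid is scaled to a
#' probability mass function summing to 1.
#'
#' @param coords `m x 2` coordinate matrix (or a `projected_map`)
#' @param bins number of bins per axis (scalar or length-2)
#' @param normalize return probabilities instead of counts
#' @return list with `counts` (bins x bins matrix), `xbreaks`, `ybreaks`,
#'   and `frame_density`, the per-frame density of the bin each frame falls in
#' @export
map_density <- function(coords, bins = 50L, normalize = FALSE) {
  if (inherits(coords, "projected_map")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("input error: coords must be m x 2")
  if (!all(is.finite(coords))) stop("input error: non-finite coordinates")
  bins <- rep(as.integer(bins), length.out = 2L)
  xb <- seq(min(coords[, 1L]), max(coords[, 1L]), length.out = bins[1L] + 1L)
  yb <- seq(min(coords[, 2L]), max(coords[, 2L]), length.out = bins[2L] + 1L)
  # widen degenerate (zero-extent) axes so every point lands in a bin
  if (xb[1L] == xb[length(xb)]) xb <- xb[1L] + seq(-0.5, 0.5, length.out = bins[1L] + 1L)
  if (yb[1L] == yb[length(yb)]) yb <- yb[1L] + seq(-0.5, 0.5, length.out = bins[2L] + 1L)
  ix <- pmin(pmax(findInterval(coords[, 1L], xb, rightmost.closed = TRUE), 1L), bins[1L])
  iy <- pmin(pmax(findInterval(coords[, 2L], yb, rightmost.closed = TRUE), 1L), bins[2L])
  counts <- matrix(0, bins[1L], bins[2L])
  for (t in seq_len(nrow(coords))) {
    counts[ix[t], iy[t]] <- counts[ix[t], iy[t]] + 1
  }
  dens <- counts
  if (normalize) dens <- dens / sum(dens)
  list(counts = dens, xbreaks = xb, ybreaks = yb,
       frame_density = dens[cbind(ix, iy)])
}

#' Compute a named set of collective-variable series over a trajectory
#'
#' @param trajectory list of frames or 3-d array
#' @param topology a [molecular_topology()]
#' @param reference reference frame for RMSD-type CVs (default: first frame)
#' @param cvs character vector among `"rg"`, `"rmsd"`, `"helix_rmsd"`,
#'   `"vertical_shift"`
#' @param ... extra arguments passed to the individual CV functions
#' @return data frame, one row per frame, one column per CV
#' @export
cv_series <- function(trajectory, topology, reference = NULL,
                      cvs = c("rg", "rmsd"), ...) {
  frames <- as_frame_list(trajectory)
  if (is.null(reference)) reference <- frames[[1L]]
  out <- data.frame(row.names = seq_along(frames))
  for (cv in cvs) {
    out[[cv]] <- switch(
      cv,
      rg = vapply(frames, radius_of_gyration, numeric(1), topology = topology, ...),
      rmsd = vapply(frames, rmsd_to_reference, numeric(1),
                    reference = reference, topology = topology),
      helix_rmsd = vapply(frames, helix_rmsd, numeric(1),
                          reference = reference, topology = topology, ...),
      vertical_shift = vapply(frames, vertical_shift, numeric(1),
                              topology = topology, ...),
      stop("input error: unknown CV '", cv, "'")
    )
  }
  out
}
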