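#' Molecular topology: residues, atom membership and sequence adjacency
#'
#' A `molecular_topology` anchors all residue indexing in rinmap. Residues are
#' stored in protein sequence order and indexed 1..N; every atom belongs to
#' exactly one residue. The fingerprint dimension order, the RIN node order and
#' all collective-variable residue selections refer to this ordering.
#'
#' @param atom_res integer vector, one entry per atom, giving the 1-based
#'   sequence index of the residue each atom belongs to. Indices must cover
#'   `1..N` contiguously and be non-decreasing is not required, but every
#'   residue must own at least one atom.
#' @param atom_names character vector of atom names (e.g. `"CA"`, `"N"`),
#'   one per atom. Used for backbone / C-alpha selections.
#' @param residue_labels character vector of length N with residue labels in
#'   author style, e.g. `"ASP1"`. Defaults to `RES<i>`.
#' @param resno integer vector of length N with author residue numbers
#'   (1-based sequence positions by default).
#' @param chain character vector of length N with chain identifiers; residues
#'   are sequence-adjacent only within the same chain.
#' @param masses numeric vector of per-atom masses (amu); defaults to 1 for
#'   every atom when unknown.
#'
#' @return An object of class `molecular_topology` with fields `n_atoms`,
#'   `n_residues`, `atom_res`, `atom_names`, `residue_labels`, `resno`,
#'   `chain`, `masses`.
#' @export
molecular_topology <- function(atom_res, atom_names = NULL,
                               residue_labels = NULL, resno = NULL,
                               chain = NULL, masses = NULL) {
  atom_res <- as.integer(atom_res)
  if (length(atom_res) == 0L) stop("topology error: no atoms")
  n_res <- max(atom_res)
  if (min(atom_res) < 1L) stop("topology error: residue indices must be >= 1")
  counts <- tabulate(atom_res, nbins = n_res)
  if (any(counts == 0L)) {
    stop("topology error: residue(s) with zero atoms: ",
         paste(which(counts == 0L), collapse = ", "))
  }
  n_atoms <- length(atom_res)
  if (is.null(atom_names)) atom_names <- rep("CA", n_atoms)
  if (length(atom_names) != n_atoms) stop("topology error: atom_names length mismatch")
  if (is.null(resno)) resno <- seq_len(n_res)
  if (is.null(residue_labels)) residue_labels <- paste0("RES", resno)
  if (length(residue_labels) != n_res) stop("topology error: residue_labels length mismatch")
  if (is.null(chain)) chain <- rep("A", n_res)
  if (length(chain) == 1L) chain <- rep(chain, n_res)
  if (length(chain) != n_res) stop("topology error: chain length mismatch")
  if (is.null(masses)) masses <- rep(1, n_atoms)
  if (length(masses) != n_atoms) stop("topology error: masses length mismatch")
  structure(list(
    n_atoms = n_atoms, n_residues = n_res, atom_res = atom_res,
    atom_names = as.character(atom_names),
    residue_labels = as.character(residue_labels),
    resno = as.integer(resno), chain = as.character(chain),
    masses = as.numeric(masses)
  ), class = "molecular_topology")
}

#' @export
print.molecular_topology <- function(x, ...) {
  cat(sprintf("molecular_topology: %d residues, %d atoms, chains: %s\n",
              x$n_residues, x$n_atoms, paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Sequence adjacency predicate
#'
#' Residues i and j are directly neighboring iff |i - j| == 1 and they lie on
#' the same chain. Chain breaks never count as neighbors.
#'
#' @param topology a [molecular_topology()]
#' @param i,j residue indices (1-based sequence positions)
#' @return logical
#' @export
is_sequence_adjacent <- function(topology, i, j) {
  check_residue_index(topology, i)
  check_residue_index(topology, j)
  abs(i - j) == 1L & topology$chain[i] == topology$chain[j]
}

check_residue_index <- function(topology, i) {
  if (any(i < 1L | i > topology$n_residues)) {
    stop("index error: residue index out of range 1..", topology$n_residues)
  }
  invisible(TRUE)
}

#' Validate a coordinate frame against a topology
#'
#' A frame is an `n_atoms x 3` numeric matrix of positions in Angstrom.
#' Molecules are expected whole and centered (periodic images are not
#' unwrapped by rinmap).
#'
#' @param frame numeric matrix, `n_atoms x 3`, Angstrom
#' @param topology a [molecular_topology()]
#' @return the frame, invisibly, after validation
#' @export
check_frame <- function(frame, topology) {
  if (!is.matrix(frame) || ncol(frame) != 3L) {
    stop("input error: frame must be an n_atoms x 3 matrix")
  }
  if (nrow(frame) != topology$n_atoms) {
    stop("format error: frame has ", nrow(frame), " atoms, topology has ",
         topology$n_atoms)
  }
  if (!all(is.finite(frame))) stop("input error: non-finite coordinates in frame")
  invisible(frame)
}

#' Select atom indices by residue and/or atom name
#'
#' @param topology a [molecular_topology()]
#' @param residues residue selector: 1-based sequence indices, or author
#'   residue numbers when `author = TRUE`; `NULL` selects all residues.
#' @param atom_names atom names to keep (e.g. `c("N","CA","C","O")`);
#'   `NULL` keeps all.
#' @param author interpret `residues` as author numbering (`resno`)
#' @return integer vector of atom indices
#' @export
select_atoms <- function(topology, residues = NULL, atom_names = NULL,
                         author = FALSE) {
  keep <- rep(TRUE, topology$n_atoms)
  if (!is.null(residues)) {
    res_idx <- if (author) match(residues, topology$resno) else as.integer(residues)
    if (anyNA(res_idx)) stop("input error: unknown residue(s) in selection")
    check_residue_index(topology, res_idx)
    keep <- keep & topology$atom_res %in% res_idx
  }
  if (!is.null(atom_names)) keep <- keep & topology$atom_names %in% atom_names
  which(keep)
}

#' Backbone atom names used by default selections
#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O")
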