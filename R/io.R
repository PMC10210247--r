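#' Read a topology and trajectory from disk
#'
#' The topology comes from a PDB file; coordinates come from one or more
#' multi-model PDB or DCD files, concatenated in the given order with
#' per-file provenance retained. All coordinates are in Angstrom (the native
#' unit of both formats).
#'
#' @param topology_path PDB file defining residues and atom membership
#' @param trajectory_paths character vector of PDB/DCD coordinate files;
#'   defaults to the topology file itself (useful for multi-model PDBs)
#' @param stride keep every `stride`-th frame (default 1 = all)
#' @return list with `topology` ([molecular_topology()]), `trajectory`
#'   (`n_atoms x 3 x n_frames` array) and `provenance` (source file per frame)
#' @export
read_trajectory <- function(topology_path, trajectory_paths = topology_path,
                            stride = 1L) {
  if (!file.exists(topology_path)) {
    stop("I/O error: cannot read topology: ", topology_path)
  }
  pdb <- bio3d::read.pdb(topology_path, multi = FALSE, verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  res_key <- paste(atom$chain, atom$resno, atom$insert)
  atom_res <- match(res_key, unique(res_key))
  first <- !duplicated(atom_res)
  masses <- tryCatch(bio3d::atom2mass(atom$elety, rescue = TRUE),
                     error = function(e) rep(1, nrow(atom)),
                     warning = function(w) suppressWarnings(
                       bio3d::atom2mass(atom$elety, rescue = TRUE)))
  topology <- molecular_topology(
    atom_res = atom_res,
    atom_names = atom$elety,
    residue_labels = paste0(atom$resid[first], atom$resno[first]),
    resno = atom$resno[first],
    chain = ifelse(is.na(atom$chain[first]), "A", atom$chain[first]),
    masses = masses
  )
  frames <- list(); provenance <- character(0)
  for (path in trajectory_paths) {
    if (!file.exists(path)) stop("I/O error: cannot read trajectory: ", path)
    xyz <- read_coordinate_file(path)
    if (ncol(xyz) != 3L * topology$n_atoms) {
      stop("format error: ", path, " has ", ncol(xyz) / 3,
           " atoms per frame, topology has ", topology$n_atoms)
    }
    these <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    })
    frames <- c(frames, these)
    provenance <- c(provenance, rep(path, length(these)))
  }
  keep <- seq(1L, length(frames), by = as.integer(stride))
  traj <- array(NA_real_, c(topology$n_atoms, 3L, length(keep)))
  for (i in seq_along(keep)) traj[, , i] <- frames[[keep[i]]]
  list(topology = topology, trajectory = traj, provenance = provenance[keep])
}

# frames x (3 * n_atoms) coordinate matrix from a PDB or DCD file
read_coordinate_file <- function(path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    return(bio3d::read.dcd(path, verbose = FALSE))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz
}

#' Persist and restore fingerprint matrices
#'
#' The matrix is written as CSV (header = residue labels, one row per frame)
#' with a JSON sidecar `<path>.meta.json` carrying the metadata the CSV
#' cannot (normalized flag, contact cutoff, creation info). Values round-trip
#' at full double precision (17 significant digits).
#'
#' @param fp a `fingerprint_matrix`
#' @param path CSV output path
#' @return `path` / the restored `fingerprint_matrix`
#' @export
write_features <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  df <- as.data.frame(signif(fp$values, 17))
  names(df) <- fp$residue_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(format = "rinmap-features", version = 1L,
               normalized = fp$normalized, cutoff = fp$cutoff,
               n_frames = nrow(fp$values), n_residues = ncol(fp$values),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such feature file: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("I/O error: missing metadata sidecar ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("normalized", "cutoff")) {
    if (is.null(meta[[field]])) {
      stop("I/O error: metadata attribute '", field, "' missing in ", meta_path)
    }
  }
  df <- utils::read.csv(path, check.names = FALSE)
  new_fingerprint_matrix(as.matrix(df), normalized = isTRUE(meta$normalized),
                         residue_labels = names(df),
                         cutoff = as.numeric(meta$cutoff))
}

#' Write a projected map (+ CV columns) as CSV
#'
#' @param pmap a `projected_map`
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_projection <- function(pmap, path) {
  stopifnot(inherits(pmap, "projected_map"))
  df <- data.frame(frame = pmap$frame_ids,
                   x = pmap$coords[, 1L],
                   y = if (ncol(pmap$coords) > 1L) pmap$coords[, 2L] else NA_real_)
  for (nm in names(pmap$cv)) df[[nm]] <- pmap$cv[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a 2-d map colored by a collective variable or by density
#'
#' Renders the projected map as a scatter plot with a color bar and writes
#' it to PNG or SVG (chosen by the output extension). Deterministic for
#' fixed inputs.
#'
#' @param pmap a `projected_map` (or plain m x 2 matrix)
#' @param color_by `"density"` (default; colors each frame by the occupancy
#'   of its [map_density()] bin) or the name of a CV column attached with
#'   [add_cv()], or a numeric vector of length m
#' @param output_path image file ending in `.png` or `.svg`
#' @param bins density grid resolution (only for `color_by = "density"`)
#' @param point_size scatter point size
#' @return `output_path`, invisibly
#' @export
plot_map <- function(pmap, color_by = "density", output_path, bins = 50L,
                     point_size = 0.8) {
  coords <- if (inherits(pmap, "projected_map")) pmap$coords else as.matrix(pmap)
  m <- nrow(coords)
  if (is.character(color_by) && length(color_by) == 1L) {
    if (color_by == "density") {
      values <- map_density(coords, bins = bins)$frame_density
      label <- "density"
    } else {
      if (!inherits(pmap, "projected_map") || is.null(pmap$cv[[color_by]])) {
        stop("input error: no CV column '", color_by, "' attached to the map")
      }
      values <- pmap$cv[[color_by]]
      label <- color_by
    }
  } else {
    values <- as.numeric(color_by)
    label <- "value"
  }
  if (length(values) != m) {
    stop("input error: color series length ", length(values),
         " != ", m, " frames")
  }
  df <- data.frame(x = coords[, 1L], y = coords[, 2L], v = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$v)) +
    ggplot2::geom_point(size = point_size, alpha = 0.8) +
    ggplot2::scale_color_viridis_c(name = label) +
    ggplot2::labs(x = "map dimension 1", y = "map dimension 2") +
    ggplot2::theme_minimal()
  ext <- tolower(tools::file_ext(output_path))
  if (!ext %in% c("png", "svg")) {
    stop("input error: output must end in .png or .svg")
  }
  if (ext == "png") {
    grDevices::png(output_path, width = 1600, height = 1200, res = 200,
                   type = "cairo")
  } else {
    grDevices::svg(output_path, width = 8, height = 6)
  }
  print(p)
  grDevices::dev.off()
  invisible(output_path)
}
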