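# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Analytic graph families for testing and validation
#'
#' Canonical unweighted graphs with known closeness centralities: paths,
#' cycles, complete graphs and stars.
#'
#' @param kind one of `"path"`, `"cycle"`, `"complete"`, `"star"`
#' @param n number of nodes (>= 2; >= 3 for cycles). Stars have node 1 as
#'   the center.
#' @return a [residue_graph()]
#' @export
analytic_graph <- function(kind = c("path", "cycle", "complete", "star"), n) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L || (kind == "cycle" && n < 3L)) {
    stop("input error: need n >= 2 (>= 3 for cycle), got ", n)
  }
  edges <- switch(kind,
    path = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
    cycle = rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(1L, n)),
    complete = t(utils::combn(n, 2L)),
    star = cbind(1L, 2L:n)
  )
  residue_graph(n, edges)
}

#' Random connected Erdos-Renyi graph
#'
#' Draws G(n, p) repeatedly until the sample is connected. Reproducible for
#' a fixed seed; the caller's RNG state is untouched.
#'
#' @param n number of nodes (>= 2)
#' @param p edge probability in (0, 1]
#' @param seed integer seed
#' @param max_tries resampling budget before giving up
#' @return a connected [residue_graph()]
#' @export
random_connected_graph <- function(n, p, seed = 1L, max_tries = 200L) {
  n <- as.integer(n)
  if (n < 2L) stop("input error: need n >= 2")
  if (p <= 0 || p > 1) stop("input error: edge probability must be in (0, 1]")
  with_seed(seed, {
    pairs <- t(utils::combn(n, 2L))
    for (try in seq_len(max_tries)) {
      keep <- stats::runif(nrow(pairs)) < p
      g <- residue_graph(n, pairs[keep, , drop = FALSE])
      if (igraph::is_connected(as_igraph(g))) return(g)
    }
    stop("generation error: no connected sample in ", max_tries,
         " tries (p too small?)")
  })
}

#' Specification of a synthetic two-state toy trajectory
#'
#' Defines a single-atom-per-residue polymer chain that interconverts between
#' a compact (high-contact, helical) and an extended (low-contact, straight)
#' state, emulating the folded/unfolded or domain-docked/domain-separated
#' dichotomy of real protein trajectories at toy scale.
#'
#' Compact-state geometry is an ideal helix (radius `compact_radius`, rise
#' `compact_rise` per residue, twist 100 degrees) whose parameters place
#' sequence-separation 2, 3 and 4 pairs below the 6 Angstrom contact cutoff.
#' Extended-state geometry is a straight chain with `extended_spacing`
#' between consecutive residues, so all non-neighbor pairs sit at >= twice
#' that spacing (7.6 Angstrom by default) and form no contacts.
#'
#' @param n_residues chain length (>= 4); default 20
#' @param n_frames number of frames; default 2000
#' @param p_switch per-frame probability of switching state (Markov chain);
#'   default 0.02
#' @param noise_sigma isotropic Gaussian coordinate jitter, Angstrom;
#'   default 0.3
#' @param seed integer seed; generation is bit-reproducible per seed
#' @param compact_radius helix radius, Angstrom (default 2.3)
#' @param compact_rise helix rise per residue, Angstrom (default 1.4)
#' @param extended_spacing consecutive-residue spacing of the straight
#'   chain, Angstrom (default 3.8)
#' @return object of class `toy_trajectory_spec`
#' @export
toy_trajectory_spec <- function(n_residues = 20L, n_frames = 2000L,
                                p_switch = 0.02, noise_sigma = 0.3,
                                seed = 1L, compact_radius = 2.3,
                                compact_rise = 1.4, extended_spacing = 3.8) {
  if (n_residues < 4L) stop("input error: n_residues must be >= 4")
  if (n_frames < 1L) stop("input error: n_frames must be >= 1")
  if (p_switch < 0 || p_switch > 1) stop("input error: p_switch must be in [0, 1]")
  if (noise_sigma < 0) stop("input error: noise_sigma must be >= 0")
  spec <- structure(list(
    n_residues = as.integer(n_residues), n_frames = as.integer(n_frames),
    p_switch = p_switch, noise_sigma = noise_sigma, seed = as.integer(seed),
    compact_radius = compact_radius, compact_rise = compact_rise,
    extended_spacing = extended_spacing
  ), class = "toy_trajectory_spec")
  check_state_geometry(spec)
  spec
}

# the two states must be distinguishable by the 6 A contact criterion:
# compact must form non-neighbor contacts, extended must not
check_state_geometry <- function(spec, cutoff = 6.0) {
  if (2 * spec$extended_spacing <= cutoff) {
    stop("spec error: extended state forms contacts (2 * extended_spacing <= ",
         cutoff, " A); states indistinguishable")
  }
  xyz <- helix_coords(spec$n_residues, spec$compact_radius, spec$compact_rise)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(row(d) - col(d))
  if (!any(d[sep > 1L] < cutoff)) {
    stop("spec error: compact state forms no non-neighbor contacts; ",
         "states indistinguishable")
  }
  invisible(TRUE)
}

helix_coords <- function(n, radius, rise, twist_deg = 100) {
  i <- seq_len(n) - 1L
  th <- i * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

extended_coords <- function(n, spacing) {
  cbind((seq_len(n) - 1L) * spacing, 0, 0)
}

#' Generate a synthetic two-state toy trajectory
#'
#' Produces a single-atom-per-residue chain trajectory that switches between
#' a compact helical state and an extended straight state via a two-state
#' Markov chain (switch probability `p_switch` per frame, starting extended),
#' with isotropic Gaussian jitter of standard deviation `noise_sigma` added
#' to every coordinate. Bit-reproducible for a fixed seed.
#'
#' With zero noise, extended frames yield an empty residue interaction
#' network (exercising disconnected-graph handling downstream) and all
#' compact frames share one identical dense edge set.
#'
#' @param spec a [toy_trajectory_spec()]
#' @return list with `trajectory` (`n_residues x 3 x n_frames` array,
#'   Angstrom), `topology` (a [molecular_topology()] with one CA atom per
#'   residue), `labels` (character vector, `"compact"` or `"extended"` per
#'   frame) and `spec`
#' @export
toy_two_state_trajectory <- function(spec = toy_trajectory_spec()) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  n <- spec$n_residues; m <- spec$n_frames
  base <- list(extended = extended_coords(n, spec$extended_spacing),
               compact = helix_coords(n, spec$compact_radius, spec$compact_rise))
  with_seed(spec$seed, {
    switches <- stats::runif(m) < spec$p_switch
    switches[1L] <- FALSE
    state <- cumsum(switches) %% 2L          # 0 = extended, 1 = compact
    labels <- ifelse(state == 1L, "compact", "extended")
    traj <- array(NA_real_, c(n, 3L, m))
    for (t in seq_len(m)) {
      jitter <- if (spec$noise_sigma > 0) {
        matrix(stats::rnorm(n * 3L, 0, spec$noise_sigma), n, 3L)
      } else 0
      traj[, , t] <- base[[labels[t]]] + jitter
    }
    topology <- molecular_topology(
      atom_res = seq_len(n), atom_names = rep("CA", n),
      residue_labels = paste0("GLY", seq_len(n))
    )
    list(trajectory = traj, topology = topology, labels = labels, spec = spec)
  })
}

#' Write a toy trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL record, so the full file-based pipeline
#' (read, featurize, embed) can be exercised end-to-end on disk.
#'
#' @param toy result of [toy_two_state_trajectory()] (or any list with
#'   `trajectory` and `topology`)
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
write_trajectory_pdb <- function(toy, path) {
  topo <- toy$topology
  frames <- as_frame_list(toy$trajectory)
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  resid3 <- substr(paste0(sub("[0-9]+$", "", topo$residue_labels), "XXX"), 1L, 3L)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topo$resno[topo$atom_res],
                   resid = resid3[topo$atom_res],
                   elety = topo$atom_names,
                   chain = topo$chain[topo$atom_res])
  invisible(path)
}
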