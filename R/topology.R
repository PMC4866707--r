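# Core containers: topology (atoms/residues) and frame_series (T x N x 3 coords).
# Internal residue indexing is 0-based and contiguous across the whole system;
# author (deposited) numbering is only reachable through a numbering_map.

#' Construct a molecular topology
#'
#' A `topology` couples an atom table to residue bookkeeping and is the
#' substrate of every trajectory analysis in the package. Atoms are stored as
#' a tibble; residue indices are 0-based and contiguous per chain, while the
#' deposited ("author") residue numbers are carried alongside and reachable
#' through [build_numbering_map()].
#'
#' @param atoms Data frame with columns `name` (atom name, unique within a
#'   residue), `element`, `residue_index` (0-based integer, contiguous per
#'   chain), `residue_name` (three-letter code), `chain_id`, and
#'   `author_resno` (deposited residue number). Optional columns `charge`
#'   (partial charge, e), `epsilon` (LJ well depth, kcal/mol) and `sigma`
#'   (LJ diameter, Angstrom) are kept if present.
#' @return An object of class `topology`.
#' @seealso [read_pdb_models()], [assign_params()]
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("name", "element", "residue_index", "residue_name",
                "chain_id", "author_resno")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("topology atoms table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$author_resno <- as.integer(atoms$author_resno)
  # contiguity per chain and atom-name uniqueness within residues
  for (ch in unique(atoms$chain_id)) {
    ri <- sort(unique(atoms$residue_index[atoms$chain_id == ch]))
    if (length(ri) > 1 && any(diff(ri) != 1L)) {
      abort(sprintf("residue_index not contiguous within chain '%s'", ch))
    }
  }
  dup <- duplicated(atoms[, c("residue_index", "name")])
  if (any(dup)) {
    abort(sprintf("duplicate atom name(s) within a residue: %s",
                  paste(unique(atoms$name[dup]), collapse = ", ")))
  }
  residues <- distinct(atoms[, c("residue_index", "residue_name",
                                 "chain_id", "author_resno")])
  residues <- arrange(residues, .data$residue_index)
  if (anyDuplicated(residues$residue_index)) {
    abort("a residue_index maps to more than one residue identity")
  }
  structure(
    list(atoms = atoms, residues = residues,
         n_atoms = nrow(atoms), n_residues = nrow(residues)),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  chains <- unique(x$atoms$chain_id)
  cat(sprintf("<topology> %d atoms, %d residues, %d chain(s) [%s]\n",
              x$n_atoms, x$n_residues, length(chains),
              paste(chains, collapse = ", ")))
  invisible(x)
}

is_topology <- function(x) inherits(x, "topology")

#' Construct a trajectory frame series
#'
#' Holds trajectory coordinates as a `frames x atoms x 3` array in Angstrom,
#' together with the frame spacing in nanoseconds and optional run-boundary
#' annotation for trajectories concatenated from independent simulations.
#' Frame spacing is always supplied by the caller (configuration), never read
#' from file headers, which are unreliable in concatenated DCDs.
#'
#' @param coords Numeric array `T x N x 3` (frames, atoms, xyz) or a single
#'   `N x 3` matrix for a one-frame series.
#' @param frame_interval_ns Positive frame spacing in nanoseconds.
#' @param source Free-text label recording where the frames came from.
#' @param run_lengths Optional integer vector of frames-per-run for
#'   concatenated multi-run trajectories; must sum to the frame count.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(coords, frame_interval_ns = 1, source = "",
                         run_lengths = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be a T x N x 3 array")
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0) {
    abort("frame_interval_ns must be > 0")
  }
  nf <- dim(coords)[1]
  if (!is.null(run_lengths)) {
    run_lengths <- as.integer(run_lengths)
    if (any(run_lengths <= 0) || sum(run_lengths) != nf) {
      abort("run_lengths must be positive and sum to the frame count")
    }
  }
  structure(
    list(coords = coords, frame_interval_ns = frame_interval_ns,
         source = source, run_lengths = run_lengths,
         n_frames = nf, n_atoms = dim(coords)[2]),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  runs <- if (is.null(x$run_lengths)) "1 run" else
    sprintf("%d runs (%s)", length(x$run_lengths),
            paste(x$run_lengths, collapse = "+"))
  cat(sprintf("<frame_series> %d frames x %d atoms, %g ns/frame, %s\n",
              x$n_frames, x$n_atoms, x$frame_interval_ns, runs))
  invisible(x)
}

is_frame_series <- function(x) inherits(x, "frame_series")

# Per-frame run label (integer); all 1 when no run annotation.
run_labels <- function(frames) {
  if (is.null(frames$run_lengths)) rep(1L, frames$n_frames)
  else rep(seq_along(frames$run_lengths), frames$run_lengths)
}

# Times in ns for each frame (1-based frame index times spacing).
frame_times <- function(frames) {
  seq_len(frames$n_frames) * frames$frame_interval_ns
}

# Extract one frame as an N x 3 matrix.
frame_coords <- function(frames, i) {
  matrix(frames$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

check_frames_topology <- function(frames, topology) {
  if (frames$n_atoms != topology$n_atoms) {
    abort(sprintf("frame series has %d atoms but topology has %d",
                  frames$n_atoms, topology$n_atoms))
  }
  invisible(TRUE)
}

#' Select atom indices from a topology
#'
#' Simple conjunctive atom selector used throughout the geometry and
#' energetics stages. All supplied conditions must hold.
#'
#' @param topology A [topology()].
#' @param residue_index Integer vector of 0-based internal residue indices.
#' @param residue_name Character vector of residue names.
#' @param atom_name Character vector of atom names.
#' @param chain_id Character vector of chain identifiers.
#' @param sidechain If `TRUE`, keep only side-chain heavy atoms (excludes
#'   backbone N/CA/C/O, amide H and all hydrogens).
#' @return Integer vector of atom row indices (1-based into the atom table).
#' @export
select_atoms <- function(topology, residue_index = NULL, residue_name = NULL,
                         atom_name = NULL, chain_id = NULL,
                         sidechain = FALSE) {
  stopifnot(is_topology(topology))
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residue_index)) keep <- keep & at$residue_index %in% residue_index
  if (!is.null(residue_name)) keep <- keep & at$residue_name %in% residue_name
  if (!is.null(atom_name)) keep <- keep & at$name %in% atom_name
  if (!is.null(chain_id)) keep <- keep & at$chain_id %in% chain_id
  if (sidechain) {
    keep <- keep & !(at$name %in% c("N", "CA", "C", "O", "OXT", "H")) &
      at$element != "H"
  }
  which(keep)
}

# Side-chain heavy atoms of a residue, falling back to CA for glycine-like
# residues that have none (robust reduction for centroid distances).
sidechain_or_ca <- function(topology, residue_index) {
  idx <- select_atoms(topology, residue_index = residue_index,
                      sidechain = TRUE)
  if (length(idx) == 0) {
    idx <- select_atoms(topology, residue_index = residue_index,
                        atom_name = "CA")
  }
  if (length(idx) == 0) {
    abort(sprintf("residue %d has neither side-chain heavy atoms nor CA",
                  residue_index))
  }
  idx
}
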