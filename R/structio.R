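# Structure and trajectory I/O. PDB reading/writing and DCD reading delegate
# to bio3d; the DCD writer (absent from bio3d) implements the CHARMM/NAMD
# 32-bit little-endian dialect directly.

#' Read a (multi-model) PDB file
#'
#' Parses a PDB file with one or more MODEL records into a shared [topology()]
#' and one coordinate set per model, as produced for NMR ensembles. Author
#' residue numbers are preserved; internal residue indices are 0-based and
#' contiguous in order of appearance.
#'
#' @param source Path to a PDB file, or the file's text content (detected by
#'   the presence of a newline).
#' @return List with elements `topology` and `models` (list of `N x 3`
#'   coordinate matrices, Angstrom, one per MODEL).
#' @export
read_pdb_models <- function(source) {
  path <- source
  if (length(source) == 1 && grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(source, "\n")[[1]], path)
    on.exit(unlink(path))
  } else if (!file.exists(path)) {
    abort(sprintf("cannot read PDB file '%s'", path))
  }
  # validate per-model atom counts before delegating to the parser
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) == length(model_starts)) {
      counts <- mapply(function(s, e) {
        sum(grepl("^(ATOM|HETATM)", lines[s:e]))
      }, model_starts, ends)
      if (length(unique(counts)) > 1) {
        abort("PDB format error: models differ in atom count")
      }
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse PDB: %s",
                                      conditionMessage(e)))
  )
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  # 0-based residue index in order of appearance of (chain, resno, insert)
  res_key <- paste(chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  residue_index <- as.integer(match(res_key, unique(res_key))) - 1L
  elesy <- at$elesy
  guess <- toupper(substr(gsub("[0-9']", "", at$elety), 1, 1))
  element <- ifelse(is.na(elesy) | elesy == "", guess, trimws(elesy))
  atoms <- tibble(
    name = trimws(at$elety), element = element,
    residue_index = residue_index, residue_name = trimws(at$resid),
    chain_id = chain, author_resno = as.integer(at$resno)
  )
  top <- topology(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  models <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  list(topology = top, models = models)
}

#' Write a (multi-model) PDB file
#'
#' @param topology A [topology()].
#' @param coords `N x 3` matrix, list of such matrices, or a [frame_series()];
#'   more than one coordinate set is written as consecutive MODEL records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, coords, path) {
  stopifnot(is_topology(topology))
  sets <- coord_sets(coords, topology)
  if (length(sets) == 0) abort("no coordinate sets to write")
  xyz <- do.call(rbind, lapply(sets, function(m) as.vector(t(m))))
  if (!all(is.finite(xyz))) abort("coordinates must be finite")
  if (any(abs(xyz) > 9999.999)) {
    abort("coordinate overflow: |x| > 9999.999 A does not fit PDB columns")
  }
  at <- topology$atoms
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(nrow(at)), elety = at$name, alt = NA,
    resid = at$residue_name, chain = at$chain_id, resno = at$author_resno,
    insert = NA, x = sets[[1]][, 1], y = sets[[1]][, 2], z = sets[[1]][, 3],
    o = 1, b = 0, segid = NA, elesy = at$element, charge = NA
  )
  pdb <- structure(list(atom = atom, xyz = bio3d::as.xyz(xyz),
                        calpha = at$name == "CA"), class = "pdb")
  tryCatch(bio3d::write.pdb(pdb, file = path, xyz = pdb$xyz),
           error = function(e) abort(sprintf("cannot write PDB to '%s': %s",
                                             path, conditionMessage(e))))
  invisible(path)
}

# normalize the accepted coordinate-argument forms to a list of N x 3 matrices
coord_sets <- function(coords, topology) {
  if (is_frame_series(coords)) {
    check_frames_topology(coords, topology)
    return(lapply(seq_len(coords$n_frames), function(i) frame_coords(coords, i)))
  }
  if (is.matrix(coords)) coords <- list(coords)
  if (!is.list(coords)) abort("coords must be a matrix, list or frame_series")
  lapply(coords, function(m) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != topology$n_atoms) {
      abort("each coordinate set must be an N x 3 matrix matching the topology")
    }
    m
  })
}

#' Read a DCD trajectory
#'
#' Reads a CHARMM/NAMD binary DCD against a companion topology. The frame
#' spacing is configuration, not read from the file header: concatenated
#' supplementary trajectories carry unreliable header timing.
#'
#' @param path Path to the DCD file.
#' @param topology A [topology()]; its atom count must match the file.
#' @param frame_interval_ns Frame spacing in nanoseconds (default 10, the
#'   spacing of the deposited supplementary trajectory sets).
#' @param run_lengths Optional frames-per-run annotation for concatenated
#'   multi-run files (e.g. `rep(100, 4)` for the deposited sets).
#' @param source Label stored on the resulting series; defaults to the path.
#' @return A [frame_series()].
#' @export
read_dcd <- function(path, topology, frame_interval_ns = 10,
                     run_lengths = NULL, source = path) {
  stopifnot(is_topology(topology))
  if (!file.exists(path)) abort(sprintf("cannot read DCD file '%s'", path))
  mat <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) {
      est <- floor(file.size(path) / (3 * (4 + 4 * topology$n_atoms + 4)))
      abort(sprintf(
        "truncated or unreadable DCD '%s' (~%d complete frame(s) by size): %s",
        path, est, conditionMessage(e)))
    }
  )
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  natom_file <- ncol(mat) / 3
  if (natom_file != topology$n_atoms) {
    abort(sprintf("DCD has %d atoms but topology has %d",
                  natom_file, topology$n_atoms))
  }
  hdr <- dcd_header_info(path)
  if (!anyNA(hdr)) {
    block <- 3 * (4 * natom_file + 8)
    n_complete <- floor((file.size(path) - hdr[["data_start"]]) / block)
    if (hdr[["nset"]] > 0 && n_complete < hdr[["nset"]]) {
      abort(sprintf(
        "truncated DCD '%s': header declares %d frame(s), %d complete",
        path, hdr[["nset"]], n_complete))
    }
  }
  coords <- array(NA_real_, dim = c(nrow(mat), topology$n_atoms, 3L))
  for (i in seq_len(nrow(mat))) {
    coords[i, , ] <- matrix(mat[i, ], ncol = 3, byrow = TRUE)
  }
  frame_series(coords, frame_interval_ns = frame_interval_ns,
               source = source, run_lengths = run_lengths)
}

# Declared frame count and offset of the first coordinate record from a
# DCD header (endianness auto-detected); NAs when the header is unreadable.
dcd_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  for (end in c("little", "big")) {
    seek(con, 0)
    marker <- readBin(con, "integer", 1, size = 4, endian = end)
    if (length(marker) != 1 || is.na(marker) || marker != 84) next
    readChar(con, 4)
    nset <- readBin(con, "integer", 1, size = 4, endian = end)
    # skip remainder of header record, then the title and natom records
    seek(con, 4 + 4 + 84)
    for (rec in 1:2) {
      len <- readBin(con, "integer", 1, size = 4, endian = end)
      if (length(len) != 1 || is.na(len) || len < 0) {
        return(c(nset = NA_integer_, data_start = NA_integer_))
      }
      seek(con, len + 4, origin = "current")
    }
    return(c(nset = nset, data_start = seek(con, NA)))
  }
  c(nset = NA_integer_, data_start = NA_integer_)
}

#' Write a DCD trajectory
#'
#' Writes frames in the CHARMM/NAMD 32-bit little-endian DCD dialect
#' (readable by `bio3d::read.dcd` and standard visualization tools).
#'
#' @param frames A [frame_series()] or `T x N x 3` array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(frames, path) {
  coords <- if (is_frame_series(frames)) frames$coords else frames
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), 3))
  if (length(dim(coords)) != 3 || dim(coords)[1] == 0) {
    abort("no frames to write")
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(sprintf("cannot open '%s'", path)))
  on.exit(close(con))
  rec <- function(payload_writer) {
    tmp <- rawConnection(raw(0), "wb")
    payload_writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- as.integer(nf)  # NSET
    icntrl[2] <- 1L              # ISTART
    icntrl[3] <- 1L              # NSAVC
    icntrl[20] <- 24L            # CHARMM version tag
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(sprintf("%-80s", "written by fuzzytraj"), c2, nchars = 80,
              eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(na), c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      rec(function(c2) writeBin(as.numeric(coords[f, , ax]), c2,
                                size = 4, endian = "little"))
    }
  }
  invisible(path)
}
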