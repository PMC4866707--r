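# Structure/trajectory I/O: PDB and DCD round trips, numbering maps,
# parameter assignment.

test_that("multi-model PDB files round-trip within format precision", {
  helix <- ideal_helix(8)
  set.seed(1)
  models <- list(helix$coords,
                 helix$coords + matrix(rnorm(length(helix$coords), sd = 2),
                                       ncol = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(helix$topology, models, path)
  back <- read_pdb_models(path)
  expect_length(back$models, 2)
  expect_equal(back$topology$n_atoms, helix$topology$n_atoms)
  expect_equal(back$topology$atoms$name, helix$topology$atoms$name)
  expect_equal(back$topology$atoms$author_resno,
               helix$topology$atoms$author_resno)
  for (i in 1:2) {
    expect_lt(max(abs(back$models[[i]] - models[[i]])), 1e-3)
  }
  # single model written and read as one coordinate set
  write_pdb(helix$topology, helix$coords, path)
  expect_length(read_pdb_models(path)$models, 1)
  # in-memory text input is accepted
  txt <- paste(readLines(path), collapse = "\n")
  expect_length(read_pdb_models(txt)$models, 1)
})

test_that("malformed PDB input is rejected with clear errors", {
  helix <- ideal_helix(5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(helix$topology, list(helix$coords, helix$coords + 1), path)
  lines <- readLines(path)
  # drop one ATOM line from the second model -> atom-count mismatch
  atom_lines <- grep("^ATOM", lines)
  broken <- lines[-atom_lines[length(atom_lines)]]
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(broken, bad)
  expect_error(read_pdb_models(bad), "atom count")
  expect_error(read_pdb_models("/nonexistent/file.pdb"), "cannot read")
  # coordinates beyond fixed-column capacity
  expect_error(write_pdb(helix$topology, helix$coords + 1e5, path),
               "overflow")
})

test_that("DCD files round-trip and enforce the topology contract", {
  helix <- ideal_helix(6)
  set.seed(2)
  coords <- array(rnorm(4 * helix$topology$n_atoms * 3, sd = 10),
                  dim = c(4, helix$topology$n_atoms, 3))
  fr <- frame_series(coords, frame_interval_ns = 10)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(fr, path)
  back <- read_dcd(path, helix$topology, frame_interval_ns = 10,
                   run_lengths = c(2, 2))
  expect_equal(back$n_frames, 4)
  expect_equal(back$frame_interval_ns, 10)
  expect_equal(back$run_lengths, c(2L, 2L))
  # 32-bit float storage precision
  expect_lt(max(abs(back$coords - coords)), 1e-4)
  # atom-count mismatch against a different topology
  expect_error(read_dcd(path, ideal_helix(10)$topology), "atoms")
  # empty frame list refuses to write
  expect_error(write_dcd(array(0, dim = c(0, 5, 3)), path), "no frames")
  # truncated file reports an I/O problem
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  trunc <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw[1:(sz - 50)], trunc)
  expect_error(suppressWarnings(read_dcd(trunc, helix$topology)),
               "truncated")
})

test_that("numbering maps express the merged two-chain convention and are bijective", {
  # two-chain layout in the style of deposited complex sets: an 84-residue
  # coactivator chain followed by a 35-residue AD chain whose author
  # numbering starts at 101, so author W120 sits at internal index 104
  co <- strrep("A", 84)
  ad <- paste0(strrep("S", 19), "W", strrep("G", 15))  # W at chain pos 20
  atoms <- dplyr::bind_rows(
    build_peptide(co, chain_id = "G")$topology$atoms,
    dplyr::mutate(build_peptide(ad, chain_id = "P")$topology$atoms,
                  residue_index = .data$residue_index + 84L))
  top <- topology(atoms)
  nm <- build_numbering_map(top, list(
    G = list(segment = "GAL11", author_start = 1),
    P = list(segment = "GCN4", author_start = 101)))
  # merged residue 104 of the 1-based deposited convention is internal
  # index 103 in the package's 0-based indexing
  expect_equal(resolve_label(nm, "GCN4-W120"), 103L)
  expect_equal(label_of(nm, 103L), "GCN4-W120")
  # bijectivity: label -> index -> label is the identity everywhere
  expect_equal(label_of(nm, resolve_label(nm, nm$label)), nm$label)
  # identity offset: author number equals the topology's own numbering
  nm0 <- build_numbering_map(top)
  expect_equal(nm0$author_number,
               top$residues$author_resno)
  # overlapping author ranges are a configuration error
  expect_error(build_numbering_map(top, list(
    G = list(segment = "X", author_start = 1),
    P = list(segment = "X", author_start = 50))), "overlap")
  expect_error(resolve_label(nm, "GCN4-W999"), "unresolvable")
})

# topology instantiating every template atom of the given residues
topology_from_templates <- function(residue_names, params) {
  rows <- lapply(seq_along(residue_names), function(i) {
    tpl <- params[params$residue_name == residue_names[i], ]
    tibble::tibble(name = tpl$atom_name, element = tpl$element,
                   residue_index = i - 1L, residue_name = residue_names[i],
                   chain_id = "P", author_resno = i)
  })
  topology(dplyr::bind_rows(rows))
}

test_that("parameter assignment covers templates and flags unknowns", {
  params <- load_ff_params()
  # built peptides (which carry no amide hydrogens) parameterize fully
  ala <- build_peptide("AAA")
  ptop <- assign_params(ala$topology, params)
  expect_true(all(is.finite(ptop$atoms$charge)))
  expect_true(all(ptop$atoms$epsilon >= 0))
  expect_true(all(ptop$atoms$sigma > 0))
  # alanine template: all heavy atoms plus the polar H are covered
  ala_tpl <- params[params$residue_name == "ALA", ]
  expect_setequal(ala_tpl$atom_name, c("N", "H", "CA", "C", "O", "CB"))
  # neutral capped peptide instantiated from full templates sums to zero
  capped <- assign_params(
    topology_from_templates(c("ACE", "ALA", "SER", "GLN", "NME"), params),
    params)
  expect_lt(abs(net_charge(capped)), 1e-6)
  # unknown residue named in the error
  bad <- topology(tibble::tibble(
    name = "CA", element = "C", residue_index = 0L,
    residue_name = "XXX", chain_id = "A", author_resno = 1L))
  expect_error(assign_params(bad, params), "XXX")
})

test_that("charged residues carry their formal charge in the template set", {
  params <- load_ff_params()
  for (case in list(c("ASP", -1), c("GLU", -1), c("LYS", 1), c("ARG", 1))) {
    ptop <- assign_params(
      topology_from_templates(c("ALA", case[1], "ALA"), params), params)
    expect_equal(net_charge(ptop), as.numeric(case[2]), tolerance = 1e-6)
  }
})
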