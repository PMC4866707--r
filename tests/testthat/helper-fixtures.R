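# Fixtures built in code at test time.

ideal_helix <- function(n = 15, sequence = strrep("A", n)) {
  build_peptide(sequence, phi = -57, psi = -47)
}

extended_chain <- function(n = 10, sequence = strrep("A", n)) {
  build_peptide(sequence, phi = -180, psi = 180)
}

# minimal hand-made topology with arbitrary point atoms (one residue each)
point_topology <- function(n, chain_id = "X") {
  topology(tibble::tibble(
    name = "CA", element = "C",
    residue_index = seq_len(n) - 1L,
    residue_name = "ALA", chain_id = chain_id,
    author_resno = seq_len(n)))
}

# frame series from a list of N x 3 matrices
frames_from <- function(coord_list, interval = 1, run_lengths = NULL) {
  arr <- array(NA_real_, dim = c(length(coord_list),
                                 nrow(coord_list[[1]]), 3))
  for (i in seq_along(coord_list)) arr[i, , ] <- coord_list[[i]]
  frame_series(arr, frame_interval_ns = interval, run_lengths = run_lengths)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

table2_sequences <- function() {
  load_activity_table()
}
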