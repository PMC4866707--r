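# Backbone construction from internal coordinates. Standard bond lengths and
# angles (Engh-Huber averages); atoms emitted per residue: N, CA, C, O and a
# CB pseudo-side-chain for non-glycine residues. Used to build reference
# helices/extended chains for the secondary-structure tests and by the
# synthetic-trajectory generator.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.4
DIHEDRAL_CB <- -122.6  # improper C-N-CA-CB for L-amino acids
BOND_CB_CG <- 1.520
ANGLE_CA_CB_CG <- 114.0

# bulky side chains get a second pseudo-atom so their reach and contact
# area stand apart from small residues
BULKY_AA <- c("TRP", "PHE", "TYR", "LEU", "MET", "ILE")

#' Build peptide coordinates from backbone dihedrals
#'
#' Constructs an all-residue peptide with atoms N, CA, C, O (plus CB for
#' non-glycine residues) from phi/psi backbone dihedrals using sequential
#' internal-coordinate (NeRF) placement with ideal bond lengths and angles.
#' Ideal alpha-helical geometry corresponds to `phi = -57`, `psi = -47`;
#' a fully extended chain to `phi = -180`, `psi = 180`.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled to the
#'   sequence length. `phi[1]` is unused (no preceding carbonyl) and `psi` of
#'   the final residue only orients its carbonyl oxygen.
#' @param omega Peptide-bond dihedral, degrees (default trans, 180).
#' @param chain_id Chain identifier for the resulting topology.
#' @param author_start Author residue number of the first residue.
#' @return List with elements `topology` (a [topology()]) and `coords`
#'   (`N x 3` matrix, Angstrom).
#' @examples
#' helix <- build_peptide(strrep("A", 15), phi = -57, psi = -47)
#' helix$topology
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                          chain_id = "P", author_start = 1L) {
  letters1 <- check_sequence(sequence)
  n <- length(letters1)
  if (n < 2) abort("sequence must have at least 2 residues")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)

  bb_n <- matrix(NA_real_, n, 3)
  bb_ca <- matrix(NA_real_, n, 3)
  bb_c <- matrix(NA_real_, n, 3)

  # seed residue 1 in the xy-plane
  bb_n[1, ] <- c(0, 0, 0)
  bb_ca[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  bb_c[1, ] <- bb_ca[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)

  for (i in seq_len(n - 1)) {
    bb_n[i + 1, ] <- place_atom(bb_n[i, ], bb_ca[i, ], bb_c[i, ],
                                BOND_C_N, ANGLE_CA_C_N, psi[i])
    bb_ca[i + 1, ] <- place_atom(bb_ca[i, ], bb_c[i, ], bb_n[i + 1, ],
                                 BOND_N_CA, ANGLE_C_N_CA, omega[i])
    bb_c[i + 1, ] <- place_atom(bb_c[i, ], bb_n[i + 1, ], bb_ca[i + 1, ],
                                BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
  }

  rows <- list()
  coords <- list()
  for (i in seq_len(n)) {
    res3 <- aa_three[[letters1[i]]]
    add <- function(nm, el, xyz) {
      rows[[length(rows) + 1]] <<- list(name = nm, element = el,
                                        residue_index = i - 1L,
                                        residue_name = res3,
                                        chain_id = chain_id,
                                        author_resno = author_start + i - 1L)
      coords[[length(coords) + 1]] <<- xyz
    }
    add("N", "N", bb_n[i, ])
    add("CA", "C", bb_ca[i, ])
    add("C", "C", bb_c[i, ])
    # carbonyl oxygen opposite the next amide nitrogen
    o <- place_atom(bb_n[i, ], bb_ca[i, ], bb_c[i, ],
                    BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
    add("O", "O", o)
    if (res3 != "GLY") {
      cb <- place_atom(bb_c[i, ], bb_n[i, ], bb_ca[i, ],
                       BOND_CA_CB, ANGLE_N_CA_CB, DIHEDRAL_CB)
      add("CB", "C", cb)
      if (res3 %in% BULKY_AA) {
        cg <- place_atom(bb_n[i, ], bb_ca[i, ], cb,
                         BOND_CB_CG, ANGLE_CA_CB_CG, 180)
        add("CG", "C", cg)
      }
    }
  }
  atoms <- bind_rows(lapply(rows, as_tibble))
  list(topology = topology(atoms), coords = do.call(rbind, coords))
}

# Reconstruct amide hydrogen positions for a frame: H sits 1.01 A from N along
# the direction opposed to the bisector of the N-C(prev) and N-CA bonds.
# Residue 1 (no preceding carbonyl) and proline get NA rows.
amide_hydrogens <- function(coords, topology) {
  res <- topology$residues
  n <- nrow(res)
  h <- matrix(NA_real_, n, 3)
  idx_of <- function(ri, nm) {
    i <- select_atoms(topology, residue_index = ri, atom_name = nm)
    if (length(i) == 1) i else NA_integer_
  }
  for (k in seq_len(n)) {
    ri <- res$residue_index[k]
    if (res$residue_name[k] == "PRO") next
    prev <- which(res$residue_index == ri - 1L &
                    res$chain_id == res$chain_id[k])
    if (length(prev) != 1) next
    i_n <- idx_of(ri, "N"); i_ca <- idx_of(ri, "CA")
    i_cprev <- idx_of(res$residue_index[prev], "C")
    if (anyNA(c(i_n, i_ca, i_cprev))) next
    nn <- coords[i_n, ]
    u <- vunit(vunit(nn - coords[i_cprev, ]) + vunit(nn - coords[i_ca, ]))
    h[k, ] <- nn + 1.01 * u
  }
  h
}
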