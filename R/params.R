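# Per-atom nonbonded parameters (partial charges, Lennard-Jones). A minimal
# coarse template library (backbone N/H/CA/C/O plus a CB pseudo-side-chain,
# acetyl/N-methylamide caps) ships with the package; it is a synthetic table
# built for the intermolecular rank-order analyses here, not a transferable
# force field, and users may substitute their own TSV.

#' Load a nonbonded parameter table
#'
#' @param path Path to a TSV with columns `residue_name`, `atom_name`,
#'   `element`, `charge` (e), `epsilon` (kcal/mol) and `sigma` (Angstrom).
#'   `NULL` loads the bundled minimal template library.
#' @return A tibble of class `ff_params`.
#' @export
load_ff_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ff_params_synthetic.tsv",
                        package = "fuzzytraj", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("residue_name", "atom_name", "charge", "epsilon", "sigma")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tab$epsilon < 0)) abort("LJ well depth epsilon must be >= 0")
  if (any(tab$sigma <= 0)) abort("LJ diameter sigma must be > 0")
  class(tab) <- c("ff_params", class(tab))
  tab
}

#' Assign nonbonded parameters to every atom of a topology
#'
#' Resolves each atom through the `(residue_name, atom_name)` template table
#' and attaches `charge`, `epsilon` and `sigma` columns to the topology's
#' atom table. Fails listing every unresolvable atom.
#'
#' @param topology A [topology()].
#' @param params A [load_ff_params()] table (default: bundled library).
#' @return The topology with parameter columns filled in.
#' @export
assign_params <- function(topology, params = load_ff_params()) {
  stopifnot(is_topology(topology))
  at <- topology$atoms
  key <- paste(at$residue_name, at$name)
  pkey <- paste(params$residue_name, params$atom_name)
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    offenders <- unique(key[is.na(hit)])
    abort(paste0("parameterization error: no template for atom(s): ",
                 paste(offenders, collapse = ", ")))
  }
  at$charge <- params$charge[hit]
  at$epsilon <- params$epsilon[hit]
  at$sigma <- params$sigma[hit]
  out <- topology
  out$atoms <- at
  out
}

#' Total charge of a topology
#'
#' Sum of assigned partial charges (e); requires [assign_params()] first.
#'
#' @param topology A parameterized [topology()].
#' @return Numeric scalar, elementary charge units.
#' @export
net_charge <- function(topology) {
  stopifnot(is_topology(topology))
  if (is.null(topology$atoms$charge)) {
    abort("topology has no charges; run assign_params() first")
  }
  sum(topology$atoms$charge)
}
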