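# Bidirectional residue-numbering maps. Deposited trajectory sets merge two
# chains into one continuous numbering while the literature labels residues by
# segment name plus author number (e.g. "GCN4-W120"); the map keeps both views
# and is a checked bijection.

#' Build a residue numbering map
#'
#' Creates a bijective map between internal 0-based residue indices and
#' author-style labels of the form `"<segment>-<aa1><number>"` (for example
#' `"GCN4-W120"`). Each chain is assigned a segment name and the author
#' number of its first residue; numbers increase by one along the chain.
#'
#' @param topology A [topology()].
#' @param offset_spec Named list: `chain_id -> list(segment, author_start)`.
#'   If `NULL`, each chain uses its chain id as the segment name and the
#'   `author_resno` values already present in the topology.
#' @return A tibble of class `numbering_map` with columns `residue_index`,
#'   `chain_id`, `segment`, `author_number` and `label`.
#' @examples
#' helix <- build_peptide("ASDFW", phi = -57, psi = -47)
#' nm <- build_numbering_map(helix$topology,
#'                           list(P = list(segment = "GCN4", author_start = 116)))
#' resolve_label(nm, "GCN4-W120")
#' @export
build_numbering_map <- function(topology, offset_spec = NULL) {
  stopifnot(is_topology(topology))
  res <- topology$residues
  if (is.null(offset_spec)) {
    seg <- res$chain_id
    num <- res$author_resno
  } else {
    chains <- unique(res$chain_id)
    missing <- setdiff(chains, names(offset_spec))
    if (length(missing) > 0) {
      abort(paste0("offset_spec lacks chain(s): ",
                   paste(missing, collapse = ", ")))
    }
    seg <- character(nrow(res))
    num <- integer(nrow(res))
    for (ch in chains) {
      spec <- offset_spec[[ch]]
      if (is.null(spec$segment) || is.null(spec$author_start)) {
        abort(sprintf("offset_spec for chain '%s' needs segment and author_start",
                      ch))
      }
      rows <- which(res$chain_id == ch)
      seg[rows] <- spec$segment
      num[rows] <- spec$author_start + seq_along(rows) - 1L
    }
  }
  aa1 <- unname(aa_one[res$residue_name])
  aa1[is.na(aa1)] <- "X"
  map <- tibble(residue_index = res$residue_index, chain_id = res$chain_id,
                segment = seg, author_number = as.integer(num),
                label = sprintf("%s-%s%d", seg, aa1, num))
  dup_rng <- duplicated(map[, c("segment", "author_number")])
  if (any(dup_rng)) {
    abort(paste0("configuration error: overlapping author ranges at ",
                 paste(unique(map$label[dup_rng]), collapse = ", ")))
  }
  if (anyDuplicated(map$label) || anyDuplicated(map$residue_index)) {
    abort("numbering map is not a bijection")
  }
  class(map) <- c("numbering_map", class(map))
  map
}

#' Resolve an author-style residue label to its internal index
#'
#' Accepts either the full label (`"GCN4-W120"`) or segment plus number
#' (`"GCN4-120"`, amino-acid letter omitted).
#'
#' @param map A [build_numbering_map()] result.
#' @param label Character vector of labels.
#' @return Integer vector of 0-based residue indices.
#' @export
resolve_label <- function(map, label) {
  stopifnot(inherits(map, "numbering_map"))
  hit <- match(label, map$label)
  # fall back to "<segment>-<number>" form
  bare <- sprintf("%s-%d", map$segment, map$author_number)
  hit2 <- match(label, bare)
  hit[is.na(hit)] <- hit2[is.na(hit)]
  if (anyNA(hit)) {
    abort(paste0("unresolvable residue label(s): ",
                 paste(label[is.na(hit)], collapse = ", ")))
  }
  map$residue_index[hit]
}

#' Label residues by internal index
#'
#' Inverse of [resolve_label()].
#'
#' @param map A [build_numbering_map()] result.
#' @param residue_index Integer vector of 0-based residue indices.
#' @return Character vector of labels.
#' @export
label_of <- function(map, residue_index) {
  stopifnot(inherits(map, "numbering_map"))
  hit <- match(residue_index, map$residue_index)
  if (anyNA(hit)) {
    abort(paste0("residue index not in map: ",
                 paste(residue_index[is.na(hit)], collapse = ", ")))
  }
  map$label[hit]
}
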