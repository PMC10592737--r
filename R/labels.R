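#' @keywords internal
"_PACKAGE"

# The multiplication sign used by Ballesteros-Weinstein numbers ("3×50").
BW_TIMES <- "×"

#' Normalize a generic residue identifier
#'
#' Ballesteros-Weinstein numbers are written with a multiplication sign
#' (e.g. `3×50`); an ASCII `x` between digits is accepted on input and
#' normalized. Common G-protein numbering ids (`G.H5.24`) pass through
#' unchanged. Whitespace is trimmed.
#'
#' @param x character vector of generic ids.
#' @return normalized character vector.
#' @export
normalize_generic_id <- function(x) {
  x <- trimws(x)
  if (any(!nzchar(x))) stop("empty generic residue id")
  gsub("(?<=[0-9])x(?=[0-9])", BW_TIMES, x, perl = TRUE)
}

#' Construct a residue label
#'
#' A residue label ties a residue's author (PDB) numbering to its generic
#' number in the numbering dialect of its chain role: Ballesteros-Weinstein
#' for the receptor, Common G-protein Numbering for the G protein.
#'
#' @param chain_role `"receptor"` or `"gprotein"`.
#' @param generic_id generic residue number (e.g. `"34x51"`, `"G.H5.24"`).
#' @param pdb_resid integer author residue number (optional, `NA` if unknown).
#' @param pdb_chain author chain id (optional).
#' @return a `residue_label` list.
#' @export
residue_label <- function(chain_role, generic_id, pdb_resid = NA_integer_,
                          pdb_chain = NA_character_) {
  chain_role <- match.arg(chain_role, c("receptor", "gprotein"))
  structure(
    list(chain_role = chain_role,
         generic_id = normalize_generic_id(generic_id),
         pdb_resid = as.integer(pdb_resid),
         pdb_chain = as.character(pdb_chain)),
    class = "residue_label")
}

#' Canonical contact-node id
#'
#' A contact node is one receptor-residue x G-protein-residue interaction,
#' named `<receptor_generic>_<gprotein_generic>` (receptor first), e.g.
#' `"7×55_G.H5.24"`. Identical generic pairs from different complexes
#' yield identical ids, which is what makes networks comparable across
#' complexes.
#'
#' @param receptor_id,gprotein_id generic residue numbers.
#' @return character canonical id.
#' @export
contact_node_id <- function(receptor_id, gprotein_id) {
  paste0(normalize_generic_id(receptor_id), "_", normalize_generic_id(gprotein_id))
}

#' Split canonical contact-node ids into their residue parts
#'
#' Inverse of [contact_node_id()] for ids containing exactly one underscore
#' separating the receptor and G-protein generic numbers.
#'
#' @param ids character vector of canonical ids.
#' @return data.frame with columns `node`, `receptor_id`, `gprotein_id`.
#' @export
parse_contact_node_id <- function(ids) {
  ids <- normalize_generic_id(ids)
  parts <- regmatches(ids, regexpr("_", ids), invert = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed contact node id(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(
    node = ids,
    receptor_id = vapply(parts, `[[`, "", 1L),
    gprotein_id = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE)
}
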