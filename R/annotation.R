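#' Extract maximal helix runs from an annotation string
#'
#' @param annotation per-residue annotation string; residues equal to
#'   \code{helix_code} are helix, everything else is not.
#' @param chain_id optional chain id carried into the result.
#' @param helix_code character treated as helix (default \code{"H"}; 3-10
#'   and pi helix codes are deliberately not helix for this analysis).
#' @return data.frame with columns \code{chain_id}, \code{start}, \code{end}
#'   (1-based, inclusive) and \code{length}, ordered by start; zero rows if
#'   the chain has no helix.
#' @examples
#' extract_helices("cHHHHHc")
#' @export
extract_helices <- function(annotation, chain_id = NA_character_,
                            helix_code = HELIX_CODE) {
  chars <- strsplit(annotation, "")[[1]]
  if (length(chars) == 0)
    return(data.frame(chain_id = character(), start = integer(),
                      end = integer(), length = integer()))
  r <- rle(chars == helix_code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(chain_id = rep(chain_id, sum(keep)), start = starts[keep],
             end = ends[keep], length = r$lengths[keep], row.names = NULL)
}

#' Consensus helices across secondary-structure assigners
#'
#' A helix survives a consensus mode when it starts \emph{and} ends at the
#' same residue in every assigner named by the mode.  The strictest mode
#' requires all of PDB, DSSP and Stride to agree; pairwise modes relax this
#' to two assigners; a single-assigner mode takes that assigner's helices
#' as-is.
#'
#' @param record chain record: a list with \code{annotations}, a named
#'   character vector/list of annotation strings keyed by assigner role.
#' @param mode one of \code{"pdb-dssp-stride"}, \code{"pdb-dssp"},
#'   \code{"pdb-stride"}, \code{"dssp-stride"}, \code{"pdb"}, \code{"dssp"},
#'   \code{"stride"}.
#' @param helix_code see [extract_helices()].
#' @return data.frame as from [extract_helices()], plus a
#'   \code{consensus_mode} column.
#' @export
consensus_helices <- function(record, mode = "pdb-dssp-stride",
                              helix_code = HELIX_CODE) {
  roles <- consensus_roles(mode)
  have <- names(record$annotations)
  missing <- setdiff(roles, have)
  if (length(missing) > 0)
    stop(sprintf("record '%s' lacks annotations for assigner(s): %s",
                 record$chain_id %||% "?", paste(missing, collapse = ", ")))
  sets <- lapply(roles, function(r)
    extract_helices(record$annotations[[r]], record$chain_id %||% NA_character_,
                    helix_code))
  keys <- lapply(sets, function(s) paste(s$start, s$end))
  common <- Reduce(intersect, keys)
  out <- sets[[1]][keys[[1]] %in% common, , drop = FALSE]
  if (nrow(out) > 0) out <- out[order(out$start), , drop = FALSE]
  out$consensus_mode <- rep(mode, nrow(out))
  rownames(out) <- NULL
  out
}

consensus_roles <- function(mode) {
  roles <- switch(tolower(mode),
    "pdb-dssp-stride" = c("PDB", "DSSP", "Stride"),
    "pdb-dssp"        = c("PDB", "DSSP"),
    "pdb-stride"      = c("PDB", "Stride"),
    "dssp-stride"     = c("DSSP", "Stride"),
    "pdb"             = "PDB",
    "dssp"            = "DSSP",
    "stride"          = "Stride",
    stop(sprintf("unknown consensus mode '%s'", mode)))
  roles
}

#' Classify a chain's helix content as exclusive or nonexclusive
#'
#' A chain carrying exactly one helix is "exclusive"; more than one,
#' "nonexclusive"; a chain with no (consensus) helix is flagged "excluded"
#' rather than treated as an error, and is dropped from datamarts.
#'
#' @param helices data.frame of helices for one chain
#'   (e.g. from [consensus_helices()]).
#' @return one of \code{"exclusive"}, \code{"nonexclusive"},
#'   \code{"excluded"}.
#' @export
classify_exclusivity <- function(helices) {
  n <- nrow(helices)
  if (n == 0) "excluded" else if (n == 1) "exclusive" else "nonexclusive"
}
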