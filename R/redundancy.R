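#' Global-alignment sequence identity
#'
#' Identity between two sequences under a global (Needleman-Wunsch)
#' alignment with match = 1, mismatch = 0 and a simple per-gap penalty of 1,
#' defined as the number of matched columns divided by the total alignment
#' length (gap columns included).  This is the deterministic stand-in for the
#' similarity measure of redundancy-removal tools such as CD-HIT.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return identity in [0, 1].
#' @export
seq_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  letters_used <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sub <- matrix(0, length(letters_used), length(letters_used),
                dimnames = list(letters_used, letters_used))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1)
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / width
}

#' Greedy redundancy clustering of sequences
#'
#' Removes sequence redundancy at a given identity level (the analysis uses
#' 0.95, 0.70 and 0.50): sequences are visited longest-first (ties keep input
#' order); each sequence joins the earliest-created representative with
#' global-alignment identity at or above the threshold, otherwise it becomes
#' a new representative.  Deterministic for a given input order.
#'
#' @param sequences named character vector of sequences.
#' @param level identity threshold in (0, 1].
#' @return list with \code{representatives} (named character vector, a subset
#'   of \code{sequences}) and \code{members} (data.frame: \code{id},
#'   \code{representative}, \code{identity}).
#' @export
cluster_redundancy <- function(sequences, level) {
  stopifnot(level > 0, level <= 1)
  if (length(sequences) == 0)
    return(list(representatives = character(),
                members = data.frame(id = character(),
                                     representative = character(),
                                     identity = numeric())))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences), seq_along(sequences))
  reps <- character()   # representative ids, in creation order
  members <- vector("list", length(sequences))
  for (i in ord) {
    id <- names(sequences)[i]
    assigned <- FALSE
    for (r in reps) {
      pid <- seq_identity(sequences[[i]], sequences[[r]])
      if (pid >= level) {
        members[[i]] <- data.frame(id = id, representative = r,
                                   identity = pid)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      members[[i]] <- data.frame(id = id, representative = id, identity = 1)
    }
  }
  list(representatives = sequences[reps],
       members = do.call(rbind, members[ord]))
}
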