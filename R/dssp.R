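#' Parse a DSSP file into per-chain annotation strings
#'
#' Reads the classic fixed-column DSSP layout: everything up to the
#' \code{"  #  RESIDUE"} header is ignored, then each record contributes one
#' residue with the amino acid in column 14, the chain identifier in column
#' 12 and the secondary-structure code in column 17.  Only code \code{H}
#' (alpha helix) maps to helix; all other codes, including \code{G} (3-10)
#' and \code{I} (pi), map to non-helix.  \code{!} break records inside a
#' chain are preserved as non-helix placeholder residues (\code{X}); \code{!*}
#' records terminate a chain.
#'
#' @param path path to a DSSP file.
#' @param helix_codes DSSP codes mapped to helix (default \code{"H"}).
#' @return named list, one element per chain: a list with \code{chain_id},
#'   \code{sequence} and \code{annotation} (same length as sequence, over
#'   \code{H}/\code{c}).
#' @export
parse_dssp <- function(path, helix_codes = "H") {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0)
    stop(sprintf("%s: no '  #  RESIDUE' header line found", path))
  chains <- list()
  cur_id <- NULL
  cur_aa <- character()
  cur_ss <- character()
  flush <- function() {
    if (!is.null(cur_id))
      chains[[cur_id]] <<- list(chain_id = cur_id,
                                sequence = paste(cur_aa, collapse = ""),
                                annotation = paste(cur_ss, collapse = ""))
    cur_id <<- NULL; cur_aa <<- character(); cur_ss <<- character()
  }
  for (ln in seq(hdr[1] + 1L, length(lines))) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (nchar(line) < 17)
      stop(sprintf("%s:%d: DSSP record shorter than 17 columns", path, ln))
    aa <- substr(line, 14, 14)
    if (aa == "!") {
      star <- nchar(line) >= 15 && substr(line, 15, 15) == "*"
      if (star) flush() else if (!is.null(cur_id)) {
        cur_aa <- c(cur_aa, "X"); cur_ss <- c(cur_ss, COIL_CODE)
      }
      next
    }
    ch <- substr(line, 12, 12)
    if (!grepl("^\\s*\\d+\\s*$", substr(line, 1, 5)))
      stop(sprintf("%s:%d: malformed DSSP residue number field", path, ln))
    if (is.null(cur_id)) cur_id <- ch
    else if (ch != cur_id) { flush(); cur_id <- ch }
    ss <- substr(line, 17, 17)
    cur_aa <- c(cur_aa, aa)
    cur_ss <- c(cur_ss, if (ss %in% helix_codes) HELIX_CODE else COIL_CODE)
  }
  flush()
  chains
}

#' Write chains to a minimal DSSP-format file
#'
#' Emits just enough of the classic DSSP layout (header banner, column
#' header, fixed-column residue records, \code{!*} chain terminators) for
#' [parse_dssp()] and other DSSP readers that rely on the standard columns.
#' Used to build synthetic DSSP fixtures.
#'
#' @param chains list of lists with \code{chain_id} (single letter),
#'   \code{sequence} and \code{annotation} (helix = \code{H}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dssp <- function(chains, path) {
  out <- c(
    "==== SECONDARY STRUCTURE DEFINITION BY THE PROGRAM DSSP (SYNTHETIC) ====",
    "REFERENCE  SYNTHETIC FIXTURE",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI"))
  num <- 0L
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    aa <- strsplit(ch$sequence, "")[[1]]
    ss <- strsplit(ch$annotation, "")[[1]]
    stopifnot(length(aa) == length(ss))
    for (r in seq_along(aa)) {
      num <- num + 1L
      out <- c(out, sprintf("%5d%5d %s %s  %s", num, r,
                            substr(ch$chain_id, 1, 1), aa[r],
                            if (ss[r] == HELIX_CODE) "H" else " "))
    }
    if (i < length(chains)) {
      num <- num + 1L
      out <- c(out, sprintf("%5d        !*             ", num))
    }
  }
  writeLines(out, path)
  invisible(path)
}
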