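# Canonical table dialect: tab-separated, UTF-8, "." decimal, header row.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-residue descriptor table
#'
#' The canonical descriptor table is a TSV with a header row containing
#' \code{chain_id}, \code{residue_index} and one numeric column per
#' descriptor.  Row order is irrelevant; rows are sorted by chain and
#' residue.  Missing cells stay missing (NA) — they are never silently
#' zeroed.  Duplicate (chain, residue) pairs and non-numeric descriptor
#' cells are errors reported with their location.
#'
#' @param path TSV path.
#' @return data.frame: \code{chain_id}, \code{residue_index}, descriptor
#'   columns.
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("chain_id", "residue_index")
  if (!all(need %in% colnames(tab)))
    stop(sprintf("%s: header must contain %s", path,
                 paste(need, collapse = ", ")))
  key <- paste(tab$chain_id, tab$residue_index)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (chain, residue) pair: %s", path,
                 key[duplicated(key)][1]))
  for (d in setdiff(colnames(tab), need)) {
    if (!is.numeric(tab[[d]])) {
      bad <- which(!is.na(tab[[d]]) &
                     is.na(suppressWarnings(as.numeric(tab[[d]]))))[1]
      stop(sprintf("%s: non-numeric value in column '%s', row %d ('%s')",
                   path, d, bad, tab[[d]][bad]))
    }
  }
  tab[order(tab$chain_id, tab$residue_index), , drop = FALSE]
}

#' Write a per-residue descriptor table
#' @param table descriptor table; @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_descriptor_table <- function(table, path) write_tsv(table, path)

#' Read chain annotations from a 3-column TSV
#'
#' Columns: \code{chain_id}, \code{assigner}, \code{annotation}.
#'
#' @param path TSV path.
#' @return named list: per chain, a named character vector of annotation
#'   strings keyed by assigner role.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chain_id", "assigner", "annotation") %in% colnames(tab)))
  lapply(split(tab, tab$chain_id), function(s) {
    out <- s$annotation
    names(out) <- s$assigner
    out
  })
}

write_annotation_tsv <- function(chains, path) {
  rows <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain_id = ch$chain_id,
               assigner = names(ch$annotations),
               annotation = unlist(ch$annotations, use.names = FALSE))))
  write_tsv(rows, path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the cohort in the pipeline's canonical exchange formats:
#' \code{sequences.fasta}, \code{annotations.tsv} (chain_id, assigner,
#' annotation), \code{descriptors.tsv} and \code{config.json}.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::AAStringSet(vapply(cohort$chains, `[[`, "", "sequence"))
  names(seqs) <- vapply(cohort$chains, `[[`, "", "chain_id")
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  write_annotation_tsv(cohort$chains, file.path(dir, "annotations.tsv"))
  write_descriptor_table(cohort$descriptors, file.path(dir, "descriptors.tsv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing \code{sequences.fasta},
#'   \code{annotations.tsv}, \code{descriptors.tsv} and \code{config.json}.
#' @return a \code{helix_cohort}-shaped list (without \code{true_helices},
#'   which only the generator knows).
#' @export
read_cohort <- function(dir) {
  seqs <- Biostrings::readAAStringSet(file.path(dir, "sequences.fasta"))
  anns <- read_annotation_tsv(file.path(dir, "annotations.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  chains <- lapply(names(seqs), function(cid)
    list(chain_id = cid,
         sequence = as.character(seqs[[cid]]),
         annotations = as.list(anns[[cid]]),
         class_label = cfg$class_label %||% "all-alpha"))
  names(chains) <- names(seqs)
  structure(list(chains = chains,
                 descriptors = read_descriptor_table(
                   file.path(dir, "descriptors.tsv")),
                 true_helices = NULL, config = cfg),
            class = "helix_cohort")
}

#' Write a datamart summary TSV
#' @param datamart a [build_datamart()] result; @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_datamart_tsv <- function(datamart, path) write_tsv(datamart$counts, path)
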