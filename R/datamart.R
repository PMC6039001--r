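#' Build per-length helix datamarts
#'
#' Applies the pipeline's grouping steps in order: filter chains by protein
#' class, remove sequence redundancy at the requested identity level, form
#' consensus helices for the requested assigner mode, classify each surviving
#' chain as exclusive (exactly one helix) or nonexclusive, and tabulate
#' helices per length.  The combined counts always equal exclusive plus
#' nonexclusive counts at every length.  Chains whose consensus helix set is
#' empty are dropped from the counts but reported in \code{dropped}.
#'
#' @param chains list of chain records (each with \code{chain_id},
#'   \code{sequence}, \code{annotations}, \code{class_label}), e.g.
#'   \code{cohort$chains} from [generate_cohort()].
#' @param class_filter keep only chains with this \code{class_label}
#'   (\code{NULL} keeps all).
#' @param consensus_mode assigner consensus mode, see [consensus_helices()].
#' @param redundancy_level identity threshold for [cluster_redundancy()]
#'   (\code{NULL} skips clustering).
#' @param name datamart name used in reports.
#' @param helix_code see [extract_helices()].
#' @return object of class \code{helix_datamart}: list with \code{name},
#'   \code{counts} (data.frame: length, n_total, n_exclusive,
#'   n_nonexclusive), \code{instances} (helix table with an
#'   \code{exclusive} flag), \code{dropped} (chain ids with no consensus
#'   helix) and \code{params}.
#' @export
build_datamart <- function(chains, class_filter = NULL,
                           consensus_mode = "pdb-dssp-stride",
                           redundancy_level = NULL,
                           name = "DM", helix_code = HELIX_CODE) {
  if (!is.null(class_filter))
    chains <- Filter(function(ch) identical(ch$class_label, class_filter),
                     chains)
  if (!is.null(redundancy_level) && length(chains) > 0) {
    seqs <- vapply(chains, `[[`, "", "sequence")
    names(seqs) <- vapply(chains, `[[`, "", "chain_id")
    reps <- names(cluster_redundancy(seqs, redundancy_level)$representatives)
    chains <- Filter(function(ch) ch$chain_id %in% reps, chains)
  }
  inst <- list()
  dropped <- character()
  for (ch in chains) {
    hel <- consensus_helices(ch, consensus_mode, helix_code)
    excl <- classify_exclusivity(hel)
    if (excl == "excluded") {
      dropped <- c(dropped, ch$chain_id)
      next
    }
    hel$exclusive <- excl == "exclusive"
    inst[[length(inst) + 1L]] <- hel
  }
  instances <- if (length(inst) > 0) do.call(rbind, inst) else
    data.frame(chain_id = character(), start = integer(), end = integer(),
               length = integer(), consensus_mode = character(),
               exclusive = logical())
  structure(list(name = name,
                 counts = tabulate_helix_lengths(instances),
                 instances = instances,
                 dropped = dropped,
                 params = list(class_filter = class_filter,
                               consensus_mode = consensus_mode,
                               redundancy_level = redundancy_level)),
            class = "helix_datamart")
}

#' Tabulate helix counts per length, split by exclusivity
#'
#' @param instances helix instance table with \code{length} and
#'   \code{exclusive} columns.
#' @return data.frame with \code{length}, \code{n_total}, \code{n_exclusive},
#'   \code{n_nonexclusive}; \code{n_total = n_exclusive + n_nonexclusive}
#'   by construction.
#' @export
tabulate_helix_lengths <- function(instances) {
  lens <- sort(unique(instances$length))
  out <- data.frame(
    length = lens,
    n_total = vapply(lens, function(L) sum(instances$length == L), 0L),
    n_exclusive = vapply(lens, function(L)
      sum(instances$length == L & instances$exclusive), 0L))
  out$n_nonexclusive <- out$n_total - out$n_exclusive
  out
}

#' Totals of a per-length datamart count table
#'
#' @param counts data.frame with \code{n_total}, \code{n_exclusive},
#'   \code{n_nonexclusive} columns (as in [tabulate_helix_lengths()] or a
#'   published helix-census table).
#' @return named numeric vector with \code{total}, \code{exclusive},
#'   \code{nonexclusive}.
#' @export
datamart_totals <- function(counts) {
  c(total = sum(counts$n_total),
    exclusive = sum(counts$n_exclusive),
    nonexclusive = sum(counts$n_nonexclusive))
}

#' @export
print.helix_datamart <- function(x, ...) {
  tot <- datamart_totals(x$counts)
  cat(sprintf(
    "datamart %s: %d helices (%d exclusive, %d nonexclusive), %d lengths\n",
    x$name, tot["total"], tot["exclusive"], tot["nonexclusive"],
    nrow(x$counts)))
  invisible(x)
}
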