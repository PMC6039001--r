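#' The canonical descriptor registry
#'
#' The 69 per-residue descriptors used for helix-nanoenvironment analysis,
#' with their categories (Structural, Geometric, Contacts, Unused Contacts,
#' Physical Chemical, WNA, Others).  Weighted-neighbour-average (WNA)
#' variants — weighted by interatomic distance (\code{_WNADist}) or surface
#' accessibility (\code{_WNASurf}) — are distinct registry entries, which is
#' why the contact/potential names appear both plain and suffixed.  The
#' registry ships as a data file so analyses can subset descriptors by
#' category; the descriptors themselves are computed upstream and arrive as
#' table columns.
#'
#' @param category optional category filter.
#' @return data.frame with \code{name} and \code{category}; 69 rows when
#'   unfiltered.
#' @export
descriptor_registry <- function(category = NULL) {
  path <- system.file("extdata", "descriptor_registry.tsv",
                      package = "helixenv", mustWork = TRUE)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(reg$name))
  if (!is.null(category)) reg <- reg[reg$category %in% category, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Published per-length helix counts
#'
#' The per-length helix census of the reference compilation: for each helix
#' length, total / exclusive / nonexclusive helix counts in all-alpha chains
#' (DM1) and in (alpha+beta)+(alpha/beta) chains (DM2).  Shipped as package
#' data; used for the desk-scale accounting checks.
#'
#' @param dm \code{"DM1"} or \code{"DM2"}.
#' @return data.frame with \code{length}, \code{n_total}, \code{n_exclusive},
#'   \code{n_nonexclusive} (rows with a zero total for the chosen datamart
#'   are dropped).
#' @export
published_helix_counts <- function(dm = c("DM1", "DM2")) {
  dm <- match.arg(dm)
  path <- system.file("extdata", "helix_length_counts.tsv",
                      package = "helixenv", mustWork = TRUE)
  tab <- utils::read.delim(path)
  pre <- if (dm == "DM1") "dm1" else "dm2"
  out <- data.frame(length = tab$length,
                    n_total = tab[[paste0(pre, "_total")]],
                    n_exclusive = tab[[paste0(pre, "_exclusive")]],
                    n_nonexclusive = tab[[paste0(pre, "_nonexclusive")]])
  out[out$n_total > 0, , drop = FALSE]
}

#' Published sliding-window KS sweep accounting
#'
#' Test counts of the single-descriptor KS sweep over all helix sizes of the
#' reference compilation: number of sizes, available tests, excluded tests,
#' and tests at or below the 1e-6 and 1e-3 p-value levels, per datamart.
#'
#' @return data.frame with one row per datamart.
#' @export
published_ks_sweep_counts <- function() {
  path <- system.file("extdata", "ks_sweep_counts.tsv",
                      package = "helixenv", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Share of tests below a significance level, as a percentage
#'
#' @param n_hits number of tests at or below the level.
#' @param n_tests number of available tests.
#' @return \code{100 * n_hits / n_tests}.
#' @export
sweep_percentage <- function(n_hits, n_tests) {
  stopifnot(n_tests > 0, n_hits >= 0, n_hits <= n_tests)
  100 * n_hits / n_tests
}

#' Number of descriptor/size/flavour plot combinations
#'
#' Every analysed combination of a descriptor, a helix size and an
#' exclusivity flavour (exclusive / nonexclusive) yields one profile plot;
#' this counts them.
#'
#' @param n_descriptors number of descriptors.
#' @param sizes vector of helix sizes analysed (or a count).
#' @param n_flavours number of exclusivity flavours (default 2).
#' @return integer combination count.
#' @export
plot_combination_count <- function(n_descriptors, sizes, n_flavours = 2) {
  n_sizes <- if (length(sizes) == 1) sizes else length(unique(sizes))
  as.integer(n_descriptors * n_sizes * n_flavours)
}
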