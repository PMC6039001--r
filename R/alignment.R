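#' Position labels for an aligned ensemble
#'
#' Pre-flank positions are negative (-flank .. -1), the helix occupies
#' 1 .. L, and the post-flank runs L+1 .. L+flank (absolute labelling; the
#' relative post-flank label is position - L).
#'
#' @param L helix length; @param flank flank width.
#' @return integer vector of length \code{2 * flank + L}.
#' @export
position_labels <- function(L, flank = 32) {
  c(seq(-flank, -1), seq_len(L), seq(L + 1, L + flank))
}

#' Positionally align equal-length helices with flanking regions
#'
#' Stacks all helix instances of one length so that helix position 1 is the
#' N-terminal residue of every instance, extending the observation field by
#' \code{flank} residues on each side.  Flank cells that fall outside the
#' chain are gaps ("-" in the field's alignment pictures); flank residues
#' that belong to some other helix in the marking annotation carry a helix
#' mark ("h").  Every helix-span cell is occupied and helix-marked.
#'
#' @param instances helix instance table (\code{chain_id}, \code{start},
#'   \code{end}, \code{length}); all lengths must be equal.
#' @param descriptors per-residue descriptor table (\code{chain_id},
#'   \code{residue_index}, one numeric column per descriptor).
#' @param chains list of chain records supplying \code{annotations} and
#'   \code{sequence}.
#' @param flank flank width in residues (default 32).
#' @param mark_role assigner role whose annotation defines helix membership
#'   of flank residues (default \code{"PDB"}).
#' @return object of class \code{aligned_ensemble}: list with \code{L},
#'   \code{flank}, \code{positions}, \code{instances}, \code{descriptor_names},
#'   \code{values} (3-D array instance x position x descriptor, NA at gaps),
#'   \code{gap} and \code{helical} (logical instance x position matrices) and
#'   \code{residues} (character matrix of amino acids, NA at gaps).
#' @export
align_ensemble <- function(instances, descriptors, chains, flank = 32,
                           mark_role = "PDB") {
  if (nrow(instances) == 0) stop("no helix instances to align")
  L <- unique(instances$length)
  if (length(L) != 1)
    stop(sprintf("mixed helix lengths in ensemble: %s",
                 paste(sort(L), collapse = ", ")))
  desc_names <- setdiff(colnames(descriptors), c("chain_id", "residue_index"))
  if (length(desc_names) == 0) stop("descriptor table has no value columns")
  P <- 2L * flank + L
  n <- nrow(instances)
  values <- array(NA_real_, c(n, P, length(desc_names)),
                  dimnames = list(NULL, NULL, desc_names))
  gap <- matrix(TRUE, n, P)
  helical <- matrix(FALSE, n, P)
  residues <- matrix(NA_character_, n, P)
  by_chain <- split(descriptors, descriptors$chain_id)
  for (i in seq_len(n)) {
    cid <- instances$chain_id[i]
    ch <- chains[[cid]]
    if (is.null(ch)) stop(sprintf("chain '%s' not found", cid))
    ann <- strsplit(ch$annotations[[mark_role]], "")[[1]]
    seq_chars <- strsplit(ch$sequence, "")[[1]]
    n_res <- length(seq_chars)
    idx <- seq(instances$start[i] - flank, instances$end[i] + flank)
    ok <- idx >= 1L & idx <= n_res
    gap[i, ] <- !ok
    helical[i, ok] <- ann[idx[ok]] == HELIX_CODE
    residues[i, ok] <- seq_chars[idx[ok]]
    tab <- by_chain[[cid]]
    if (is.null(tab)) stop(sprintf("no descriptor rows for chain '%s'", cid))
    m <- match(idx[ok], tab$residue_index)
    if (anyNA(m)) {
      miss <- idx[ok][is.na(m)][1]
      stop(sprintf("missing descriptor row: chain '%s', residue %d",
                   cid, miss))
    }
    for (d in seq_along(desc_names))
      values[i, ok, d] <- tab[[desc_names[d]]][m]
  }
  structure(list(L = L, flank = as.integer(flank),
                 positions = position_labels(L, flank),
                 instances = instances, descriptor_names = desc_names,
                 values = values, gap = gap, helical = helical,
                 residues = residues),
            class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf(
    "aligned ensemble: %d helices of length %d, flank %d (%d positions), %d descriptors\n",
    nrow(x$gap), x$L, x$flank, length(x$positions),
    length(x$descriptor_names)))
  invisible(x)
}

helix_columns <- function(ensemble) {
  seq(ensemble$flank + 1L, ensemble$flank + ensemble$L)
}

check_descriptor <- function(ensemble, descriptor) {
  if (!descriptor %in% ensemble$descriptor_names)
    stop(sprintf("unknown descriptor '%s'", descriptor))
  descriptor
}

#' Per-position profile of a descriptor over an aligned ensemble
#'
#' For every alignment position, the mean, standard deviation and standard
#' error of the mean (SEM = SD / sqrt(n)) of the descriptor over the non-gap
#' instances, together with two reliability measures: \code{occupancy_pct}
#' (percent of instances with a residue present) and \code{helical_pct}
#' (percent of instances whose residue at that position belongs to a helix).
#' Positions with fewer than two occupied cells report SD and SEM as NA.
#'
#' @param ensemble an [align_ensemble()] result.
#' @param descriptor descriptor name.
#' @return data.frame: \code{position}, \code{mean}, \code{sd}, \code{sem},
#'   \code{n}, \code{occupancy_pct}, \code{helical_pct}.
#' @export
position_profile <- function(ensemble, descriptor) {
  check_descriptor(ensemble, descriptor)
  v <- ensemble$values[, , descriptor, drop = FALSE]
  dim(v) <- dim(ensemble$gap)
  n_inst <- nrow(ensemble$gap)
  n <- colSums(!ensemble$gap)
  means <- colMeans(v, na.rm = TRUE)
  means[n == 0] <- NA_real_
  sds <- apply(v, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else sd(col)
  })
  data.frame(position = ensemble$positions,
             mean = means, sd = sds, sem = sds / sqrt(n), n = n,
             occupancy_pct = 100 * n / n_inst,
             helical_pct = 100 * colSums(ensemble$helical) / n_inst)
}

#' Position-by-amino-acid frequency matrix (sequence logo counts)
#'
#' @param ensemble an [align_ensemble()] result.
#' @param alphabet amino-acid alphabet (columns of the result).
#' @return numeric matrix, positions x amino acids; each occupied position's
#'   row sums to 1 (gaps excluded from the denominator); all-gap rows are 0.
#' @export
logo_matrix <- function(ensemble, alphabet = AMINO_ACIDS) {
  P <- length(ensemble$positions)
  out <- matrix(0, P, length(alphabet),
                dimnames = list(ensemble$positions, alphabet))
  for (j in seq_len(P)) {
    aa <- ensemble$residues[, j]
    aa <- aa[!is.na(aa)]
    if (length(aa) > 0)
      out[j, ] <- tabulate(factor(aa, levels = alphabet),
                           nbins = length(alphabet)) / length(aa)
  }
  out
}

#' Empirical cumulative distribution function table
#'
#' \eqn{F_n(x) = (1/n) \sum_i 1[X_i \le x]}, evaluated at the sorted unique
#' sample values.
#'
#' @param values nonempty numeric vector (NAs dropped).
#' @return data.frame of class \code{ecdf_table}: \code{value} (sorted
#'   unique) and \code{Fn} (nondecreasing, ending at 1); the sample size is
#'   attached as attribute \code{n}.
#' @export
ecdf_table <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("ecdf_table needs at least one value")
  x <- sort(unique(values))
  tbl <- data.frame(value = x,
                    Fn = cumsum(tabulate(match(sort(values), x))) /
                      length(values))
  attr(tbl, "n") <- length(values)
  class(tbl) <- c("ecdf_table", class(tbl))
  tbl
}

#' Evaluate an ECDF table at arbitrary points
#' @param tbl an [ecdf_table()]; @param x numeric points.
#' @return \eqn{F_n(x)}; 0 below the sample minimum, 1 at or above the max.
#' @export
ecdf_eval <- function(tbl, x) {
  vapply(x, function(xx) {
    i <- findInterval(xx, tbl$value)
    if (i == 0) 0 else tbl$Fn[i]
  }, numeric(1))
}

#' Inside and outside value sets of an aligned ensemble
#'
#' The "inside" set comes from helix-span columns and the "outside" set from
#' flank columns.  Granularity \code{"position"} (the default throughout the
#' profile-level analysis) uses per-position means over instances;
#' \code{"residue"} pools the raw non-gap cell values (the granularity of the
#' inverse-CV comparisons).
#'
#' @param ensemble an [align_ensemble()] result.
#' @param descriptor descriptor name.
#' @param granularity \code{"position"} or \code{"residue"}.
#' @return list with numeric vectors \code{inside} and \code{outside}.
#' @export
inside_outside_values <- function(ensemble, descriptor,
                                  granularity = c("position", "residue")) {
  granularity <- match.arg(granularity)
  check_descriptor(ensemble, descriptor)
  hc <- helix_columns(ensemble)
  v <- ensemble$values[, , descriptor, drop = FALSE]
  dim(v) <- dim(ensemble$gap)
  if (granularity == "position") {
    m <- colMeans(v, na.rm = TRUE)
    m[colSums(!ensemble$gap) == 0] <- NA_real_
    list(inside = m[hc], outside = m[-hc][!is.na(m[-hc])])
  } else {
    list(inside = as.vector(v[, hc])[!is.na(as.vector(v[, hc]))],
         outside = as.vector(v[, -hc])[!is.na(as.vector(v[, -hc]))])
  }
}

#' Inside-vs-outside ECDF pair for a descriptor
#'
#' @inheritParams inside_outside_values
#' @return list with two [ecdf_table()]s, \code{inside} and \code{outside},
#'   and \code{max_gap}, the largest absolute difference between the two
#'   curves over the pooled support.
#' @export
ecdf_pair <- function(ensemble, descriptor,
                      granularity = c("position", "residue")) {
  io <- inside_outside_values(ensemble, descriptor, granularity)
  inside <- ecdf_table(io$inside)
  outside <- ecdf_table(io$outside)
  support <- sort(unique(c(inside$value, outside$value)))
  gap <- max(abs(ecdf_eval(inside, support) - ecdf_eval(outside, support)))
  list(inside = inside, outside = outside, max_gap = gap)
}
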