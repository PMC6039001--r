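#' Configuration for a synthetic helix cohort
#'
#' Describes the stated world a synthetic cohort is drawn from: chain count
#' and lengths, helix length and multiplicity, and the per-descriptor value
#' model.  The value of descriptor \eqn{d} at residue \eqn{r} is
#' \deqn{x_{rd} = \mu_d + \delta_d \sigma_d 1[r \in helix] + \sigma_d e_{rd}}
#' where \eqn{e_{rd}} is unit-variance noise, optionally correlated across
#' descriptors through a shared per-residue factor, and optionally
#' heavy-tailed (standardized log-normal) for a trailing fraction of the
#' descriptors so that the normality filter has something to reject.
#'
#' @param n_chains number of chains to simulate.
#' @param chain_length_range integer length-2 vector, inclusive range of
#'   chain lengths in residues.
#' @param helix_length helix length L in residues; minimum analysed length
#'   is 5.
#' @param helices_per_chain integer vector of candidate helix counts per
#'   chain, sampled uniformly (a single value fixes the count; 1 makes every
#'   chain "exclusive").
#' @param n_descriptors number of descriptor columns.
#' @param baseline_mean,baseline_sd per-descriptor baseline mean and SD
#'   (recycled to \code{n_descriptors}); SDs must be positive.
#' @param inside_effect per-descriptor mean shift applied on helix residues,
#'   in units of \code{baseline_sd} (recycled).
#' @param correlation_model optional per-descriptor loading in [-1, 1] on a
#'   shared per-residue factor; \code{NULL} for independent noise.
#' @param nonnormal_fraction fraction of descriptors (taken from the end of
#'   the descriptor list) whose noise is standardized log-normal.
#' @param assigner_disagreement_p probability that a perturbed assigner view
#'   moves a given helix terminus by one residue.
#' @param duplicate_fraction fraction of chains that are near-duplicates of
#'   earlier chains (same annotation, mutated sequence, fresh noise).
#' @param mutation_rate per-residue substitution probability for duplicates.
#' @param class_label protein class recorded on every chain, one of
#'   \code{"all-alpha"} or \code{"alpha-beta"}.
#' @param seed integer master seed; per-chain sub-streams are derived from it.
#' @return an object of class \code{synthetic_config}.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_chains = 50,
                             chain_length_range = c(90, 140),
                             helix_length = 12,
                             helices_per_chain = 1L,
                             n_descriptors = 5,
                             baseline_mean = 0,
                             baseline_sd = 1,
                             inside_effect = 1,
                             correlation_model = NULL,
                             nonnormal_fraction = 0,
                             assigner_disagreement_p = 0,
                             duplicate_fraction = 0,
                             mutation_rate = 0.05,
                             class_label = c("all-alpha", "alpha-beta"),
                             seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(
    n_chains >= 1,
    length(chain_length_range) == 2,
    chain_length_range[1] >= 1,
    chain_length_range[1] <= chain_length_range[2],
    helix_length >= 5,
    all(helices_per_chain >= 1),
    n_descriptors >= 1
  )
  probs <- c(assigner_disagreement_p, duplicate_fraction, mutation_rate,
             nonnormal_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  baseline_mean <- rep_len(baseline_mean, n_descriptors)
  baseline_sd <- rep_len(baseline_sd, n_descriptors)
  inside_effect <- rep_len(inside_effect, n_descriptors)
  if (any(baseline_sd <= 0)) stop("baseline_sd must be > 0")
  if (!is.null(correlation_model)) {
    correlation_model <- rep_len(correlation_model, n_descriptors)
    if (any(abs(correlation_model) > 1))
      stop("correlation_model loadings must lie in [-1, 1]")
  }
  # a chain must be able to host k helices separated by >= 1 non-helix residue
  k_max <- max(helices_per_chain)
  need <- k_max * helix_length + (k_max - 1)
  if (chain_length_range[1] < need)
    stop(sprintf(
      "chains of length %d cannot hold %d helices of length %d (need >= %d)",
      chain_length_range[1], k_max, helix_length, need))
  structure(
    list(n_chains = as.integer(n_chains),
         chain_length_range = as.integer(chain_length_range),
         helix_length = as.integer(helix_length),
         helices_per_chain = as.integer(helices_per_chain),
         n_descriptors = as.integer(n_descriptors),
         baseline_mean = baseline_mean,
         baseline_sd = baseline_sd,
         inside_effect = inside_effect,
         correlation_model = correlation_model,
         nonnormal_fraction = nonnormal_fraction,
         assigner_disagreement_p = assigner_disagreement_p,
         duplicate_fraction = duplicate_fraction,
         mutation_rate = mutation_rate,
         class_label = class_label,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic per-chain sub-stream seed, kept below .Machine$integer.max.
substream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 7919) %% 2147483629)
}

# Place k helices of length L in a chain of n residues with >= 1 non-helix
# residue between consecutive helices (chain ends may touch a helix).
place_helices <- function(n, k, L) {
  slack <- n - k * L - (k - 1)
  extras <- tabulate(sample.int(k + 1, slack, replace = TRUE), nbins = k + 1)
  gaps <- c(0L, rep(1L, max(k - 1, 0)), 0L) + extras
  starts <- integer(k)
  pos <- 0L
  for (j in seq_len(k)) {
    pos <- pos + gaps[j]
    starts[j] <- pos + 1L
    pos <- pos + L
  }
  data.frame(start = starts, end = starts + L - 1L)
}

helices_to_annotation <- function(helices, n) {
  ann <- rep(COIL_CODE, n)
  for (j in seq_len(nrow(helices)))
    ann[helices$start[j]:helices$end[j]] <- HELIX_CODE
  paste(ann, collapse = "")
}

#' Derive three assigner views of a truth annotation
#'
#' Emulates secondary-structure assigner disagreement: the PDB role reproduces
#' the truth annotation; the DSSP and Stride roles independently move each
#' helix terminus by one residue with probability \code{disagreement_p}.
#' Perturbations only ever move termini (never interior residues), keep every
#' helix at least one residue long, and never let two helices touch or merge.
#' If a sampled move is impossible (chain end or neighbouring helix in the
#' way) the opposite move is used, so at \code{disagreement_p = 1} every helix
#' terminus is guaranteed to move in the perturbed views.
#'
#' @param truth annotation string over \code{c("H", "c")}.
#' @param disagreement_p per-terminus perturbation probability.
#' @param seed optional integer seed (uses the current RNG state if NULL).
#' @return named character vector of annotation strings for roles
#'   \code{PDB}, \code{DSSP}, \code{Stride}.
#' @export
make_assigner_views <- function(truth, disagreement_p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(truth)
  hel <- extract_helices(truth)
  perturb <- function() {
    if (nrow(hel) == 0) return(truth)
    h <- hel
    for (j in seq_len(nrow(h))) {
      lo <- if (j == 1) 1L else h$end[j - 1L] + 2L       # keep >= 1 gap
      hi <- if (j == nrow(h)) n else hel$start[j + 1L] - 2L
      for (side in c("start", "end")) {
        if (runif(1) >= disagreement_p) next
        delta <- sample(c(-1L, 1L), 1)
        cand <- h[[side]][j] + delta
        ok <- function(v) {
          if (side == "start") v >= lo && v <= h$end[j]
          else v >= h$start[j] && v <= hi
        }
        if (!ok(cand)) cand <- h[[side]][j] - delta
        if (ok(cand)) h[[side]][j] <- cand
      }
    }
    helices_to_annotation(h, n)
  }
  c(PDB = truth, DSSP = perturb(), Stride = perturb())
}

standardized_lognormal <- function(n) {
  (rlnorm(n) - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
}

descriptor_noise <- function(n_res, config) {
  p <- config$n_descriptors
  n_heavy <- round(config$nonnormal_fraction * p)
  heavy <- seq_len(p) > p - n_heavy
  eps <- matrix(0, n_res, p)
  for (d in seq_len(p))
    eps[, d] <- if (heavy[d]) standardized_lognormal(n_res) else rnorm(n_res)
  if (!is.null(config$correlation_model)) {
    z <- rnorm(n_res)
    lam <- config$correlation_model
    eps <- sweep(eps, 2, sqrt(1 - lam^2), `*`) + outer(z, lam)
  }
  eps
}

mutate_sequence <- function(seq_chars, rate) {
  hit <- runif(length(seq_chars)) < rate
  if (any(hit))
    seq_chars[hit] <- vapply(seq_chars[hit], function(a)
      sample(setdiff(AMINO_ACIDS, a), 1), character(1))
  seq_chars
}

#' Generate a synthetic cohort of chains, annotations and descriptors
#'
#' Draws the world described by a [synthetic_config()]: chain sequences,
#' truth helix placements, three assigner annotation views, and a
#' residue-by-descriptor value table with the configured inside-helix mean
#' shift.  Near-duplicate chains (controlled by \code{duplicate_fraction})
#' reuse an earlier chain's helix placement and mutate its sequence at
#' \code{mutation_rate}, providing material for redundancy clustering.
#' Generation is deterministic for a fixed seed; each chain uses a sub-stream
#' derived from the master seed.
#'
#' @param config a [synthetic_config()].
#' @return an object of class \code{helix_cohort}: a list with
#'   \code{chains} (list of chain records: \code{chain_id}, \code{sequence},
#'   \code{annotations} named by assigner role, \code{class_label}),
#'   \code{descriptors} (data.frame: chain_id, residue_index, one numeric
#'   column per descriptor \code{D1..Dp}), \code{true_helices} (data.frame:
#'   chain_id, start, end, length) and \code{config}.
#' @examples
#' cfg <- synthetic_config(n_chains = 4, seed = 7)
#' cohort <- generate_cohort(cfg)
#' names(cohort$chains)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_dup <- floor(config$duplicate_fraction * config$n_chains)
  n_orig <- config$n_chains - n_dup
  if (n_orig < 1) stop("duplicate_fraction leaves no original chains")
  chains <- vector("list", config$n_chains)
  desc_rows <- vector("list", config$n_chains)
  truths <- vector("list", config$n_chains)
  L <- config$helix_length
  for (i in seq_len(config$n_chains)) {
    set.seed(substream_seed(config$seed, i))
    cid <- sprintf("SYN%04d", i)
    if (i <= n_orig) {
      n_res <- sample(seq(config$chain_length_range[1],
                          config$chain_length_range[2]), 1)
      k <- if (length(config$helices_per_chain) == 1) config$helices_per_chain
           else sample(config$helices_per_chain, 1)
      hel <- place_helices(n_res, k, L)
      seq_chars <- sample(AMINO_ACIDS, n_res, replace = TRUE)
    } else {
      src_idx <- sample.int(n_orig, 1)
      src <- chains[[src_idx]]
      n_res <- nchar(src$sequence)
      hel <- truths[[src_idx]]
      seq_chars <- mutate_sequence(strsplit(src$sequence, "")[[1]],
                                   config$mutation_rate)
    }
    truth_ann <- helices_to_annotation(hel, n_res)
    views <- make_assigner_views(truth_ann, config$assigner_disagreement_p)
    inside <- rep(FALSE, n_res)
    for (j in seq_len(nrow(hel))) inside[hel$start[j]:hel$end[j]] <- TRUE
    eps <- descriptor_noise(n_res, config)
    vals <- sweep(eps, 2, config$baseline_sd, `*`)
    vals <- sweep(vals, 2, config$baseline_mean, `+`)
    shift <- config$inside_effect * config$baseline_sd
    vals <- vals + outer(inside, shift)
    colnames(vals) <- paste0("D", seq_len(config$n_descriptors))
    chains[[i]] <- list(chain_id = cid,
                        sequence = paste(seq_chars, collapse = ""),
                        annotations = views,
                        class_label = config$class_label)
    desc_rows[[i]] <- data.frame(chain_id = cid,
                                 residue_index = seq_len(n_res), vals,
                                 stringsAsFactors = FALSE)
    truths[[i]] <- hel
  }
  true_helices <- do.call(rbind, lapply(seq_along(truths), function(i)
    if (nrow(truths[[i]]) > 0)
      data.frame(chain_id = chains[[i]]$chain_id, truths[[i]],
                 length = truths[[i]]$end - truths[[i]]$start + 1L)))
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  structure(list(chains = chains,
                 descriptors = do.call(rbind, desc_rows),
                 true_helices = true_helices,
                 config = config),
            class = "helix_cohort")
}

#' @export
print.helix_cohort <- function(x, ...) {
  cat(sprintf(
    "helix cohort: %d chains, %d descriptors, helix length %d, seed %d\n",
    length(x$chains), x$config$n_descriptors, x$config$helix_length,
    x$config$seed))
  invisible(x)
}
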