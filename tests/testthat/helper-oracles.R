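# Independent oracles used to check the package's own statistics.

# Needleman-Wunsch global alignment identity: match = 1, mismatch = 0,
# per-gap penalty 1; identity = matches / alignment length.  Small DP kept
# deliberately naive and separate from seq_identity()'s Biostrings route.
nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  # traceback to recover matches and alignment length
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  matches / len
}

# Brute-force two-sample KS distance: max ECDF gap over a dense evaluation
# grid (midpoints included so plateaus between points are covered).
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  grid <- sort(c(pts, pts - 1e-9))
  max(vapply(grid, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# All multisets of a given size drawn from a value grid.
enumerate_multisets <- function(values, size) {
  idx <- do.call(expand.grid, rep(list(seq_along(values)), size))
  idx <- idx[apply(idx, 1, function(r) all(diff(r) >= 0)), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) values[as.integer(idx[i, ])])
}

# Minimal hand-built cohort: chains given as annotation strings, one
# descriptor ("D1") with deterministic values value_fun(residue index).
make_manual_cohort <- function(annotations, value_fun = function(i) i,
                               class_label = "all-alpha") {
  chains <- list()
  rows <- list()
  for (k in seq_along(annotations)) {
    cid <- sprintf("CH%02d", k)
    ann <- annotations[[k]]
    n <- nchar(ann)
    chains[[cid]] <- list(
      chain_id = cid,
      sequence = paste(rep("A", n), collapse = ""),
      annotations = c(PDB = ann, DSSP = ann, Stride = ann),
      class_label = class_label)
    rows[[k]] <- data.frame(chain_id = cid, residue_index = seq_len(n),
                            D1 = value_fun(seq_len(n)))
  }
  list(chains = chains, descriptors = do.call(rbind, rows))
}
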