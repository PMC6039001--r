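#' Normality filter for descriptor columns
#'
#' Retains a descriptor only if a Shapiro-Wilk test of its values, run
#' separately within each group, is non-significant (p >= alpha) in every
#' group.  Constant columns are removed as degenerate.  Groups larger than
#' 5000 observations are deterministically thinned to 5000 evenly spaced
#' values (the test's size limit).
#'
#' @param table numeric matrix or data.frame, observations x descriptors.
#' @param groups optional grouping vector (e.g. inside/outside labels); NULL
#'   tests each column as a single sample.
#' @param alpha significance level (default 0.05).
#' @return list with \code{retained} (character), \code{removed_nonnormal}
#'   (data.frame: descriptor, group, W, p) and \code{removed_degenerate}
#'   (character).
#' @export
normality_filter <- function(table, groups = NULL, alpha = 0.05) {
  table <- as.data.frame(table)
  if (is.null(groups)) groups <- rep("all", nrow(table))
  groups <- as.factor(groups)
  retained <- character()
  nonnormal <- list()
  degenerate <- character()
  for (d in colnames(table)) {
    x <- table[[d]]
    if (length(unique(x[!is.na(x)])) < 2) {
      degenerate <- c(degenerate, d)
      next
    }
    fails <- NULL
    for (g in levels(groups)) {
      xs <- x[groups == g & !is.na(x)]
      if (length(xs) < 3)
        stop(sprintf("descriptor '%s', group '%s': need >= 3 observations",
                     d, g))
      if (length(xs) > 5000)
        xs <- xs[round(seq(1, length(xs), length.out = 5000))]
      if (length(unique(xs)) < 2) { fails <- data.frame(
        descriptor = d, group = g, W = NA_real_, p = 0); break }
      sw <- shapiro.test(xs)
      if (sw$p.value < alpha) {
        fails <- data.frame(descriptor = d, group = g,
                            W = unname(sw$statistic), p = sw$p.value)
        break
      }
    }
    if (is.null(fails)) retained <- c(retained, d)
    else nonnormal[[length(nonnormal) + 1L]] <- fails
  }
  list(retained = retained,
       removed_nonnormal = if (length(nonnormal) > 0)
         do.call(rbind, nonnormal) else
         data.frame(descriptor = character(), group = character(),
                    W = numeric(), p = numeric()),
       removed_degenerate = degenerate)
}

#' Pairwise-correlation filter for descriptor columns
#'
#' Greedy elimination of linearly correlated descriptors: while any pair has
#' absolute Pearson correlation at or above the cutoff, the member of the
#' worst pair with the larger mean absolute correlation to all remaining
#' descriptors is dropped (ties drop the later column).  The result has all
#' pairwise |r| below the cutoff.
#'
#' @param table numeric matrix or data.frame, observations x descriptors.
#' @param cutoff correlation cutoff (default 0.9).
#' @return list with \code{retained} (character) and
#'   \code{removed_correlation} (data.frame: descriptor, partner, r).
#' @export
correlation_filter <- function(table, cutoff = 0.9) {
  table <- as.data.frame(table)
  stopifnot(nrow(table) >= 2)
  keep <- colnames(table)
  removed <- list()
  while (length(keep) >= 2) {
    C <- cor(table[, keep, drop = FALSE])
    A <- abs(C); diag(A) <- 0
    mx <- max(A)
    if (mx < cutoff) break
    hit <- which(A == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE][1, ]
    i <- hit[1]; j <- hit[2]
    mi <- mean(A[i, -i]); mj <- mean(A[j, -j])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    partner <- if (drop == i) j else i
    removed[[length(removed) + 1L]] <- data.frame(
      descriptor = keep[drop], partner = keep[partner], r = C[i, j])
    keep <- keep[-drop]
  }
  list(retained = keep,
       removed_correlation = if (length(removed) > 0)
         do.call(rbind, removed) else
         data.frame(descriptor = character(), partner = character(),
                    r = numeric()))
}

#' Apply the normality and correlation filters in sequence
#'
#' Normality first, then correlation among the normality survivors —
#' the order of the published filtering recipe.
#'
#' @inheritParams normality_filter
#' @inheritParams correlation_filter
#' @return a filter report: list with \code{input}, \code{retained},
#'   \code{removed_nonnormal}, \code{removed_degenerate},
#'   \code{removed_correlation}.
#' @export
apply_descriptor_filters <- function(table, groups = NULL, alpha = 0.05,
                                     cutoff = 0.9) {
  table <- as.data.frame(table)
  norm <- normality_filter(table, groups, alpha)
  if (length(norm$retained) == 0)
    return(list(input = colnames(table), retained = character(),
                removed_nonnormal = norm$removed_nonnormal,
                removed_degenerate = norm$removed_degenerate,
                removed_correlation = data.frame(descriptor = character(),
                                                 partner = character(),
                                                 r = numeric())))
  corr <- correlation_filter(table[, norm$retained, drop = FALSE], cutoff)
  list(input = colnames(table),
       retained = corr$retained,
       removed_nonnormal = norm$removed_nonnormal,
       removed_degenerate = norm$removed_degenerate,
       removed_correlation = corr$removed_correlation)
}

# Eigenvalues of solve(W) %*% B for a one-way layout.
manova_eigen <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  N <- nrow(X); p <- ncol(X)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(groups)) {
    Xi <- X[groups == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    cc <- sweep(Xi, 2, mi)
    W <- W + crossprod(cc)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  if (kappa(W) > 1e12)
    stop("singular pooled covariance; apply stronger correlation filtering")
  eig <- Re(eigen(solve(W, B), only.values = TRUE)$values)
  list(eig = pmax(eig, 0), q = g - 1, df_res = N - g, p = p)
}

manova_stat_table <- function(eig, q, df_res) {
  p <- length(eig)
  s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1)
  nn <- 0.5 * (df_res - p - 1)
  rows <- list()
  # Pillai's trace
  V <- sum(eig / (1 + eig))
  df1 <- s * (2 * m + s + 1); df2 <- s * (2 * nn + s + 1)
  rows$Pillai <- c(V, (2 * nn + s + 1) / (2 * m + s + 1) * V / (s - V),
                   df1, df2)
  # Wilks' lambda (Rao's F)
  lam <- prod(1 / (1 + eig))
  tmp1 <- df_res - 0.5 * (p - q + 1)
  tmp2 <- (p * q - 2) / 4
  tmp3 <- p^2 + q^2 - 5
  tmp3 <- if (tmp3 > 0) sqrt(((p * q)^2 - 4) / tmp3) else 1
  rows$Wilks <- c(lam, ((lam^(-1 / tmp3) - 1) * (tmp1 * tmp3 - 2 * tmp2)) /
                    (p * q), p * q, tmp1 * tmp3 - 2 * tmp2)
  # Hotelling-Lawley trace
  U <- sum(eig)
  df2h <- 2 * (s * nn + 1)
  rows$`Hotelling-Lawley` <- c(U, df2h * U / (s * s * (2 * m + s + 1)),
                               s * (2 * m + s + 1), df2h)
  # Roy's largest root (upper-bound F)
  r1 <- max(p, q)
  rows$Roy <- c(max(eig), (df_res - r1 + q) * max(eig) / r1,
                r1, df_res - r1 + q)
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    data.frame(statistic = nm, value = v[1], approx_F = v[2],
               df1 = v[3], df2 = v[4],
               p_value = pf(v[2], v[3], v[4], lower.tail = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' MANOVA of inside-vs-outside residue groups
#'
#' One-way multivariate analysis of variance comparing the descriptor
#' vectors of residues inside a helix region against residues outside it,
#' reporting the four canonical statistics — Wilks' lambda, Pillai's trace,
#' the Hotelling-Lawley trace and Roy's largest root — each with its F
#' approximation, degrees of freedom and p-value.  With two groups all four
#' F approximations coincide (a single nonzero eigenvalue); with a single
#' descriptor the test reduces to one-way ANOVA.
#'
#' @param table numeric matrix or data.frame of retained descriptors,
#'   observations (residues) x descriptors.
#' @param labels grouping vector of length \code{nrow(table)} (e.g. logical
#'   inside/outside).
#' @param filter_report optional filter report recorded in the result.
#' @return object of class \code{manova_report}: list with
#'   \code{group_sizes}, \code{n_descriptors}, \code{stats} (four-row
#'   data.frame) and \code{filter_report}.
#' @export
manova_inside_outside <- function(table, labels, filter_report = NULL) {
  table <- as.data.frame(table)
  labels <- as.factor(labels)
  stopifnot(nrow(table) == length(labels), nlevels(labels) >= 2)
  p <- ncol(table)
  sizes <- table(labels)
  if (any(sizes <= p))
    stop(sprintf(
      "each group must exceed the descriptor count (%d); sizes: %s",
      p, paste(sizes, collapse = ", ")))
  me <- manova_eigen(table, labels)
  structure(list(group_sizes = as.integer(sizes),
                 n_descriptors = p,
                 stats = manova_stat_table(me$eig, me$q, me$df_res),
                 filter_report = filter_report),
            class = "manova_report")
}

#' @export
print.manova_report <- function(x, ...) {
  cat(sprintf("MANOVA: groups of %s on %d descriptors\n",
              paste(x$group_sizes, collapse = " / "), x$n_descriptors))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Descriptor-usage ranking across helix sizes
#'
#' Counts, for every descriptor, the number of analysed helix sizes at which
#' it survived filtering (and thus entered the MANOVA), with the share of
#' sizes as a percentage, sorted most-used first.
#'
#' @param reports named list (one element per helix size) of filter reports
#'   or plain character vectors of retained descriptor names.
#' @return data.frame: \code{descriptor}, \code{n_sizes}, \code{pct}.
#' @export
usage_ranking <- function(reports) {
  stopifnot(length(reports) >= 1)
  retained <- lapply(reports, function(r)
    if (is.character(r)) r else r$retained)
  all_desc <- sort(unique(unlist(retained)))
  counts <- vapply(all_desc, function(d)
    sum(vapply(retained, function(r) d %in% r, TRUE)), 0L)
  out <- data.frame(descriptor = all_desc, n_sizes = counts,
                    pct = 100 * counts / length(reports))
  out <- out[order(-out$n_sizes, out$descriptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess whether a chain region has a helix-like nanoenvironment
#'
#' Runs the filtered inside-vs-outside MANOVA for one candidate region of a
#' single chain: residues within \code{region} form the inside group, all
#' other residues the outside group.  The verdict is "helix-like" when the
#' smallest of the four MANOVA p-values is at or below the threshold
#' (default 1e-6, the working significance level of the published
#' quality-assessment case).
#'
#' @param chain_table per-residue descriptor table for one chain
#'   (\code{residue_index} plus numeric descriptor columns).
#' @param region integer length-2 vector, first and last residue of the
#'   candidate region (1-based, inclusive).
#' @param threshold p-value threshold for the verdict.
#' @param alpha,cutoff filter parameters, see [apply_descriptor_filters()].
#' @return list of class \code{region_assessment}: \code{region},
#'   \code{helix_like} (logical), \code{min_p}, \code{manova}
#'   (a \code{manova_report}) and \code{filter_report}.
#' @export
assess_region <- function(chain_table, region, threshold = 1e-6,
                          alpha = 0.05, cutoff = 0.9) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  idx <- chain_table$residue_index
  if (is.null(idx)) idx <- seq_len(nrow(chain_table))
  if (region[1] < min(idx) || region[2] > max(idx))
    stop("region outside chain")
  inside <- idx >= region[1] & idx <= region[2]
  if (all(inside)) stop("region covers the whole chain")
  if (sum(inside) < 2 || sum(!inside) < 2)
    stop("insufficient group size: need >= 2 residues inside and outside")
  X <- chain_table[, setdiff(colnames(chain_table),
                             c("chain_id", "residue_index")), drop = FALSE]
  rep <- apply_descriptor_filters(X, inside, alpha, cutoff)
  if (length(rep$retained) == 0)
    stop("no descriptors survive filtering for this region")
  mv <- manova_inside_outside(X[, rep$retained, drop = FALSE], inside, rep)
  min_p <- min(mv$stats$p_value)
  structure(list(region = region, helix_like = min_p <= threshold,
                 min_p = min_p, manova = mv, filter_report = rep),
            class = "region_assessment")
}

#' @export
print.region_assessment <- function(x, ...) {
  cat(sprintf("region %d..%d: %s (min MANOVA p = %.3g)\n",
              x$region[1], x$region[2],
              if (x$helix_like) "helix-like nanoenvironment" else
                "no helix-like signal", x$min_p))
  invisible(x)
}
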