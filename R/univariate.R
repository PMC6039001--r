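#' Pooled-variance two-sample Student t-test
#'
#' Implements the classical equal-variance form:
#' \deqn{t = (\bar x_1 - \bar x_2) / (S_{x_1 x_2} \sqrt{1/n_1 + 1/n_2})}
#' with pooled SD
#' \eqn{S_{x_1 x_2} = \sqrt{((n_1-1) S^2_{x_1} + (n_2-1) S^2_{x_2}) / (n_1+n_2-2)}}
#' and \eqn{n_1 + n_2 - 2} degrees of freedom; the p-value is two-sided.
#' Degenerate inputs (zero pooled variance) yield \code{t = 0, p = 1} when
#' the means are equal — so constant descriptors scan cleanly — and a
#' flagged infinite statistic when they are not.
#'
#' @param x1,x2 numeric samples, each of size >= 2 (NAs dropped).
#' @return list of class \code{helix_ttest}: \code{t}, \code{df},
#'   \code{pooled_sd}, \code{mean1}, \code{mean2}, \code{n1}, \code{n2},
#'   \code{p_value}, \code{degenerate}.
#' @export
two_sample_t <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("two_sample_t needs at least 2 values per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / df
  m1 <- mean(x1); m2 <- mean(x2)
  if (sp2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) {
      t <- 0; p <- 1; degen <- TRUE
    } else {
      warning("zero pooled variance with unequal means; statistic is infinite")
      t <- sign(m1 - m2) * Inf; p <- 0; degen <- TRUE
    }
  } else {
    t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(t), df)
    degen <- FALSE
  }
  structure(list(t = t, df = df, pooled_sd = sqrt(max(sp2, 0)),
                 mean1 = m1, mean2 = m2, n1 = n1, n2 = n2,
                 p_value = p, degenerate = degen),
            class = "helix_ttest")
}

# Asymptotic Kolmogorov distribution tail: P(sqrt(ne) * Dn > lambda).
kolmogorov_p <- function(lambda, terms = 100) {
  if (lambda <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D_n = \sup_x |F_1(x) - F_2(x)|} computed over the pooled sample
#' support, with an asymptotic p-value from the Kolmogorov distribution at
#' effective sample size \eqn{n_1 n_2 / (n_1 + n_2)}.
#'
#' @param x1,x2 nonempty numeric samples (NAs dropped).
#' @return list of class \code{helix_ks}: \code{Dn}, \code{n1}, \code{n2},
#'   \code{p_value}.
#' @export
ks_two_sample <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1 || n2 < 1) stop("ks_two_sample needs nonempty samples")
  support <- sort(unique(c(x1, x2)))
  F1 <- vapply(support, function(x) mean(x1 <= x), numeric(1))
  F2 <- vapply(support, function(x) mean(x2 <= x), numeric(1))
  Dn <- max(abs(F1 - F2))
  ne <- n1 * n2 / (n1 + n2)
  structure(list(Dn = Dn, n1 = n1, n2 = n2,
                 p_value = kolmogorov_p(sqrt(ne) * Dn)),
            class = "helix_ks")
}

run_window_test <- function(inside, outside, test) {
  inside <- inside[!is.na(inside)]; outside <- outside[!is.na(outside)]
  if (test == "t") {
    if (length(inside) < 2 || length(outside) < 2) return(NA_real_)
    suppressWarnings(two_sample_t(inside, outside)$p_value)
  } else {
    if (length(inside) < 1 || length(outside) < 1) return(NA_real_)
    ks_two_sample(inside, outside)$p_value
  }
}

#' Sliding-window scan of a positional profile
#'
#' Slides a window of \code{w} positions along a per-position profile (the
#' \code{mean} column of [position_profile()], or any numeric vector over
#' the \code{2*flank + L} alignment positions) and, at each placement, tests
#' the values under the window against all remaining positions with a
#' pooled-variance t-test or a two-sample KS test.  When the profile carries
#' an inside-helix shift, the placement with the smallest p-value is expected
#' at the helix span.
#'
#' @param profile numeric vector of per-position values (NAs allowed; a
#'   placement whose groups retain fewer than the test's minimum number of
#'   usable values yields an NA p-value).
#' @param w window width, \code{1 <= w <= length(profile) - 2}; the analysis
#'   default is the helix length L.
#' @param test \code{"t"} or \code{"ks"}.
#' @param positions optional position labels (defaults to 1..length(profile)).
#' @return object of class \code{window_scan}: data.frame with
#'   \code{placement} (index of the window's first position),
#'   \code{position} (its label) and \code{p_value}; attributes \code{w},
#'   \code{test} and \code{argmin} (earliest placement attaining the
#'   smallest defined p-value; NA if none defined).
#' @export
sliding_window_scan <- function(profile, w, test = c("t", "ks"),
                                positions = seq_along(profile)) {
  test <- match.arg(test)
  P <- length(profile)
  if (w < 1 || P - w < 2)
    stop(sprintf("window width %d out of range for %d positions", w, P))
  n_place <- P - w + 1L
  p <- vapply(seq_len(n_place), function(i) {
    run_window_test(profile[i:(i + w - 1L)], profile[-(i:(i + w - 1L))], test)
  }, numeric(1))
  out <- data.frame(placement = seq_len(n_place),
                    position = positions[seq_len(n_place)], p_value = p)
  attr(out, "w") <- w
  attr(out, "test") <- test
  attr(out, "argmin") <- if (all(is.na(p))) NA_integer_ else
    which.min(p)  # which.min takes the earliest placement on ties
  class(out) <- c("window_scan", class(out))
  out
}

#' Scans over a range of window sizes
#'
#' Runs [sliding_window_scan()] for every window width from 1 to
#' \code{2 * L} (or any supplied range), mirroring the varying-window
#' experiment: the minimum-p placement per width identifies the helix span,
#' preferably already at small widths.
#'
#' @param profile per-position values as in [sliding_window_scan()].
#' @param L helix length (sets the default width range \code{1:(2*L)}).
#' @param widths integer vector of window widths.
#' @param test \code{"t"} or \code{"ks"}.
#' @param positions optional position labels.
#' @return list with \code{scans} (one \code{window_scan} per width, named
#'   by width) and \code{summary} (data.frame: \code{w}, \code{argmin},
#'   \code{min_p}).
#' @export
multi_window_scan <- function(profile, L, widths = seq_len(2 * L),
                              test = c("t", "ks"),
                              positions = seq_along(profile)) {
  test <- match.arg(test)
  widths <- widths[widths >= 1 & widths <= length(profile) - 2]
  scans <- lapply(widths, function(w)
    sliding_window_scan(profile, w, test, positions))
  names(scans) <- widths
  summary <- data.frame(
    w = widths,
    argmin = vapply(scans, function(s) as.integer(attr(s, "argmin")), 0L),
    min_p = vapply(scans, function(s)
      if (all(is.na(s$p_value))) NA_real_ else
        min(s$p_value, na.rm = TRUE), 0))
  list(scans = scans, summary = summary)
}

#' Inverse coefficient-of-variation signal classification
#'
#' Normalizes the inside-helix and outside-helix value sets of a descriptor
#' by the inverse coefficient of variation (mean divided by SD) and
#' classifies the absolute difference of the two normalized values:
#' below 0.1 no signal, between 0.1 and 1.0 a moderate signal, above 1.0 a
#' strong signal.  By default the raw residue values of each region are
#' used (the granularity of the region-set comparisons).
#'
#' @param ensemble an [align_ensemble()] result.
#' @param descriptor descriptor name.
#' @param granularity see [inside_outside_values()]; default
#'   \code{"residue"}.
#' @param thresholds length-2 numeric, the none/moderate and moderate/strong
#'   boundaries (default \code{c(0.1, 1.0)}).
#' @return data.frame row: \code{descriptor}, \code{inside_norm},
#'   \code{outside_norm}, \code{difference}, \code{class} (one of
#'   \code{"none"}, \code{"moderate"}, \code{"strong"}, \code{"undefined"}
#'   when a region SD is zero).
#' @export
icv_classify <- function(ensemble, descriptor,
                         granularity = c("residue", "position"),
                         thresholds = c(0.1, 1.0)) {
  granularity <- match.arg(granularity)
  io <- inside_outside_values(ensemble, descriptor, granularity)
  sd_in <- sd(io$inside); sd_out <- sd(io$outside)
  if (is.na(sd_in) || is.na(sd_out) || sd_in == 0 || sd_out == 0) {
    return(data.frame(descriptor = descriptor, inside_norm = NA_real_,
                      outside_norm = NA_real_, difference = NA_real_,
                      class = "undefined"))
  }
  ni <- mean(io$inside) / sd_in
  no <- mean(io$outside) / sd_out
  d <- ni - no
  cls <- classify_difference(abs(d), thresholds)
  data.frame(descriptor = descriptor, inside_norm = ni, outside_norm = no,
             difference = d, class = cls)
}

classify_difference <- function(absdiff, thresholds = c(0.1, 1.0)) {
  if (absdiff < thresholds[1]) "none"
  else if (absdiff <= thresholds[2]) "moderate"
  else "strong"
}

#' Census of signal-bearing descriptors
#'
#' Classifies every descriptor of an ensemble with [icv_classify()] and
#' tallies the classes.  The signal percentage is the share of descriptors
#' with a moderate or strong signal.
#'
#' @param ensemble an [align_ensemble()] result.
#' @param descriptors descriptor names (default: all in the ensemble).
#' @param ... passed to [icv_classify()].
#' @return list of class \code{signal_census}: \code{table} (one row per
#'   descriptor), \code{counts} (named: strong, moderate, none, undefined)
#'   and \code{signal_pct}.
#' @export
signal_census <- function(ensemble, descriptors = ensemble$descriptor_names,
                          ...) {
  tab <- do.call(rbind, lapply(descriptors, function(d)
    icv_classify(ensemble, d, ...)))
  counts <- vapply(c("strong", "moderate", "none", "undefined"),
                   function(cl) sum(tab$class == cl), 0L)
  structure(list(table = tab, counts = counts,
                 signal_pct = census_percentage(counts["strong"],
                                                counts["moderate"],
                                                length(descriptors))),
            class = "signal_census")
}

#' Signal-census percentage from class counts
#'
#' @param n_strong,n_moderate,n_total counts of strong and moderate
#'   descriptors and the descriptor total.
#' @return percentage of signal-bearing descriptors,
#'   \code{100 * (n_strong + n_moderate) / n_total}.
#' @export
census_percentage <- function(n_strong, n_moderate, n_total) {
  stopifnot(n_total > 0, n_strong + n_moderate <= n_total)
  unname(100 * (n_strong + n_moderate) / n_total)
}

#' @export
print.signal_census <- function(x, ...) {
  cat(sprintf(
    "signal census: %d strong, %d moderate, %d none, %d undefined (%.1f%% signal-bearing)\n",
    x$counts["strong"], x$counts["moderate"], x$counts["none"],
    x$counts["undefined"], x$signal_pct))
  invisible(x)
}
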