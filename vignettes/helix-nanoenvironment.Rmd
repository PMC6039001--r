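---
title: "Detecting the alpha-helix nanoenvironment signal"
author: "helixenv developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the alpha-helix nanoenvironment signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixenv)
```

## The model

A protein secondary structure element does not exist in isolation: the
residues of an α-helix together with the residues immediately around it form
a *nanoenvironment* whose physicochemical character should differ measurably
from the rest of the chain. helixenv operationalizes that neighbourhood as
the helix span plus 32 residues on either side, and asks a purely
statistical question: for a per-residue descriptor $x$ (a hydrogen-bond
contact count, an electrostatic potential, a dihedral angle, …), do the
values inside the span differ from the values outside it?

The analysis pipeline is:

1. **Consensus helices.** Secondary-structure assigners disagree at helix
   termini. A helix enters the analysis only if every assigner named by the
   chosen *consensus mode* (all of PDB/DSSP/Stride, or one of the three
   pairs) places both its start and its end at the same residue. Only code
   `H` counts as α-helix; 3~10~ (`G`) and π (`I`) helices are deliberately
   non-helix (configurable in `parse_dssp()`).
2. **Redundancy removal.** Near-identical sequences would pseudo-replicate
   the ensemble, so chains are greedily clustered at an identity level
   (0.95, 0.70 or 0.50) and one representative per cluster is kept.
3. **Positional alignment.** All helices of one length $L$ are stacked so
   position 1 is every helix's N-terminal residue, over $64 + L$ columns.
   Flank cells beyond a chain end are gaps; flank residues belonging to
   *another* helix are helix-marked, because neighbouring helices perturb
   the flank statistics and the reliability plot must show where.
4. **Profiles and univariate tests.** Per-position mean/SD/SEM, occupancy,
   logo frequencies and inside/outside ECDFs; then a sliding window of $w$
   positions is tested (pooled-variance $t$ or two-sample KS) against all
   positions outside the window, for every placement and, if requested,
   every $w \in 1..2L$. A real helix signal shows up as a sharp p-value
   minimum exactly when the window covers the span.
5. **Inverse-CV classification.** Per descriptor, inside and outside value
   sets are normalized by mean/SD (the inverse coefficient of variation);
   the absolute difference of the two normalized values classifies the
   descriptor: $<0.1$ no signal, $0.1$–$1.0$ moderate, $>1.0$ strong.
6. **Multivariate analysis.** Residue vectors inside vs outside the span
   are compared by one-way MANOVA after two filters: per-group
   Shapiro–Wilk normality at $\alpha = 0.05$, then greedy removal of
   pairwise correlations $|r| \ge 0.9$. All four canonical statistics
   (Wilks' $\Lambda$, Pillai's trace, Hotelling–Lawley trace, Roy's largest
   root) are reported with their $F$ approximations. `assess_region()`
   applies this machinery to one candidate region of one chain and calls it
   a helix-like nanoenvironment when the minimum p-value is at most a
   threshold (default $10^{-6}$).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| flank | 32 | residues | the neighbourhood width; the empirically conventional observation field around a helix |
| consensus mode | pdb-dssp-stride | — | the most rigorous grouping; pairwise modes trade purity for sample size |
| redundancy level | none / 0.95–0.50 | identity | higher keeps more chains; 0.70 is the usual working level |
| window size $w$ | $L$ | positions | a window matching the helix length maximizes contrast at the true placement; the multi-window sweep covers $1..2L$ |
| signal thresholds | 0.1, 1.0 | normalized units | inverse-CV class boundaries for none/moderate/strong |
| normality $\alpha$ | 0.05 | — | per-group Shapiro–Wilk level |
| correlation cutoff | 0.9 | $|r|$ | collinear descriptors destabilize the MANOVA covariance |
| assessment threshold | $10^{-6}$ | p-value | the working level at which a region is called helix-like |

## The synthetic world

`synthetic_config()` states the world the tests live in. Descriptor $d$ at
residue $r$ is

$$x_{rd} = \mu_d + \delta_d\,\sigma_d\,[r \in \text{helix}] + \sigma_d e_{rd},$$

with unit-variance noise $e$, optionally correlated across descriptors by a
shared per-residue factor, and optionally standardized log-normal for a
trailing fraction of descriptors (so the normality filter has true
positives). Assigner disagreement moves helix termini by one residue with a
set probability — only termini, never interior residues, and never merging
two helices, which mirrors how real assigners actually differ. Duplicate
chains reuse a source chain's helix layout and mutate its sequence at a set
rate. Gaps arise only implicitly, when a helix sits closer than 32 residues
to a chain end — the same mechanism that produces them in real alignments.

Calibration defaults (the field's plausible magnitudes, chosen once): chains
of 90–140 residues, helix length 12, inside effect 1 SD, Gaussian baseline
$\mu = 0, \sigma = 1$, 5% substitution rate for near-duplicates. No
published effect sizes exist for real descriptors, so these are calibration
choices, not reproduced values.

What the generator does **not** emulate: atomic coordinates (descriptors
are drawn, not computed from structure), descriptor-specific marginal
distributions, autocorrelation of descriptor values along the chain, and
composition bias of real sequences. A green test therefore establishes that
the *statistical machinery* behaves as specified on data with the assumed
structure — not that any particular real descriptor carries a signal.

## Numerical choices

* **ECDF** uses the weak inequality $F_n(x) = \tfrac1n\sum_i [X_i \le x]$
  (the standard estimator; it is what makes $F_n(2) = 2/3$ for $\{1,2,3\}$).
* **Degenerate samples**: a zero pooled variance with equal means yields
  $t = 0, p = 1$ so constant profiles scan cleanly; with unequal means the
  statistic is flagged infinite rather than silently clamped.
* **KS p-values** come from the asymptotic Kolmogorov series at effective
  size $n_1 n_2/(n_1+n_2)$; the suite checks agreement with an exact
  brute-force $D_n$ oracle and with `stats::ks.test(exact = FALSE)`.
* **Window scans**: "outside" is everything not under the window, not just
  the flanks; placements with too few usable values give NA p-values, and
  the argmin takes the earliest placement on ties. Window size 1 is allowed
  (the multi-window sweep needs it); its $t$ rows are all-NA by the
  insufficient-data rule while KS still runs.
* **Granularity**: profile-level statistics (per-position means) are the
  default for scans and ECDFs; the inverse-CV classification uses raw
  residue values of each region. Both are explicit flags
  (`inside_outside_values(..., granularity=)`) because the two conventions
  answer slightly different questions.
* **MANOVA** is computed from the eigenvalues of $W^{-1}B$ with the
  standard $F$ approximations; a condition-number guard ($\kappa > 10^{12}$)
  turns singular pooled covariances into an actionable error pointing at the
  correlation filter. With two groups there is one nonzero eigenvalue and
  all four $F$ approximations coincide — asserted numerically in the tests.
* **Normality test**: Shapiro–Wilk per group. The original workflow used
  visual Q-Q plots; automation needs a numeric criterion, and Shapiro–Wilk
  is the standard omnibus choice at these sample sizes (groups above 5000
  observations are deterministically thinned to the test's limit).
* **Sequence identity** is matches / alignment-length under a global
  alignment with match 1, mismatch 0, per-gap penalty 1 (computed with
  Biostrings, checked against a hand-rolled Needleman–Wunsch oracle). The
  redundancy step is usually delegated to CD-HIT; an explicit deterministic
  rule is required for reproducibility, so ties join the earliest
  representative and sequences are visited longest-first.
* **Indexing** is 1-based inclusive throughout — R's native convention and
  the one used in reports; no 0-based internal layer was worth the
  translation hazard.
* **Reliability** has two denominators in circulation (residue presence vs
  helical membership), so profiles report both `occupancy_pct` and
  `helical_pct` rather than choosing.

## Design choices where the design was open

* The four MANOVA statistics are not named in the original description
  ("the four applied MANOVA tests"); Wilks, Pillai, Hotelling–Lawley and
  Roy are the canonical four and are what any standard MANOVA
  implementation reports.
* The MANOVA observation unit is the individual residue (inside vs outside
  groups), since the test needs per-observation vectors; per-position means
  would discard the within-position variance.
* Filters run normality-first, correlation-second, matching the order the
  filtering recipe is stated in; both are idempotent, so the order only
  affects which member of a correlated non-normal pair is blamed in the
  report.
* Pipeline stage order is class filter → redundancy → consensus → group by
  length → align → statistics. Whether redundancy removal precedes class
  filtering is not specified anywhere; this order follows the stated
  step sequence of the original workflow.
* The descriptor-usage trend across helix sizes (retained-descriptor count
  shrinking with size) is reproduced qualitatively by a sweep in which
  larger sizes contribute more observations: the normality filter's power
  grows with sample size, so mildly heavy-tailed descriptors survive small
  ensembles and fail large ones. That is the mechanism the test asserts —
  a monotone non-increase of the mean retained count.

## Limitations

* Real descriptor computation (including distance- and surface-weighted
  neighbour averages) is upstream and out of scope; the package consumes
  tables.
* Dataset-scale published figures (census over 69 real descriptors,
  MANOVA coverage percentages across all helix sizes) depend on database
  snapshots and are not reproducible at desk scale; the package reproduces
  the printed *accounting* exactly and the *statistical behaviour* on
  synthetic cohorts.
* The asymptotic KS p-value is conservative for very small samples; an
  exact variant is used only as a test oracle.
* No multiple-testing correction is applied across placements or
  descriptors — deliberately, since the original analysis reports raw
  p-values binned at fixed thresholds.
* β-strands and turns are not implemented; the helix machinery (run
  extraction, consensus, alignment) is code-agnostic enough to host them
  later via the `helix_code` arguments.
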