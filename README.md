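# helixenv

Statistical characterization of the **nanoenvironment of α-helices** in
protein chains. Every α-helix lives in a neighbourhood — the helix span plus
the residues immediately before its N-terminus and after its C-terminus —
and per-residue structural and physicochemical descriptors (hydrogen-bond
contact counts, electrostatic potentials, dihedral angles, packing
densities, …) carry a detectable "signal" that distinguishes this
neighbourhood from the rest of the chain. helixenv implements the full
detection pipeline for users of per-residue descriptor tables (e.g.
STING-style databases): structural bioinformaticians validating
secondary-structure assignments, and anyone building quality checks for
predicted or low-resolution structures.

## What it computes

1. **Datamarts** — helices are extracted from up to three assigner
   annotations (PDB, DSSP, Stride roles) and kept only when the assigners
   named by a *consensus mode* agree on both termini; chains are classified
   *exclusive* (one helix) or *nonexclusive*, sequence redundancy is removed
   by greedy identity clustering (0.95 / 0.70 / 0.50 levels), and helices
   are tabulated per length.
2. **Positional alignment** — all helices of one length L are stacked with
   ±32-residue flanks (64 + L positions); flank cells beyond the chain are
   gaps, flank residues inside *other* helices are helix-marked.
3. **Profiles** — per position: mean, SD, SEM, occupancy% and helical%
   (reliability), amino-acid logo frequencies, inside/outside ECDFs.
4. **Univariate signal** — pooled-variance Student t,

   t = (x̄₁ − x̄₂) / (S_{x₁x₂} √(1/n₁ + 1/n₂)),  df = n₁ + n₂ − 2,

   and the two-sample Kolmogorov–Smirnov statistic
   Dₙ = supₓ |F₁(x) − F₂(x)|, driven across the alignment by a sliding
   window (window vs everything outside it, every placement, window sizes
   1…2L); plus inverse coefficient-of-variation classification
   (|mean/SD inside − mean/SD outside| < 0.1 none, ≤ 1 moderate, > 1 strong).
5. **Multivariate signal** — descriptors filtered by per-group Shapiro–Wilk
   normality (α = 0.05) and pairwise correlation (|r| ≥ 0.9 greedily
   removed), then a two-group MANOVA (Wilks, Pillai, Hotelling–Lawley, Roy)
   of inside vs outside residues; descriptor-usage ranking across helix
   sizes; and `assess_region()`, which flags a candidate region as a
   helix-like nanoenvironment when the minimum MANOVA p ≤ 1e-6.
6. **Synthetic cohorts** — a seeded generator with controlled inside-helix
   effect sizes, assigner disagreement, inter-descriptor correlation,
   heavy-tailed noise and near-duplicate sequences, so the whole pipeline is
   testable without any database.

## Worked example

```r
library(helixenv)

cfg <- synthetic_config(n_chains = 30, helix_length = 12, n_descriptors = 4,
                        inside_effect = 1, seed = 42)
cohort <- generate_cohort(cfg)
res <- run_pipeline(cohort, run_config(test = "t", seed = 42))

res$datamart
#> datamart DM: 30 helices (30 exclusive, 0 nonexclusive), 1 lengths

scan <- res$lengths[["12"]]$scans[["D1"]]
attr(scan, "argmin"); min(scan$p_value, na.rm = TRUE)
#> [1] 33
#> [1] 1.104681e-30

res$lengths[["12"]]$census
#> signal census: 2 strong, 2 moderate, 0 none, 0 undefined (100.0% signal-bearing)

res$lengths[["12"]]$manova
#> MANOVA: groups of 1920 / 360 on 3 descriptors
#>         statistic     value approx_F df1  df2       p_value
#>            Pillai 0.2753242 288.2383   3 2276 1.395311e-158
#>             Wilks 0.7246758 288.2383   3 2276 1.395311e-158
#>  Hotelling-Lawley 0.3799275 288.2383   3 2276 1.395311e-158
#>               Roy 0.3799275 288.2383   3 2276 1.395311e-158
```

Reading this: the aligned ensemble has 64 + 12 = 76 positions with the helix
at columns 33–44, so an argmin placement of 33 means the L-sized sliding
window localizes the helix exactly; the t-test p there (~1e-30) says the
in-window per-position means are far from the outside ones. The census
classifies all four descriptors as signal-bearing (a 1-SD injected effect),
and the four MANOVA statistics — identical F by construction for two
groups — reject the "no nanoenvironment difference" null overwhelmingly.
One descriptor of the four was dropped by the correlation/normality filters
before MANOVA.

A command-line front end mirrors the stages:

```sh
exec/helixenv simulate --chains 30 --length 12 --seed 42 --out cohort/
exec/helixenv run --in cohort/ --out results/
exec/helixenv assess --in cohort/ --chain SYN0001 --region 30:41
```

## Vignette

`vignettes/helix-nanoenvironment.Rmd` documents the model, every tunable
parameter, what the synthetic generator does and does not emulate, the
numerical choices, and known limitations.
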