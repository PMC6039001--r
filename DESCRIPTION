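Package: helixenv
Title: Statistical Characterization of Alpha-Helix Nanoenvironments
Version: 0.1.0
Authors@R:
    person("Helixenv", "Developers", email = "helixenv@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and characterize the nanoenvironment of
    alpha-helices in protein chains from per-residue structural and
    physicochemical descriptor tables.  Same-length helices defined by a
    multi-assigner consensus (PDB, DSSP, Stride) are positionally aligned
    with 32-residue flanks; per-position descriptor profiles, sliding-window
    Student t and Kolmogorov-Smirnov scans, inverse coefficient-of-variation
    signal classification, and descriptor-filtered MANOVA then quantify how
    the helix span differs from its surroundings.  A seeded synthetic-cohort
    generator with controlled effect sizes, assigner disagreement and
    sequence redundancy makes the full pipeline testable without any
    external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
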