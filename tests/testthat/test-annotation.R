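test_that("extract_helices decomposes annotation runs", {
  expect_identical(nrow(extract_helices("cccc")), 0L)
  h <- extract_helices("cHHHHHc")
  expect_identical(h$start, 2L)
  expect_identical(h$end, 6L)
  expect_identical(h$length, 5L)
  h3 <- extract_helices("HHcHHHcH")
  expect_identical(h3$length, c(2L, 3L, 1L))
  expect_identical(h3$start, c(1L, 4L, 8L))
})

test_that("extracted helices repaint to the source annotation", {
  set.seed(7)
  for (i in 1:25) {
    ann <- paste(sample(c("H", "c"), 40, replace = TRUE,
                        prob = c(0.4, 0.6)), collapse = "")
    hel <- extract_helices(ann)
    repaint <- rep("c", nchar(ann))
    for (j in seq_len(nrow(hel)))
      repaint[hel$start[j]:hel$end[j]] <- "H"
    expect_identical(paste(repaint, collapse = ""), ann)
  }
})

test_that("consensus keeps helices only when all assigners agree on both termini", {
  base <- paste(rep("c", 30), collapse = "")
  paint <- function(s, e) {
    x <- strsplit(base, "")[[1]]; x[s:e] <- "H"; paste(x, collapse = "")
  }
  rec <- list(chain_id = "X",
              annotations = list(PDB = paint(10, 21), DSSP = paint(10, 21),
                                 Stride = paint(10, 20)))
  kept <- consensus_helices(rec, "pdb-dssp")
  expect_identical(kept$start, 10L)
  expect_identical(kept$end, 21L)
  expect_identical(nrow(consensus_helices(rec, "pdb-dssp-stride")), 0L)
  # all three agree
  rec2 <- list(chain_id = "Y", annotations = list(
    PDB = paint(5, 16), DSSP = paint(5, 16), Stride = paint(5, 16)))
  expect_identical(nrow(consensus_helices(rec2, "pdb-dssp-stride")), 1L)
  # all disagree pairwise -> empty for every pairwise mode
  rec3 <- list(chain_id = "Z", annotations = list(
    PDB = paint(5, 16), DSSP = paint(6, 17), Stride = paint(7, 18)))
  for (m in c("pdb-dssp", "pdb-stride", "dssp-stride", "pdb-dssp-stride"))
    expect_identical(nrow(consensus_helices(rec3, m)), 0L)
  expect_error(consensus_helices(list(chain_id = "W",
                                      annotations = list(PDB = base)),
                                 "pdb-dssp"), "lacks annotations")
})

test_that("all-three consensus is nested in every pairwise consensus", {
  for (s in 1:10) {
    cfg <- synthetic_config(n_chains = 4, helices_per_chain = 2,
                            chain_length_range = c(80, 100),
                            assigner_disagreement_p = 0.5, seed = s)
    cohort <- generate_cohort(cfg)
    for (ch in cohort$chains) {
      all3 <- consensus_helices(ch, "pdb-dssp-stride")
      key3 <- paste(all3$start, all3$end)
      for (m in c("pdb-dssp", "pdb-stride", "dssp-stride")) {
        pk <- consensus_helices(ch, m)
        expect_true(all(key3 %in% paste(pk$start, pk$end)))
      }
    }
  }
})

test_that("exclusivity classification counts helices", {
  expect_identical(classify_exclusivity(extract_helices("cHHHHHc")),
                   "exclusive")
  expect_identical(classify_exclusivity(extract_helices("HHHHHcHHHHH")),
                   "nonexclusive")
  expect_identical(classify_exclusivity(extract_helices("cccc")),
                   "excluded")
})

test_that("DSSP write/parse round-trips a 3-chain fixture", {
  chains <- list(
    list(chain_id = "A", sequence = "MKVLITAG", annotation = "ccHHHHcc"),
    list(chain_id = "B", sequence = "GHHHHHHY", annotation = "cHHHHHHc"),
    list(chain_id = "C", sequence = "AAAA", annotation = "cccc"))
  f <- withr::local_tempfile(fileext = ".dssp")
  write_dssp(chains, f)
  parsed <- parse_dssp(f)
  expect_identical(length(parsed), 3L)
  for (ch in chains) {
    got <- parsed[[ch$chain_id]]
    expect_identical(got$sequence, ch$sequence)
    expect_identical(got$annotation, ch$annotation)
    expect_identical(nchar(got$annotation), nchar(got$sequence))
  }
})

test_that("DSSP parser flags malformed input with its line number", {
  f <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("HEADER junk"), f)
  expect_error(parse_dssp(f), "RESIDUE")
  writeLines(c("  #  RESIDUE AA STRUCTURE",
               "  bad line that is long enough to parse  "), f)
  expect_error(parse_dssp(f), ":2:")
})

test_that("G and I helix codes are not alpha-helix by default", {
  f <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("  #  RESIDUE AA STRUCTURE",
               "    1    1 A A  G",
               "    2    2 A A  H",
               "    3    3 A A  I",
               "    4    4 A A   "), f)
  expect_identical(parse_dssp(f)[["A"]]$annotation, "cHcc")
  expect_identical(parse_dssp(f, helix_codes = c("H", "G", "I"))[["A"]]$annotation,
                   "HHHc")
})

test_that("sequence identity matches the Needleman-Wunsch oracle", {
  expect_equal(seq_identity("AAAAAAAAAA", "AAAAAACCCC"), 0.6)
  expect_equal(seq_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  set.seed(99)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "D", "E"), sample(4:9, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E"), sample(4:9, 1), replace = TRUE),
               collapse = "")
    expect_equal(seq_identity(a, b), nw_identity(a, b), tolerance = 1e-12,
                 info = paste(a, b))
  }
})

test_that("redundancy clustering follows the greedy threshold rule", {
  two <- c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL")
  expect_identical(length(cluster_redundancy(two, 0.95)$representatives), 1L)
  pair60 <- c(a = "AAAAAAAAAA", b = "AAAAAACCCC")   # identity 0.6
  expect_identical(length(cluster_redundancy(pair60, 0.70)$representatives),
                   2L)
  expect_identical(length(cluster_redundancy(pair60, 0.50)$representatives),
                   1L)
  # threshold 1.0 merges only exact duplicates; reps non-increasing downward
  seqs <- c(x = "ACDEFGHIKL", y = "ACDEFGHIKL", z = "ACDEFGHIKC",
            w = "MMMMMMMMMM")
  expect_identical(sort(names(cluster_redundancy(seqs, 1.0)$representatives)),
                   c("w", "x", "z"))
  n_reps <- vapply(c(0.5, 0.7, 0.95, 1.0), function(th)
    length(cluster_redundancy(seqs, th)$representatives), 0L)
  expect_true(all(diff(n_reps) >= 0))
  expect_identical(nrow(cluster_redundancy(character(), 0.9)$members), 0L)
})

test_that("datamarts count, split and stay additive", {
  cfg <- synthetic_config(n_chains = 10, helix_length = 12, seed = 5)
  cohort <- generate_cohort(cfg)
  dm <- build_datamart(cohort$chains)
  expect_identical(dm$counts$length, 12L)
  expect_identical(dm$counts$n_exclusive, 10L)
  expect_identical(dm$counts$n_nonexclusive, 0L)
  # mixed multiplicity: additivity at every length
  cfg2 <- synthetic_config(n_chains = 12, helices_per_chain = 1:3,
                           chain_length_range = c(80, 120), seed = 6)
  dm2 <- build_datamart(generate_cohort(cfg2)$chains)
  expect_identical(dm2$counts$n_total,
                   dm2$counts$n_exclusive + dm2$counts$n_nonexclusive)
  # redundancy clustering can only shrink counts
  cfg3 <- synthetic_config(n_chains = 10, duplicate_fraction = 0.4, seed = 7)
  ch3 <- generate_cohort(cfg3)$chains
  before <- datamart_totals(build_datamart(ch3)$counts)
  after <- datamart_totals(build_datamart(ch3, redundancy_level = 0.95)$counts)
  expect_lte(after["total"], before["total"])
  # class filter drops the other class
  dm_none <- build_datamart(ch3, class_filter = "alpha-beta")
  expect_identical(nrow(dm_none$instances), 0L)
})
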