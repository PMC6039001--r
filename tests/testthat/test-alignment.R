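make_L5_ensemble <- function() {
  # chains 1-3: helix starts at residue 2 (position -1 occupied);
  # chains 4-5: helix starts at residue 1 (pre-flank all gaps)
  ann <- c(rep("cHHHHHcccc", 3), rep("HHHHHccccc", 2))
  k <- 0
  cohort <- make_manual_cohort(as.list(ann))
  # give chain k the constant value k so position -1 sees {1,2,3}
  cohort$descriptors$D1 <- as.numeric(factor(cohort$descriptors$chain_id))
  inst <- do.call(rbind, lapply(names(cohort$chains), function(cid)
    extract_helices(cohort$chains[[cid]]$annotations[["PDB"]], cid)))
  align_ensemble(inst, cohort$descriptors, cohort$chains)
}

test_that("ensemble geometry: 64 + L columns, gaps and spans", {
  cfg <- synthetic_config(n_chains = 5, helix_length = 12, seed = 2)
  cohort <- generate_cohort(cfg)
  dm <- build_datamart(cohort$chains)
  ens <- align_ensemble(dm$instances, cohort$descriptors, cohort$chains)
  expect_identical(length(ens$positions), 64L + 12L)
  hc <- 33:44
  expect_true(all(!ens$gap[, hc]))
  expect_true(all(ens$helical[, hc]))
  # positions adjacent to the span are never helix-marked when occupied
  adj <- c(32L, 45L)
  expect_true(all(!ens$helical[, adj][!ens$gap[, adj]]))
  ens5 <- make_L5_ensemble()
  expect_identical(length(ens5$positions), 69L)
})

test_that("helix at chain start makes the whole pre-flank gaps", {
  cohort <- make_manual_cohort(list("HHHHHHHHHHHHcccc"))
  inst <- extract_helices("HHHHHHHHHHHHcccc", "CH01")
  ens <- align_ensemble(inst, cohort$descriptors, cohort$chains)
  expect_true(all(ens$gap[1, 1:32]))
  expect_true(all(!ens$gap[1, 33:44]))
})

test_that("a second helix downstream is helix-marked in the flank", {
  # helix 1 at 3..14, helix 2 at 18..29: post-flank positions 4..15 after C-term
  ann <- "ccHHHHHHHHHHHHcccHHHHHHHHHHHHcc"
  cohort <- make_manual_cohort(list(ann))
  inst <- extract_helices(ann, "CH01")[1, ]
  ens <- align_ensemble(inst, cohort$descriptors, cohort$chains)
  post <- 44 + (18:29 - 14)   # columns of residues 18..29
  expect_true(all(ens$helical[1, post]))
  expect_true(all(!ens$helical[1, 45:(post[1] - 1)]))
})

test_that("alignment errors name the problem", {
  cohort <- make_manual_cohort(list("cHHHHHc", "cHHHHHHc"))
  inst <- rbind(extract_helices("cHHHHHc", "CH01"),
                extract_helices("cHHHHHHc", "CH02"))
  expect_error(align_ensemble(inst, cohort$descriptors, cohort$chains),
               "mixed helix lengths")
  one <- extract_helices("cHHHHHc", "CH01")
  broken <- cohort$descriptors[-2, ]   # drop residue 2 of CH01
  expect_error(align_ensemble(one, broken, cohort$chains),
               "chain 'CH01', residue 2")
})

test_that("profiles: arithmetic, gaps and occupancy", {
  ens <- make_L5_ensemble()
  pr <- position_profile(ens, "D1")
  # position -1 (column 32) sees chains 1-3 only: values {1,2,3}
  expect_equal(pr$mean[32], 2)
  expect_equal(pr$sd[32], 1)
  expect_equal(pr$sem[32], 1 / sqrt(3))
  expect_equal(pr$occupancy_pct[32], 60)
  # helix span fully occupied and fully helical
  expect_true(all(pr$occupancy_pct[33:37] == 100))
  expect_true(all(pr$helical_pct[33:37] == 100))
  expect_true(all(pr$sem <= pr$sd + 1e-12, na.rm = TRUE))
  # n < 2 -> NA sd, never zero
  expect_true(all(is.na(pr$sd[pr$n < 2])))
  expect_error(position_profile(ens, "nope"), "unknown descriptor")
})

test_that("constant ensemble has zero spread; shifting shifts only means", {
  cohort <- make_manual_cohort(list("ccccHHHHHcccc"),
                               value_fun = function(i) rep(7, length(i)))
  inst <- extract_helices("ccccHHHHHcccc", "CH01")
  ens <- align_ensemble(rbind(inst, inst), cohort$descriptors, cohort$chains)
  pr <- position_profile(ens, "D1")
  occ <- pr$n > 0
  expect_true(all(pr$mean[occ] == 7))
  expect_true(all(pr$sd[occ] == 0))
  ens2 <- ens
  ens2$values <- ens2$values + 3
  pr2 <- position_profile(ens2, "D1")
  expect_equal(pr2$mean[occ], pr$mean[occ] + 3)
  expect_equal(pr2$sd, pr$sd)
  expect_equal(pr2$occupancy_pct, pr$occupancy_pct)
})

test_that("logo matrix normalizes over non-gap residues", {
  ens <- make_L5_ensemble()
  lg <- logo_matrix(ens)
  sums <- rowSums(lg)
  occ <- colSums(!ens$gap) > 0
  expect_true(all(abs(sums[occ] - 1) < 1e-12))
  expect_true(all(sums[!occ] == 0))
  expect_equal(unname(lg[33, "A"]), 1)   # all manual sequences are poly-A
  # mixed residues at one position
  ens$residues[, 33] <- c("A", "A", "C", "G", "A")
  lg2 <- logo_matrix(ens)
  expect_equal(unname(lg2[33, c("A", "C", "G")]), c(0.6, 0.2, 0.2))
})

test_that("ECDF obeys its definition", {
  tbl <- ecdf_table(c(1, 2, 3))
  expect_equal(ecdf_eval(tbl, 2), 2 / 3)
  expect_equal(ecdf_eval(tbl, 0.5), 0)
  expect_equal(ecdf_eval(tbl, 3), 1)
  expect_true(all(diff(tbl$Fn) >= 0))
  # ties: Fn at a repeated value counts all occurrences
  t2 <- ecdf_table(c(5, 5, 6))
  expect_equal(ecdf_eval(t2, 5), 2 / 3)
  # agreement with stats::ecdf on random data
  set.seed(31)
  x <- rnorm(40)
  t3 <- ecdf_table(x)
  expect_equal(ecdf_eval(t3, 0.3), unname(stats::ecdf(x)(0.3)))
  expect_error(ecdf_table(numeric()), "at least one")
})

test_that("inside/outside ECDF pair detects sameness and shift", {
  ens <- make_L5_ensemble()
  # identical constant samples -> identical curves, max gap 0
  cohort <- make_manual_cohort(list("ccccHHHHHcccc"),
                               value_fun = function(i) rep(1, length(i)))
  inst <- extract_helices("ccccHHHHHcccc", "CH01")
  ce <- align_ensemble(rbind(inst, inst), cohort$descriptors, cohort$chains)
  expect_equal(ecdf_pair(ce, "D1")$max_gap, 0)
  # strong shift separates the curves
  cfg <- synthetic_config(n_chains = 30, inside_effect = 2, seed = 17)
  co <- generate_cohort(cfg)
  dm <- build_datamart(co$chains)
  se <- align_ensemble(dm$instances, co$descriptors, co$chains)
  expect_gt(ecdf_pair(se, "D1")$max_gap, 0.5)
})

test_that("profile recovers the injected inside shift within 3 SEM", {
  cfg <- synthetic_config(n_chains = 120, helix_length = 12,
                          inside_effect = 1, seed = 19)
  co <- generate_cohort(cfg)
  dm <- build_datamart(co$chains)
  ens <- align_ensemble(dm$instances, co$descriptors, co$chains)
  pr <- position_profile(ens, "D1")
  hc <- 33:44
  est <- mean(pr$mean[hc]) - mean(pr$mean[-hc], na.rm = TRUE)
  sem <- sqrt(mean(pr$sem[hc]^2) / length(hc) +
                mean(pr$sem[-hc]^2, na.rm = TRUE) / sum(!is.na(pr$sem[-hc])))
  expect_lt(abs(est - 1), 3 * sem)
})

test_that("single-helix cohorts have occupancy falling toward flank ends", {
  cfg <- synthetic_config(n_chains = 40, helix_length = 12,
                          chain_length_range = c(40, 70), seed = 23)
  co <- generate_cohort(cfg)
  dm <- build_datamart(co$chains)
  ens <- align_ensemble(dm$instances, co$descriptors, co$chains)
  occ <- position_profile(ens, "D1")$occupancy_pct
  expect_true(all(diff(occ[1:32]) >= 0))        # rising into the helix
  expect_true(all(diff(occ[45:76]) <= 0))       # falling away from it
})
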