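test_that("Tanimoto on bitsets: worked values, identity, symmetry, range", {
  expect_equal(tanimoto(fingerprint("a", 1:3), fingerprint("b", 2:4)), 0.5)
  expect_equal(tanimoto(fingerprint("a", 1:5), fingerprint("b", 1:5)), 1)
  expect_equal(tanimoto(fingerprint("a", 1:5), fingerprint("b", 6:10)), 0)
  expect_equal(tanimoto(fingerprint("a", integer(0)), fingerprint("b", integer(0))), 0)
  expect_error(tanimoto(fingerprint("a", 1, n_bits = 1024),
                        fingerprint("b", 1, n_bits = 2048)), "mismatch")
  withr::local_seed(19)
  for (i in 1:15) {
    x <- fingerprint("x", sample(0:255, 40))
    y <- fingerprint("y", sample(0:255, 40))
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0); expect_lte(tanimoto(x, y), 1)
  }
})

test_that("Tanimoto distance (1 - Tc) satisfies the triangle inequality", {
  withr::local_seed(23)
  for (i in 1:25) {
    f <- lapply(1:3, function(j) fingerprint(j, sample(0:127, sample(10:50, 1))))
    dab <- 1 - tanimoto(f[[1]], f[[2]])
    dbc <- 1 - tanimoto(f[[2]], f[[3]])
    dac <- 1 - tanimoto(f[[1]], f[[3]])
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("greedy diversity filtering keeps all pairwise Tc below the ceiling", {
  A <- fingerprint("m1", 1:10)
  B <- fingerprint("m2", 1:7)          # Tc(A,B) = 0.7
  C <- fingerprint("m3", c(1, 2, 31:38))  # Tc to A and B well below 0.6
  kept <- diversity_filter(list(A, B, C), tc_max = 0.6)
  expect_equal(vapply(kept, `[[`, character(1), "molecule_id"), c("m1", "m3"))

  all_same <- replicate(5, fingerprint("x", 1:20), simplify = FALSE)
  expect_length(diversity_filter(all_same), 1)

  disjoint <- lapply(1:5, function(i) fingerprint(i, (i * 30):(i * 30 + 9)))
  expect_length(diversity_filter(disjoint), 5)

  withr::local_seed(29)
  fps <- lapply(1:12, function(i) fingerprint(i, sample(0:99, 30)))
  kept <- diversity_filter(fps, tc_max = 0.4)
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1)) expect_lt(tanimoto(kept[[i]], kept[[j]]), 0.4)
  }
})

test_that("sigma-Tc sums strictly-above-threshold similarities", {
  # references constructed as query subsets give exact Tc 0.2, 0.35, 0.55
  q <- fingerprint("q", 0:59)
  refs <- list(fingerprint("r1", 0:11),   # 12/60 = 0.2
               fingerprint("r2", 0:20),   # 21/60 = 0.35
               fingerprint("r3", 0:32))   # 33/60 = 0.55
  prof <- sum_tc(q, refs)
  expect_equal(prof$sum_tc, 0.90)
  expect_equal(prof$n_contributing, 2)
  # boundary: Tc exactly 0.3 is excluded
  expect_equal(sum_tc(q, list(fingerprint("r", 0:17)))$sum_tc, 0)  # 18/60 = 0.3
  expect_equal(sum_tc(q, list(fingerprint("r", 0:5)))$sum_tc, 0)
  # self-comparison excluded with a warning
  expect_warning(selfp <- sum_tc(q, c(refs, list(fingerprint("q", 0:59)))),
                 "among references")
  expect_equal(selfp$sum_tc, 0.90)
  # monotone non-decreasing as references accumulate
  expect_gte(sum_tc(q, refs)$sum_tc, sum_tc(q, refs[1:2])$sum_tc)
  # rank/percentile against a reference distribution
  prof2 <- sum_tc(q, refs, ref_sum_tc = c(5, 2, 0.3, 0.1))
  expect_equal(prof2$rank, 3L)
  expect_equal(prof2$percentile, 50)
})

test_that("ligand efficiency is the per-heavy-atom binding free energy", {
  expect_equal(ligand_efficiency(1e-6, 10), 0.822)
  expect_equal(ligand_efficiency(1, 25), 0)
  expect_equal(ligand_efficiency(1e-7, 22), 1.37 * 7 / 22)  # ~0.44
  kds <- 10^seq(-9, -3, by = 1)
  les <- ligand_efficiency(kds, 20)
  expect_true(all(diff(les) < 0))
  expect_true(all(diff(ligand_efficiency(1e-6, 10:30)) < 0))
  expect_error(ligand_efficiency(0, 10), "positive")
})

test_that("Lipinski curation keeps rule-of-five compliant compounds", {
  props <- data.frame(
    molecule_id = c("hit1", "big", "greasy", "edge", "holey"),
    MW = c(315, 600, 400, 500, 450),
    logP = c(3.79, 2, 6.2, 5.0, 1),
    HBD = c(2, 1, 1, 5, 6),
    HBA = c(4, 3, 5, 10, 4))
  kept <- lipinski_filter(props)
  expect_setequal(kept$molecule_id, c("hit1", "edge"))  # boundaries inclusive
  props$MW[1] <- NA
  expect_warning(kept2 <- lipinski_filter(props), "missing properties")
  expect_setequal(kept2$molecule_id, "edge")
})

test_that("circular fingerprints from SMILES identify equal molecules", {
  f1 <- fingerprint_from_smiles("c1ccccc1")
  f2 <- fingerprint_from_smiles("c1ccccc1")
  expect_equal(tanimoto(f1, f2), 1)
  # kekulized spelling of the same molecule
  f3 <- fingerprint_from_smiles("C1=CC=CC=C1")
  expect_equal(tanimoto(f1, f3), 1)
  # shared small environments, distinct larger ones
  eth <- fingerprint_from_smiles("CC")
  hex <- fingerprint_from_smiles("CCCCCC")
  tc <- tanimoto(eth, hex)
  expect_gt(tc, 0); expect_lt(tc, 1)
  expect_error(fingerprint_from_smiles(""), "non-empty")
})
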