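test_that("ROC vertices follow the ranked staircase with diagonal tie blocks", {
  lib <- scored_library(paste0("c", 1:4), c(1, 3, 2, 4),
                        c("active", "active", "decoy", "decoy"))
  roc <- build_roc(lib)
  expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))

  # a fully tied library collapses to the single diagonal segment
  tied <- scored_library(paste0("t", 1:6), rep(1, 6),
                         rep(c("active", "decoy"), 3))
  expect_equal(as.data.frame(build_roc(tied)),
               data.frame(fpr = c(0, 1), tpr = c(0, 1)))

  perf <- scored_library(paste0("p", 1:8), 1:8,
                         rep(c("active", "decoy"), c(3, 5)))
  rp <- build_roc(perf)
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  worst <- scored_library(paste0("w", 1:8), 1:8,
                          rep(c("decoy", "active"), c(5, 3)))
  rw <- build_roc(worst)
  expect_true(any(rw$fpr == 1 & rw$tpr == 0))

  expect_error(build_roc(scored_library("a", 1, "active")), "at least one")
})

test_that("ROC vertices are invariant under strictly monotone score transforms", {
  withr::local_seed(11)
  for (i in 1:5) {
    lib <- random_library(8, 25, round_digits = 1)
    r0 <- build_roc(lib)
    lib2 <- lib
    lib2$score <- exp(3 * lib$score) - 2
    expect_equal(as.data.frame(build_roc(lib2)), as.data.frame(r0))
  }
})

test_that("trapezoidal AUC matches brute-force pair counting with half ties", {
  lib <- scored_library(paste0("c", 1:4), c(1, 3, 2, 4),
                        c("active", "active", "decoy", "decoy"))
  expect_equal(auc(build_roc(lib)), 75)
  withr::local_seed(7)
  for (i in 1:20) {
    lib <- random_library(sample(2:30, 1), sample(2:60, 1),
                          round_digits = sample(c(0, 1, Inf), 1))
    expect_equal(auc(build_roc(lib)), auc_paircount(lib), tolerance = 1e-12)
  }
})

test_that("LogAUC attains its analytic bounds and stays inside them", {
  perf <- scored_library(paste0("c", 1:110), c(1:10, 101:200),
                         rep(c("active", "decoy"), c(10, 100)))
  expect_equal(logauc(build_roc(perf)), 85.5)
  inv <- scored_library(paste0("c", 1:110), c(101:110, 1:100),
                        rep(c("active", "decoy"), c(10, 100)))
  expect_equal(logauc(build_roc(inv)), -14.5)
  withr::local_seed(21)
  for (i in 1:30) {
    lib <- random_library(sample(2:20, 1), sample(5:80, 1))
    la <- logauc(build_roc(lib))
    expect_gte(la, -14.5); expect_lte(la, 85.5)
    a <- auc(build_roc(lib))
    expect_gte(a, 0); expect_lte(a, 100)
  }
})

test_that("moving a decoy below an adjacent active never decreases LogAUC", {
  withr::local_seed(31)
  for (i in 1:10) {
    lib <- random_library(6, 20)
    ord <- order(lib$score)
    lab <- lib$label[ord]
    k <- which(lab[-length(lab)] == "decoy" & lab[-1] == "active")
    if (!length(k)) next
    k <- k[1]
    lib2 <- lib
    i1 <- ord[k]; i2 <- ord[k + 1]
    lib2$score[c(i1, i2)] <- lib$score[c(i2, i1)]
    expect_gte(logauc(build_roc(lib2)), logauc(build_roc(lib)))
  }
})

test_that("random labels give LogAUC near 0 and EF1 near 1 in expectation", {
  withr::local_seed(41)
  n_rep <- 60
  las <- numeric(n_rep); efs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    lib <- random_library(33, 400)
    roc <- build_roc(lib)
    las[i] <- logauc(roc)
    efs[i] <- ef(roc)
  }
  expect_lt(abs(mean(las)), 3 * stats::sd(las) / sqrt(n_rep) + 0.5)
  expect_lt(abs(mean(efs) - 1), 3 * stats::sd(efs) / sqrt(n_rep))
})

test_that("EF follows the TPR/FPR staircase reading", {
  roc <- structure(data.frame(fpr = c(0, 0.01, 1), tpr = c(0, 0.10, 1)),
                   class = c("roc_curve", "data.frame"))
  expect_equal(ef(roc, 0.01), 10)
  perf <- build_roc(scored_library(paste0("c", 1:110), c(1:10, 101:200),
                                   rep(c("active", "decoy"), c(10, 100))))
  expect_equal(ef(perf, 0.01), 100)
  expect_error(ef(perf, 0), "level")
})

test_that("ensemble ranking sorts by LogAUC with below-median pose demotion", {
  one <- data.frame(structure_id = "X", pose_success_pct = 40,
                    auc = 80, logauc = 30, ef1 = 20)
  expect_equal(rank_ensemble(one)$structure_id, "X")

  two <- data.frame(structure_id = c("2YI5-A", "2BYI-A"),
                    pose_success_pct = c(38, 38),
                    auc = c(83.0, 83.5), logauc = c(31.9, 33.5),
                    ef1 = c(27.6, 25.9))
  expect_equal(rank_ensemble(two)$structure_id[1], "2BYI-A")

  three <- data.frame(structure_id = c("A", "B", "C"),
                      pose_success_pct = c(10, 40, 45),
                      auc = c(90, 80, 70), logauc = c(50, 30, 20),
                      ef1 = c(30, 20, 10))
  rk <- rank_ensemble(three)
  expect_equal(rk$structure_id, c("B", "C", "A"))  # A demoted despite top LogAUC
  expect_true(rk$demoted[rk$structure_id == "A"])
})

test_that("top-candidate selection unions per-library top scorers", {
  a <- scored_library(sprintf("a%02d", 1:40), 1:40, rep("active", 40))
  b <- scored_library(sprintf("b%02d", 1:40), 1:40, rep("active", 40))
  expect_length(select_top_candidates(list(a, b), 30), 60)
  expect_length(select_top_candidates(list(a, a), 30), 30)
  expect_equal(select_top_candidates(list(a), 1), "a01")
  small <- scored_library("s1", 5, "active")
  expect_warning(got <- select_top_candidates(list(small), 30), "exceeds")
  expect_equal(got, "s1")
})
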