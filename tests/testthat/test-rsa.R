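test_that("true RDMs are 1 minus Pearson correlation", {
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  d <- true_rdm(x)
  expect_symmetric_zero_diag(d)
  expect_equal(d["a", "b"], 0)                     # identical up to scale
  expect_equal(d["a", "c"], 2)                     # exact negation
  # toy oracle: direct Pearson formula
  r <- sum((x[1, ] - mean(x[1, ])) * (x[3, ] - mean(x[3, ]))) /
    (sqrt(sum((x[1, ] - mean(x[1, ]))^2)) * sqrt(sum((x[3, ] - mean(x[3, ]))^2)))
  expect_equal(d["a", "c"], 1 - r)
  bad <- rbind(x, d = c(5, 5, 5, 5))
  expect_error(true_rdm(bad), "zero-variance.*d")
})

test_that("group RDMs are entrywise means over aligned subjects", {
  m1 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  g <- group_rdm(list(m1, m2))
  expect_equal(g["x", "y"], 0.3)
  expect_equal(unclass(group_rdm(list(m2, m1))), unclass(g))
  m3 <- m2; dimnames(m3) <- list(c("y", "x"), c("y", "x"))
  expect_error(group_rdm(list(m1, m3)), "ordering")
})

test_that("candidate models satisfy their categorical structure", {
  mods <- candidate_rdms()
  expect_named(mods, c("body_separate", "body_pattern1", "body_pattern2",
                       "emotion_separate", "emotion_pattern1",
                       "emotion_pattern2", "random"))
  info <- bodybubbles:::parse_conditions(design_conditions())
  for (m in mods) {
    expect_symmetric_zero_diag(m)
    expect_gte(min(m), 0)
    expect_lte(max(m), 1)
  }
  # body_separate: zero on same-part blocks, one elsewhere
  same_part <- outer(info$part, info$part, `==`)
  bs <- unclass(mods$body_separate)
  expect_true(all(bs[same_part] == 0))
  expect_true(all(bs[!same_part] == 1))
  # body_pattern1 merges whole body with torso_with_arms
  bp1 <- unclass(mods$body_pattern1)
  wb <- info$part == "whole_body"; ta <- info$part == "torso_with_arms"
  expect_true(all(bp1[outer(wb, ta, `&`)] == 0))
  # emotion_separate: same-emotion blocks zero
  es <- unclass(mods$emotion_separate)
  same_emo <- outer(info$emotion, info$emotion, `==`)
  expect_true(all(es[same_emo & !diag(12)] == 0))
  expect_true(all(es[!same_emo] == 1))
})

test_that("body_pattern2 ranks follow the three-tier part structure", {
  bp2 <- unclass(candidate_rdms()$body_pattern2) * 3
  info <- bodybubbles:::parse_conditions(design_conditions())
  parts <- unique(info$part)
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    sel <- outer(info$part == parts[i], info$part == parts[j], `&`)
    v <- unique(bp2[sel])
    expect_length(v, 1)
    vals <- c(vals, v)
  }
  # the six unordered part pairs carry the rank multiset {1,1,2,2,2,3}
  expect_equal(sort(vals), c(1, 1, 2, 2, 2, 3))
  # within-part entries are zero
  expect_true(all(bp2[outer(info$part, info$part, `==`)] == 0))
})

test_that("emotion_pattern2 refines the whole-body/torso block by emotion", {
  ep2 <- unclass(candidate_rdms()$emotion_pattern2) * 8
  info <- bodybubbles:::parse_conditions(design_conditions())
  wbta <- info$part %in% c("whole_body", "torso_with_arms")
  blk <- outer(wbta, wbta, `&`) & !diag(12)
  expect_true(all(ep2[blk] %in% 0:5))
  neut <- info$emotion == "neutral"
  worse <- blk & outer(neut, neut, `|`) & !outer(info$emotion, info$emotion, `==`)
  better <- blk & outer(info$emotion, info$emotion, `==`)
  expect_gt(min(ep2[worse]), max(ep2[better]))
  ta <- info$part == "torso_with_arms"; legs <- info$part == "legs"
  expect_true(all(ep2[outer(ta, legs, `&`)] == 6))
  wb <- info$part == "whole_body"; head <- info$part == "head"
  expect_true(all(ep2[outer(wb, head, `&`)] == 8))
})

test_that("the random model is seeded and uniform", {
  a <- candidate_rdms(seed = 1)$random
  b <- candidate_rdms(seed = 1)$random
  c2 <- candidate_rdms(seed = 2)$random
  expect_identical(a, b)
  expect_false(identical(a, c2))
})

test_that("tau_a matches exhaustive pair counting", {
  brute_tau <- function(x, y) {
    n <- length(x); s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    s / (n * (n - 1) / 2)
  }
  expect_equal(kendall_tau_a(1:5, 1:5), 1)
  expect_equal(kendall_tau_a(1:5, 5:1), -1)
  set.seed(17)
  for (i in 1:100) {
    x <- sample(10, 10, replace = TRUE)   # ties occur
    y <- rnorm(10)
    expect_equal(kendall_tau_a(x, y), brute_tau(x, y))
  }
  expect_error(kendall_tau_a(1:3, 1:4), "equal length")
})

test_that("tau_a is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(20); y <- rnorm(20)
  t0 <- kendall_tau_a(x, y)
  expect_equal(kendall_tau_a(exp(x), y), t0)
  expect_equal(kendall_tau_a(x, 3 * y - 7), t0)
  expect_equal(kendall_tau_a(x, x), 1)
})

test_that("exact signed-rank p-values match null enumeration", {
  # 12 all-positive values: the most extreme one-sided outcome
  expect_equal(relatedness_test(rep(0.3, 12) + (1:12) / 100), 2^-12)
  expect_equal(relatedness_test(rep(0, 5)), 1)
  # enumeration oracle with ties, n = 8
  set.seed(6)
  x <- round(rnorm(8), 1); x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x)); W <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  expect_equal(signed_rank_p(x, "greater"), mean(Wnull >= W))
  # exact-null symmetry: p(x) + p(-x) = 1 + P(W = w_obs)
  expect_equal(signed_rank_p(x, "greater") + signed_rank_p(-x, "greater"),
               1 + mean(Wnull == W))
})

test_that("pairwise model tests are symmetric and exact", {
  a <- c(0.5, 0.4, 0.6, 0.3, 0.45, 0.55, 0.35, 0.62, 0.41, 0.52)
  b <- a - 0.1                      # all differences positive, n = 10
  expect_equal(pairwise_model_test(a, b), 2 * 2^-10)
  expect_equal(pairwise_model_test(a, b), pairwise_model_test(b, a))
  expect_equal(pairwise_model_test(a, a), 1)
  expect_error(pairwise_model_test(a, b[-1]), "paired")
})

test_that("BH step-up flags match the by-hand procedure", {
  p <- c(0.01, 0.02, 0.04, 0.20)
  res <- fdr_correct(p, q = 0.05)
  expect_equal(unname(res$significant[, 1]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$thresholds[["q0.05"]], 0.02)
  expect_false(any(fdr_correct(rep(1, 5), 0.05)$significant))
  expect_true(all(fdr_correct(rep(1e-4, 6), 0.05)$significant))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classical MDS reproduces an exact 2-D embedding", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("c", 1:6)
  m <- mds_2d(d)
  expect_lt(sqrt(mean((dist(m$coords) - dist(pts))^2)), 1e-8)
  # sign convention: first non-zero loading of each axis is non-negative
  for (j in 1:2) {
    nz <- which(abs(m$coords[, j]) > 1e-12)[1]
    expect_gte(m$coords[nz, j], 0)
  }
  # eigenvalues equal those of the double-centered Gram matrix
  D2 <- d^2; J <- diag(6) - 1 / 6
  B <- -0.5 * J %*% D2 %*% J
  ev <- sort(eigen(B, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(sort(m$eig, decreasing = TRUE)[1:2], ev[1:2],
               tolerance = 1e-8)
})

test_that("duplicate conditions land on coincident MDS coordinates", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  m <- mds_2d(d)
  expect_lt(max(abs(m$coords[1, ] - m$coords[2, ])), 1e-8)
})

test_that("single-linkage dendrograms match the minimax-path oracle", {
  # cophenetic distance under single linkage equals the minimax path
  # (bottleneck) distance, computed here by brute-force relaxation
  set.seed(41)
  for (rep in 1:5) {
    n <- 8
    d <- matrix(runif(n * n, 0.1, 1), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    h <- rdm_dendrogram(d)
    expect_true(!is.unsorted(h$height))
    mm <- d
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
      mm[i, j] <- min(mm[i, j], max(mm[i, k], mm[k, j]))
    expect_equal(as.matrix(stats::cophenetic(h)), mm,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("well-separated blocks split at the dendrogram root", {
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1; diag(d) <- 0
  h <- rdm_dendrogram(d)
  top <- cutree(h, k = 2)
  expect_equal(length(unique(top[1:3])), 1)
  expect_equal(length(unique(top[4:6])), 1)
  expect_false(top[1] == top[4])
})

test_that("Dice overlap follows the defining formula", {
  a <- matrix(FALSE, 5, 6); b <- a
  a[1:3, 1:5] <- TRUE          # 15
  b[2:4, 1:5] <- TRUE          # 15, overlap 10
  r <- dice_overlap(a, b)
  expect_equal(r$r_overlap, 2 * 10 / 30)
  expect_equal(dice_overlap(a, a)$r_overlap, 1)
  expect_equal(dice_overlap(a, !a)$r_overlap, 0)
  expect_equal(dice_overlap(a & FALSE, b & FALSE)$r_overlap, 0)
  expect_error(dice_overlap(a, matrix(TRUE, 2, 2)), "grid")
  v <- dice_overlap(matrix(c(rep(TRUE, 30), rep(FALSE, 70))),
                    matrix(c(rep(FALSE, 15), rep(TRUE, 30), rep(FALSE, 55))))
  expect_equal(v$v1, 30); expect_equal(v$v2, 30)
  expect_equal(v$v_overlap, 15); expect_equal(v$r_overlap, 0.5)
})

test_that("noise-free simulated patterns reproduce the generating RDM exactly", {
  spec <- pattern_spec("body_pattern2", n_subjects = 2, n_voxels = 40,
                       noise_sd = 0, seed = 4)
  pats <- simulate_patterns(spec)
  mats <- pattern_matrices(pats)
  target <- 0.6 * unclass(candidate_rdms(seed = 4)$body_pattern2)
  for (m in mats) {
    d <- unclass(true_rdm(m))
    expect_lt(max(abs(d - target)), 1e-8)
  }
  # bit-identical reruns
  expect_identical(pats, simulate_patterns(spec))
})

test_that("subject-mean empirical RDMs converge to the generating model", {
  # tau_a counts model-tied pairs in its denominator, so the attainable
  # ceiling is the model's untied-pair fraction; at 5000 voxels the
  # group RDM must reach 90% of that ceiling
  spec <- pattern_spec("emotion_pattern2", n_subjects = 4, n_voxels = 5000,
                       noise_sd = 0.5, seed = 13)
  mats <- pattern_matrices(simulate_patterns(spec))
  g <- group_rdm(lapply(mats, true_rdm))
  model <- lower_tri(candidate_rdms(seed = 13)$emotion_pattern2)
  ceiling_tau <- mean(outer(model, model, `-`)[upper.tri(diag(66))] != 0)
  expect_gt(kendall_tau_a(lower_tri(g), model), 0.9 * ceiling_tau)
})

test_that("pattern simulation rejects non-PSD targets", {
  expect_error(pattern_spec("no_such_model"), "must be one of")
  expect_error(pattern_spec("body_separate", noise_sd = -1), "noise_sd")
  # the unstructured random model cannot be realized as a correlation
  # structure at this contrast
  expect_error(simulate_patterns(pattern_spec("random", n_subjects = 2,
                                              n_voxels = 30, seed = 2)),
               "lower signal_scale")
})

test_that("model comparison is invariant to condition reordering", {
  spec <- pattern_spec("emotion_pattern2", n_subjects = 6, n_voxels = 60,
                       noise_sd = 0.5, seed = 21)
  mats <- pattern_matrices(simulate_patterns(spec))
  rdms <- lapply(mats, true_rdm)
  mods <- candidate_rdms()
  cmp1 <- rsa_compare(rdms, mods)
  perm <- sample(12)
  set.seed(1)
  cmp2 <- rsa_compare(lapply(rdms, function(r) {
    structure(unclass(r)[perm, perm], class = c("rdm", "matrix"))
  }), lapply(mods, function(m) {
    structure(unclass(m)[perm, perm], class = c("rdm", "matrix"))
  }))
  expect_equal(cmp1$taus, cmp2$taus)
  expect_equal(cmp1$relatedness$p, cmp2$relatedness$p)
})

test_that("relatedness tests reject near the nominal rate under pure noise", {
  set.seed(55)
  model <- lower_tri(candidate_rdms()$body_separate)
  rej <- mean(replicate(200, {
    taus <- vapply(1:8, function(s) {
      pat <- matrix(rnorm(12 * 30), 12, 30,
                    dimnames = list(design_conditions(), NULL))
      kendall_tau_a(lower_tri(true_rdm(pat)), model)
    }, numeric(1))
    relatedness_test(taus) < 0.05
  }))
  ci <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rej, 0.05 - ci - 0.01)
  expect_lte(rej, 0.05 + ci + 0.01)
})
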