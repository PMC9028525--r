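test_that("unbiased hit rate follows Wagner's formula", {
  tab <- matrix(c(8, 4, 2, 6), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  hu <- unbiased_hit_rate(tab)
  expect_equal(unname(hu["A"]), 64 / (10 * 12))
  expect_equal(unname(hu["B"]), 36 / (10 * 8))
})

test_that("perfect responders score one, never-chosen categories zero", {
  perfect <- diag(c(5, 7, 9))
  expect_equal(unname(unbiased_hit_rate(perfect)), c(1, 1, 1))
  tab <- matrix(c(5, 5, 0, 0), 2, 2)   # column 2 never chosen
  expect_equal(unname(unbiased_hit_rate(tab))[2], 0)
  empty <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_error(unbiased_hit_rate(empty), "no presentations")
})

test_that("H_u never exceeds the raw hit rate", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(9, 5), 3, 3)
    if (any(rowSums(tab) == 0)) next
    hu <- unbiased_hit_rate(tab)
    acc <- diag(tab) / rowSums(tab)
    expect_true(all(hu <= acc + 1e-12))
    if (all(tab[upper.tri(tab) | lower.tri(tab)] == 0))
      expect_equal(unname(hu), unname(acc))
  }
})

sim_rm_data <- function(n, a, b, effect = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n), f1 = letters[1:a], f2 = LETTERS[1:b])
  d$value <- rnorm(nrow(d)) + rnorm(n)[d$subject] +
    effect * (as.integer(d$f1) - 1)
  d
}

test_that("two-level factors have Greenhouse-Geisser epsilon exactly one", {
  d <- sim_rm_data(8, 2, 3, seed = 5)
  res <- rm_anova_gg(d, dv = "value", subject = "subject",
                     factors = c("f1", "f2"))
  expect_equal(res$effects$epsilon[res$effects$effect == "f1"], 1)
  expect_true(all(res$effects$epsilon > 0 & res$effects$epsilon <= 1 + 1e-12))
  # shrinking the dfs raises the p-value whenever F exceeds 1
  big <- res$effects$F > 1
  expect_true(all(res$effects$p_gg[big] >= res$effects$p[big] - 1e-12))
})

test_that("a large planted main effect is detected after GG correction", {
  d <- sim_rm_data(20, 3, 3, effect = 5, seed = 9)
  res <- rm_anova_gg(d, dv = "value", subject = "subject",
                     factors = c("f1", "f2"))
  expect_lt(res$effects$p_gg[res$effects$effect == "f1"], 0.001)
  pw <- res$pairwise$f1
  expect_true(all(pw$p_bonferroni >= pw$p))
})

test_that("F, epsilon and corrected p match car's multivariate-model route", {
  d <- sim_rm_data(10, 3, 4, effect = 0.8, seed = 77)
  res <- rm_anova_gg(d, dv = "value", subject = "subject",
                     factors = c("f1", "f2"))
  Y <- matrix(0, 10, 12)
  for (i in seq_len(nrow(d)))
    Y[d$subject[i], (as.integer(d$f1[i]) - 1) * 4 + as.integer(d$f2[i])] <-
      d$value[i]
  idata <- expand.grid(f2 = LETTERS[1:4], f1 = letters[1:3])[, 2:1]
  mlm <- lm(Y ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~ f1 * f2, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))  # HF eps > 1 note
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  for (eff in c("f1", "f2", "f1:f2")) {
    mine <- res$effects[res$effects$effect == eff, ]
    Fcar <- ut[eff, "F value"]
    expect_equal(mine$F, unname(Fcar), tolerance = 1e-8)
    expect_equal(mine$epsilon, unname(adj[eff, "GG eps"]), tolerance = 1e-8)
    expect_equal(mine$p_gg, unname(adj[eff, "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("sums of squares match a by-hand cell-means oracle", {
  d <- sim_rm_data(3, 3, 2, effect = 1, seed = 3)
  res <- rm_anova_gg(d, dv = "value", subject = "subject",
                     factors = c("f1", "f2"))
  # defining formulas, computed with explicit loops
  cells <- tapply(d$value, list(d$subject, d$f1, d$f2), mean)
  m <- mean(cells)
  mA <- apply(cells, 2, mean); mS <- apply(cells, 1, mean)
  ssA <- 3 * 2 * sum((mA - m)^2)
  mSA <- apply(cells, c(1, 2), mean)
  ssAS <- 2 * sum((mSA - outer(mS, mA, `+`) + m)^2)
  effA <- res$effects[res$effects$effect == "f1", ]
  expect_equal(effA$ss, ssA)
  expect_equal(effA$F, (ssA / 2) / (ssAS / 4))
})

test_that("GG-corrected type-I error stays near the nominal level", {
  set.seed(2024)
  rej <- mean(replicate(500, {
    Y <- matrix(rnorm(15 * 3), 15, 3) + rnorm(15)
    bodybubbles::rm_anova1(Y)$p_gg < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("simple effects run one-way RM-ANOVAs per stratum", {
  d <- sim_rm_data(10, 3, 2, effect = 3, seed = 44)
  se <- simple_effects(d, dv = "value", subject = "subject",
                       within = "f1", at = "f2")
  expect_named(se, c("A", "B"))
  for (lv in se) {
    expect_lt(lv$anova$p_gg, 0.01)
    expect_equal(nrow(lv$pairwise), 3)
  }
})
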