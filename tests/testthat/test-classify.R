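test_that("accumulation matches a brute-force per-pixel loop", {
  trials <- toy_trials(n = 10)
  acc <- accumulate(trials)
  # independent oracle: naive summation loops
  dims <- dim(trials[[1]]$planes[[1]])
  for (k in 1:2) {
    cs <- es <- matrix(0, dims[1], dims[2])
    for (tr in trials) {
      for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
        if (tr$correct) cs[r, c] <- cs[r, c] + tr$planes[[k]][r, c]
        else es[r, c] <- es[r, c] + tr$planes[[k]][r, c]
      }
    }
    expect_equal(acc$correct_sum[[k]], cs)
    expect_equal(acc$error_sum[[k]], es)
  }
  expect_equal(acc$n_correct + acc$n_error, 10)
})

test_that("accumulation is invariant to trial order", {
  trials <- toy_trials(n = 8)
  a <- accumulate(trials)
  b <- accumulate(trials[sample(8)])
  expect_equal(a$correct_sum, b$correct_sum)
  expect_equal(a$error_sum, b$error_sum)
})

test_that("a single correct trial accumulates only into the correct sums", {
  tr <- toy_trials(n = 1)
  tr[[1]]$correct <- TRUE
  acc <- accumulate(tr)
  expect_equal(acc$correct_sum[[1]], tr[[1]]$planes[[1]])
  expect_true(all(acc$error_sum[[1]] == 0))
})

test_that("proportion images are correct/(correct+error) with NA when unsampled", {
  cs <- list(matrix(c(3, 1, 0, 2), 2, 2))
  es <- list(matrix(c(1, 1, 0, 0), 2, 2))
  acc <- bodybubbles:::new_accumulator(cs, es, 1L, 1L)
  p <- proportion_image(acc)$planes[[1]]
  expect_equal(p[1, 1], 0.75)              # 3 / (3 + 1)
  expect_equal(p[2, 1], 0.5)               # symmetric sums
  expect_true(is.na(p[1, 2]))              # never sampled
  expect_equal(p[2, 2], 1)                 # zero error sum
})

test_that("smoothed z-planes are standardized; constants map to zero", {
  const <- matrix(0.6, 40, 30)
  z0 <- smooth_z(const, sigma_px = 3)
  expect_true(all(z0$planes[[1]] == 0))
  set.seed(4)
  p <- matrix(runif(60 * 50), 60, 50)
  p[sample(3000, 100)] <- NA
  z <- smooth_z(p, sigma_px = 4)
  v <- z$planes[[1]][z$defined[[1]]]
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sd(v) - 1), 1e-6)
  expect_error(smooth_z(matrix(NA_real_, 5, 5), 2), "no sampled")
})

test_that("the smoothing kernel matches the analytic Gaussian on an impulse", {
  H <- 96; W <- 96; sigma <- 8
  x <- matrix(0, H, W); x[48, 48] <- 1
  s <- bodybubbles:::smooth2d(x, sigma)
  d2 <- outer((1:H - 48)^2, (1:W - 48)^2, `+`)
  kernel <- exp(-d2 / (2 * sigma^2))
  kernel <- kernel / sum(kernel)
  expect_lt(max(abs(s - kernel)), 1e-6)
})

test_that("an all-zero z-map yields no clusters", {
  z <- smooth_z(matrix(0.5, 64, 48), sigma_px = 4)
  res <- cluster_test(z, 2.7, 0.05)
  expect_equal(nrow(res$clusters), 0)
  expect_false(any(res$sig[[1]]))
})

test_that("cluster_test insists on standardized input", {
  z <- smooth_z(matrix(runif(48 * 48), 48, 48), sigma_px = 3)
  z$planes[[1]] <- z$planes[[1]] + 5
  expect_error(cluster_test(z), "not standardized")
})

test_that("a planted disc is recovered as one significant cluster", {
  H <- 128; W <- 128; r <- 12
  set.seed(31)
  p <- matrix(0.5 + rnorm(H * W, 0, 0.05), H, W)
  disc <- outer((1:H - 64)^2, (1:W - 64)^2, `+`) <= r^2
  p[disc] <- p[disc] + 0.3
  z <- smooth_z(p, sigma_px = 4)
  res <- cluster_test(z, 2.7, 0.05, n_fields = 400)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_gte(sum(res$sig[[1]] & disc) / sum(disc), 0.8)
})

test_that("diagnostic proportions count significant pixels per band and part", {
  H <- 20; W <- 10
  sig1 <- matrix(FALSE, H, W); sig1[1:5, 1:4] <- TRUE      # 20 px
  sig2 <- matrix(FALSE, H, W)
  res <- structure(list(sig = list(sig1, sig2)), class = "cluster_result")
  expect_equal(unname(diagnostic_proportion_by_band(res)),
               c(20 / 200, 0))
  parts <- list(head = matrix(FALSE, H, W), torso = matrix(FALSE, H, W),
                legs = matrix(FALSE, H, W))
  parts$head[1:5, 1:2] <- TRUE       # 10 px, fully significant
  parts$torso[6:15, 1:10] <- TRUE    # 100 px, none significant
  parts$legs[16:20, 1:4] <- TRUE     # 20 px, none significant
  pp <- diagnostic_proportion_by_part(res, parts)
  expect_equal(unname(pp), c(1, 0, 0))
  parts$legs[] <- FALSE
  expect_error(diagnostic_proportion_by_part(res, parts), "empty part")
})

test_that("fully significant planes give proportion one", {
  res <- structure(list(sig = list(matrix(TRUE, 4, 4))),
                   class = "cluster_result")
  expect_equal(unname(diagnostic_proportion_by_band(res)), 1)
})

test_that("sampling-referenced z maps need the accumulator", {
  expect_error(smooth_z(matrix(0.5, 8, 8), 2, reference = "sampling"),
               "accumulator")
})
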