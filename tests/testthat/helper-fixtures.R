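# Shared small-scale fixtures, built once per test run and memoized.

.fixtures <- new.env()

# 120 x 96 bodies (2 actors), 4-band spec scaled to the small image.
small_bodies <- function() {
  if (is.null(.fixtures$bodies))
    .fixtures$bodies <- make_body_set(2, image_size = c(120, 96), seed = 42)
  .fixtures$bodies
}

small_spec <- function() {
  if (is.null(.fixtures$spec))
    .fixtures$spec <- band_spec(width_px = 96, height_px = 120,
                                width_deg = 2.14, height_deg = 2.67,
                                n_bands = 4)
  .fixtures$spec
}

# A short closed-loop session against the canonical observer.
small_session <- function() {
  if (is.null(.fixtures$session)) {
    bodies <- small_bodies()
    obs <- make_observer(bodies)
    .fixtures$session <- run_session(
      bodies, obs, n_trials = 120, spec = small_spec(),
      state = density_state(attr(bodies, "expressions"), init_count = 60,
                            bounds = c(1, 200)),
      seed = 7)
  }
  .fixtures$session
}

# Toy trial records: K tiny mask planes per trial with known values.
toy_trials <- function(n = 10, dims = c(8, 6), K = 2, seed = 3) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(lapply(seq_len(n), function(i) {
    list(planes = lapply(seq_len(K), function(k)
      matrix(runif(prod(dims)), dims[1], dims[2])),
      correct = runif(1) < 0.6)
  }))
}

expect_symmetric_zero_diag <- function(m) {
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
}
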