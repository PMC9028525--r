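#' Random-field-theory cluster extent p-value
#'
#' Family-wise p-value for a cluster of `size` contiguous pixels above
#' threshold `t` in a smooth standardized 2-D Gaussian field.  Uses the
#' expected-Euler-characteristic count of supra-threshold clusters and the
#' exponential approximation to the cluster-extent distribution: with
#' `E[m]` the expected cluster count, `E[N]` the expected supra-threshold
#' area, and `P(n >= k) = exp(-k * E[m] / E[N])`, the family-wise p-value
#' is `1 - exp(-E[m] * P(n >= k))`.
#'
#' @param size cluster extent(s) in pixels.
#' @param t cluster-forming threshold (z units).
#' @param fwhm field smoothness (full width at half maximum, pixels).
#' @param area search area in pixels.
#' @return numeric vector of p-values.
#' @export
rft_cluster_p <- function(size, t, fwhm, area) {
  stop_if_not(t > 0 && fwhm > 0 && area > 0, "invalid RFT parameters")
  Em <- rft_expected_clusters(t, fwhm, area)
  EN <- area * stats::pnorm(t, lower.tail = FALSE)
  beta <- Em / EN
  1 - exp(-Em * exp(-beta * size))
}

#' Expected number of supra-threshold clusters (2-D Gaussian field)
#'
#' `E[m] = resels * 4 log(2) * (2 pi)^{-3/2} * t * exp(-t^2 / 2)` with
#' `resels = area / fwhm^2`.
#'
#' @inheritParams rft_cluster_p
#' @return expected cluster count.
#' @export
rft_expected_clusters <- function(t, fwhm, area) {
  resels <- area / fwhm^2
  resels * 4 * log(2) * (2 * pi)^(-3 / 2) * t * exp(-t^2 / 2)
}

#' Critical cluster extent at a given alpha
#'
#' Smallest cluster size whose family-wise p-value is at or below `alpha`.
#'
#' @inheritParams rft_cluster_p
#' @param alpha family-wise significance level.
#' @return critical extent in pixels (integer).
#' @export
rft_cluster_threshold <- function(t, fwhm, area, alpha = 0.05) {
  Em <- rft_expected_clusters(t, fwhm, area)
  EN <- area * stats::pnorm(t, lower.tail = FALSE)
  beta <- Em / EN
  ceiling(log(Em / (-log(1 - alpha))) / beta)
}

# Cache of Monte-Carlo max-cluster-extent null distributions, keyed by
# (H, W, t, fwhm, n_fields, seed).
.null_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the maximum cluster extent
#'
#' Simulates stationary unit-variance Gaussian fields with the stated
#' smoothness (circular convolution of white noise with the matching
#' Gaussian kernel), thresholds them at `t`, and records the largest
#' 8-connected cluster extent of each field.  Because the smoothness of a
#' smoothed classification image is known exactly (the applied kernel and
#' the bubble sigma), the null can be simulated rather than approximated;
#' the resulting max-extent distribution gives family-wise-exact cluster
#' p-values.  Results are cached per parameter set and are deterministic
#' (internal fixed seed).
#'
#' @param t cluster-forming threshold (z units).
#' @param fwhm field smoothness in pixels.
#' @param H,W field size in pixels.
#' @param n_fields Monte-Carlo replicates.
#' @param seed seed of the internal simulation.
#' @return sorted integer vector of `n_fields` maximum cluster extents.
#' @export
mc_cluster_null <- function(t, fwhm, H, W, n_fields = 1000, seed = 7919) {
  key <- paste(H, W, signif(t, 8), signif(fwhm, 8), n_fields, seed,
               sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  sigma <- fwhm / sqrt(8 * log(2))
  sm <- make_smoother(H, W, sigma, boundary = "circular")
  maxima <- local_seed(seed, {
    vapply(seq_len(n_fields), function(i) {
      f <- sm(matrix(stats::rnorm(H * W), H, W))
      f <- (f - mean(f)) / stats::sd(f)
      sz <- attr(label8_cpp(f > t), "sizes")
      if (length(sz)) max(sz) else 0L
    }, integer(1))
  })
  .null_cache[[key]] <- sort(maxima)
  .null_cache[[key]]
}

#' Simulate stationary smooth Gaussian z-fields
#'
#' Generates unit-variance Gaussian random fields by circular convolution
#' of white noise with a Gaussian kernel, i.e. stationary fields with the
#' kernel's smoothness and no boundary artifacts -- the regime the
#' random-field cluster test assumes.  Used to check the test's
#' family-wise false-alarm calibration by Monte Carlo.
#'
#' @param n number of fields.
#' @param H,W field size in pixels.
#' @param sigma_px smoothing kernel standard deviation.
#' @param seed integer seed.
#' @return list of H x W matrices, each standardized to mean 0, sd 1.
#' @export
simulate_smooth_fields <- function(n, H, W, sigma_px = 8, seed = 1) {
  sm <- make_smoother(H, W, sigma_px, boundary = "circular")
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- sm(matrix(stats::rnorm(H * W), H, W))
      (f - mean(f)) / stats::sd(f)
    })
  })
}
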