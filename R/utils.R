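# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs in the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Discrete Gaussian kernel
#'
#' Unit-sum 1-D Gaussian kernel truncated at `radius` pixels
#' (default 4 standard deviations).
#'
#' @param sigma standard deviation in pixels.
#' @param radius truncation radius in pixels.
#' @return numeric vector of length `2 * radius + 1`.
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# A reusable Gaussian smoother for H x W planes.  boundary = "renorm"
# performs linear convolution and divides by the local kernel mass, so a
# constant plane stays exactly constant and the interior impulse response
# equals the normalized kernel; boundary = "circular" wraps around (used to
# synthesize stationary smooth noise fields).
make_smoother <- function(H, W, sigma, boundary = c("renorm", "circular")) {
  boundary <- match.arg(boundary)
  if (boundary == "circular") {
    k1h <- gaussian_kernel(sigma, radius = min(ceiling(4 * sigma), floor((H - 1) / 2)))
    k1w <- gaussian_kernel(sigma, radius = min(ceiling(4 * sigma), floor((W - 1) / 2)))
    kh <- numeric(H); rh <- (length(k1h) - 1L) / 2L
    kh[((seq_along(k1h) - 1L - rh) %% H) + 1L] <- k1h
    kw <- numeric(W); rw <- (length(k1w) - 1L) / 2L
    kw[((seq_along(k1w) - 1L - rw) %% W) + 1L] <- k1w
    fk <- stats::fft(outer(kh, kw))
    n <- H * W
    return(function(x) Re(stats::fft(stats::fft(x) * fk, inverse = TRUE)) / n)
  }
  rad <- ceiling(4 * sigma)
  PH <- stats::nextn(H + 2L * rad, c(2, 3, 5))
  PW <- stats::nextn(W + 2L * rad, c(2, 3, 5))
  k1 <- gaussian_kernel(sigma, rad)
  kh <- numeric(PH); kh[((seq_along(k1) - 1L - rad) %% PH) + 1L] <- k1
  kw <- numeric(PW); kw[((seq_along(k1) - 1L - rad) %% PW) + 1L] <- k1
  fk <- stats::fft(outer(kh, kw))
  n <- PH * PW
  conv <- function(x) {
    xp <- matrix(0, PH, PW)
    xp[seq_len(H), seq_len(W)] <- x
    Re(stats::fft(stats::fft(xp) * fk, inverse = TRUE))[seq_len(H), seq_len(W)] / n
  }
  mass <- conv(matrix(1, H, W))
  function(x) conv(x) / mass
}

# 2-D Gaussian smoothing of a single plane (convenience wrapper; for
# repeated smoothing of same-size planes build the smoother once).
smooth2d <- function(x, sigma, boundary = "renorm") {
  make_smoother(nrow(x), ncol(x), sigma, boundary)(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
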