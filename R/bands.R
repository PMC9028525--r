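#' Spatial-frequency band specification for Bubbles stimuli
#'
#' Defines one-octave spatial-frequency bands for a stimulus of known pixel
#' and visual-angle size, together with the per-band Gaussian bubble sizes.
#' The highest band's upper cut-off is the horizontal Nyquist frequency
#' (one cycle per 2 pixels, i.e. `width_px / 2` cycles per image width);
#' each subsequent cut-off halves it.  Bubble standard deviations are set so
#' that each bubble reveals a fixed number of cycles of its band's upper
#' cut-off frequency, which makes them grow by an octave from fine to
#' coarse scales.
#'
#' With the default stimulus geometry (245 px wide, 5.47 degrees) and five
#' bands, the cut-offs are 122.5, 61.25, 30.6, 15.3, 7.7 and 3.8 cycles per
#' image (22.4, 11.2, 5.6, 2.8, 1.4 and 0.7 cycles/degree) and the bubble
#' standard deviations are 0.13, 0.27, 0.54, 1.07 and 2.14 degrees.
#'
#' @param width_px,height_px stimulus size in pixels.
#' @param width_deg,height_deg stimulus size in degrees of visual angle.
#' @param n_bands number of one-octave bands.
#' @param cycles_per_bubble cycles of the band's upper cut-off revealed per
#'   bubble (sets the bubble standard deviation).
#' @return an object of class `band_spec` with elements `cutoffs_cpi`,
#'   `cutoffs_cdeg` (length `n_bands + 1`: upper cut-offs plus the final
#'   lower bound), `sigmas_deg`, `sigmas_px`, and the geometry fields.
#' @export
band_spec <- function(width_px = 245, height_px = 310,
                      width_deg = 5.47, height_deg = 6.90,
                      n_bands = 5, cycles_per_bubble = 3) {
  stop_if_not(width_px > 0 && height_px > 0 && width_deg > 0 && height_deg > 0,
              "stimulus dimensions must be positive")
  stop_if_not(n_bands >= 1, "n_bands must be at least 1")
  stop_if_not(cycles_per_bubble > 0, "cycles_per_bubble must be positive")
  cpi <- band_cutoffs(width_px, width_deg, n_bands)
  sig_deg <- cycles_per_bubble / cpi$cutoffs_cdeg[seq_len(n_bands)]
  spec <- list(
    width_px = width_px, height_px = height_px,
    width_deg = width_deg, height_deg = height_deg,
    px_per_deg = width_px / width_deg,
    n_bands = n_bands, cycles_per_bubble = cycles_per_bubble,
    cutoffs_cpi = cpi$cutoffs_cpi, cutoffs_cdeg = cpi$cutoffs_cdeg,
    sigmas_deg = sig_deg, sigmas_px = sig_deg * width_px / width_deg
  )
  class(spec) <- "band_spec"
  spec
}

#' Octave band cut-off frequencies
#'
#' The top cut-off is the horizontal Nyquist frequency `width_px / 2` in
#' cycles per image width; each of the following `n_bands` cut-offs halves
#' its predecessor, defining `n_bands` non-overlapping one-octave bands.
#'
#' @param width_px image width in pixels.
#' @param width_deg image width in degrees of visual angle.
#' @param n_bands number of bands.
#' @return list with `cutoffs_cpi` and `cutoffs_cdeg`, each of length
#'   `n_bands + 1` (band upper cut-offs followed by the lowest band's
#'   lower bound).
#' @export
band_cutoffs <- function(width_px, width_deg, n_bands) {
  stop_if_not(width_px > 0 && width_deg > 0, "dimensions must be positive")
  stop_if_not(n_bands >= 1, "n_bands must be at least 1")
  cpi <- (width_px / 2) / 2^(0:n_bands)
  list(cutoffs_cpi = cpi, cutoffs_cdeg = cpi / width_deg)
}

#' Per-band bubble standard deviations
#'
#' sigma_deg\[k\] = `cycles_per_bubble / cutoff_cdeg[k]` (using each band's
#' upper cut-off), converted to pixels with the stimulus pixel density.
#'
#' @param spec a [band_spec()].
#' @param cycles_per_bubble cycles revealed per bubble.
#' @return list with `sigmas_deg` and `sigmas_px`, one entry per band.
#' @export
bubble_sigmas <- function(spec, cycles_per_bubble = spec$cycles_per_bubble) {
  stop_if_not(inherits(spec, "band_spec"), "spec must be a band_spec")
  stop_if_not(cycles_per_bubble > 0, "cycles_per_bubble must be positive")
  cd <- spec$cutoffs_cdeg[seq_len(spec$n_bands)]
  stop_if_not(all(cd > 0), "zero cut-off frequency")
  sd_deg <- cycles_per_bubble / cd
  list(sigmas_deg = sd_deg, sigmas_px = sd_deg * spec$px_per_deg)
}

# Radial low-pass transfer function on the FFT grid of an H x W image:
# raised cosine in log2 frequency with half-amplitude at `cutoff_cpi`
# (expressed in cycles per image *width*) and a one-octave transition.
lowpass_transfer <- function(H, W, cutoff_cpi, width_px) {
  fx <- 0:(W - 1); fx <- pmin(fx, W - fx) / W
  fy <- 0:(H - 1); fy <- pmin(fy, H - fy) / H
  r <- sqrt(outer(fy^2, fx^2, "+"))
  c0 <- cutoff_cpi / width_px
  lr <- log2(r / c0)                      # r = 0 -> -Inf -> pass
  L <- matrix(0, H, W)
  L[lr <= -0.5] <- 1
  mid <- is.finite(lr) & lr > -0.5 & lr < 0.5
  L[mid] <- cos(pi / 2 * (lr[mid] + 0.5))^2
  L
}

#' Decompose an image into one-octave spatial-frequency bands
#'
#' Recursively peels off spatial-frequency layers: at each scale the current
#' image is split into a low-pass part (raised-cosine radial filter with
#' half-amplitude at the band's lower cut-off, one-octave transition) and
#' the band-pass remainder.  The final low-pass plane is kept as the
#' residual, so the sum of all band planes plus the residual reconstructs
#' the input exactly (up to floating-point error).
#'
#' @param image numeric matrix (grayscale plane) matching `spec` dimensions.
#' @param spec a [band_spec()].
#' @return object of class `sf_stack`: list with `bands` (list of planes,
#'   fine to coarse), `residual`, and `spec`.
#' @export
decompose_sf <- function(image, spec) {
  stop_if_not(is.matrix(image), "image must be a matrix")
  stop_if_not(nrow(image) == spec$height_px && ncol(image) == spec$width_px,
              "image dimensions do not match the band specification")
  H <- nrow(image); W <- ncol(image)
  cur <- image
  bands <- vector("list", spec$n_bands)
  for (k in seq_len(spec$n_bands)) {
    L <- lowpass_transfer(H, W, spec$cutoffs_cpi[k + 1], spec$width_px)
    low <- Re(stats::fft(stats::fft(cur) * L, inverse = TRUE)) / (H * W)
    bands[[k]] <- cur - low
    cur <- low
  }
  structure(list(bands = bands, residual = cur, spec = spec),
            class = "sf_stack")
}

#' Sample a multi-scale bubbles mask
#'
#' For each band, places the requested number of unit-peak Gaussian bubbles
#' (standard deviation from the band specification) at centers drawn
#' uniformly over the full image plane, sums them and caps the result at 1.
#'
#' @param counts integer vector of bubble counts, one per band.
#' @param spec a [band_spec()].
#' @return object of class `bubble_mask`: `planes` (list of H x W matrices
#'   in \[0, 1\]), `counts`, and `centers` (per band, a matrix of x/y pixel
#'   coordinates, 0-based).
#' @export
sample_mask <- function(counts, spec) {
  stop_if_not(length(counts) == spec$n_bands, "one bubble count per band")
  stop_if_not(all(counts >= 0), "bubble counts must be non-negative")
  H <- spec$height_px; W <- spec$width_px
  centers <- planes <- vector("list", spec$n_bands)
  for (k in seq_len(spec$n_bands)) {
    n <- as.integer(counts[k])
    cx <- stats::runif(n, 0, W) - 0.5
    cy <- stats::runif(n, 0, H) - 0.5
    centers[[k]] <- cbind(x = cx, y = cy)
    planes[[k]] <- if (n == 0) matrix(0, H, W) else
      bubble_plane_cpp(H, W, cx, cy, spec$sigmas_px[k])
  }
  structure(list(planes = planes, counts = as.integer(counts),
                 centers = centers),
            class = "bubble_mask")
}

# Rebuild the mask planes of one band from stored centers (deterministic).
mask_plane_from_centers <- function(centers, spec, band) {
  H <- spec$height_px; W <- spec$width_px
  if (nrow(centers) == 0) return(matrix(0, H, W))
  bubble_plane_cpp(H, W, centers[, 1], centers[, 2], spec$sigmas_px[band])
}

#' Compose a sparse Bubbles stimulus
#'
#' stimulus = residual + sum over bands of band_k * mask_k, clipped to the
#' displayable range.  The low-pass residual is always shown unmasked; with
#' all masks at 1 the original image is recovered, with all masks at 0 only
#' the residual (the background merged with the coarsest structure) remains.
#'
#' @param stack an [decompose_sf()] result.
#' @param mask a [sample_mask()] result with the same band structure.
#' @param range displayable gray range, defaults to c(0, 255).
#' @return numeric matrix, the stimulus plane.
#' @export
compose_stimulus <- function(stack, mask, range = c(0, 255)) {
  stop_if_not(inherits(stack, "sf_stack"), "stack must be an sf_stack")
  stop_if_not(length(stack$bands) == length(mask$planes),
              "stack and mask band structure differ")
  out <- stack$residual
  for (k in seq_along(stack$bands)) out <- out + stack$bands[[k]] * mask$planes[[k]]
  pmin(pmax(out, range[1]), range[2])
}
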