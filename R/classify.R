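#' Accumulate bubbles masks by response outcome
#'
#' Sums, per spatial-frequency band and per pixel, the bubbles masks of
#' trials that led to a correct response and (separately) the masks of
#' trials that led to an error.
#'
#' Two inputs are supported: a `bubbles_session` (masks are rebuilt
#' deterministically from the stored bubble centers), or a plain list of
#' trial records, each a list with `planes` (per-band mask planes) and
#' `correct` (logical) -- convenient for small hand-built cases.
#'
#' @param trials a `bubbles_session` or a list of trial records.
#' @param subset optional integer or logical index selecting trials (for a
#'   session, e.g. the trials of one expression).
#' @param ... unused.
#' @return object of class `mask_accumulator`: `correct_sum` and
#'   `error_sum` (lists of per-band planes), `n_correct`, `n_error`.
#' @export
accumulate <- function(trials, subset = NULL, ...) UseMethod("accumulate")

#' @export
accumulate.bubbles_session <- function(trials, subset = NULL, ...) {
  session <- trials
  idx <- seq_len(nrow(session$log))
  if (!is.null(subset)) idx <- idx[subset]
  stop_if_not(length(idx) > 0, "no trials to accumulate")
  spec <- session$spec
  K <- spec$n_bands
  H <- spec$height_px; W <- spec$width_px
  cs <- es <- sq <- lapply(seq_len(K), function(k) matrix(0, H, W))
  ok <- session$log$correct[idx]
  for (i in seq_along(idx)) {
    tc <- session$centers[[idx[i]]]
    for (k in seq_len(K)) {
      if (nrow(tc[[k]]) == 0) next
      plane <- mask_plane_from_centers(tc[[k]], spec, k)
      if (ok[i]) cs[[k]] <- cs[[k]] + plane else es[[k]] <- es[[k]] + plane
      sq[[k]] <- sq[[k]] + plane^2
    }
  }
  new_accumulator(cs, es, sum(ok), sum(!ok), sq)
}

#' @export
accumulate.list <- function(trials, subset = NULL, ...) {
  if (!is.null(subset)) trials <- trials[subset]
  stop_if_not(length(trials) > 0, "no trials to accumulate")
  K <- length(trials[[1]]$planes)
  dims <- dim(trials[[1]]$planes[[1]])
  cs <- es <- sq <- lapply(seq_len(K), function(k) matrix(0, dims[1], dims[2]))
  nc <- ne <- 0L
  for (tr in trials) {
    stop_if_not(length(tr$planes) == K &&
                  all(dim(tr$planes[[1]]) == dims),
                "all trials must share the band structure")
    if (isTRUE(tr$correct)) {
      for (k in seq_len(K)) cs[[k]] <- cs[[k]] + tr$planes[[k]]
      nc <- nc + 1L
    } else {
      for (k in seq_len(K)) es[[k]] <- es[[k]] + tr$planes[[k]]
      ne <- ne + 1L
    }
    for (k in seq_len(K)) sq[[k]] <- sq[[k]] + tr$planes[[k]]^2
  }
  new_accumulator(cs, es, nc, ne, sq)
}

new_accumulator <- function(cs, es, nc, ne, sq = NULL) {
  structure(list(correct_sum = cs, error_sum = es,
                 n_correct = nc, n_error = ne, sq_sum = sq),
            class = "mask_accumulator")
}

# Per-pixel standard error of the proportion image under the
# label-shuffling null: the correct-mask sum is a weighted sample of
# n_correct of the n trials' weights, so with per-pixel weight sums S1
# (= correct + error) and S2 (squared masks),
#   Var(num) = m (n - m) / (n (n - 1)) * (S2 - S1^2 / n)
# and se(p_hat) = sqrt(Var(num)) / S1.
proportion_null_se <- function(acc) {
  n <- acc$n_correct + acc$n_error
  m <- acc$n_correct
  lapply(seq_along(acc$correct_sum), function(k) {
    s1 <- acc$correct_sum[[k]] + acc$error_sum[[k]]
    v <- m * (n - m) / (n * (n - 1)) * pmax(acc$sq_sum[[k]] - s1^2 / n, 0)
    se <- sqrt(v) / s1
    se[s1 == 0] <- NA_real_
    se
  })
}

#' Per-band proportion images
#'
#' Pixelwise correct / (correct + error) mask sums.  Pixels never sampled
#' by any bubble (zero denominator) are marked `NA` rather than raising an
#' error.
#'
#' @param acc a [accumulate()] result.
#' @return object of class `proportion_image`: list `planes` of per-band
#'   matrices with values in \[0, 1\] or `NA`.
#' @export
proportion_image <- function(acc) {
  stop_if_not(inherits(acc, "mask_accumulator"), "acc must be an accumulator")
  planes <- lapply(seq_along(acc$correct_sum), function(k) {
    den <- acc$correct_sum[[k]] + acc$error_sum[[k]]
    p <- acc$correct_sum[[k]] / den
    p[den == 0] <- NA_real_
    p
  })
  structure(list(planes = planes), class = "proportion_image")
}

#' Smooth and z-transform proportion images
#'
#' Undefined (never-sampled) pixels are imputed with the plane's defined
#' mean, the plane is smoothed with a Gaussian kernel of the stated
#' standard deviation (locally renormalized at the image border), and the
#' smoothed plane is standardized to mean 0 and unit standard deviation
#' over the defined region.  A zero-variance plane standardizes to all
#' zeros by convention.
#'
#' Two standardization references are available.  `"plane"` (the default)
#' standardizes the smoothed plane by its own mean and standard
#' deviation.  `"sampling"` first variance-stabilizes each pixel by its
#' exact standard error under the label-shuffling null (computed from the
#' accumulated mask weights, see the details of [accumulate()]); this
#' removes the spatial non-stationarity caused by uneven bubble coverage
#' (image borders, sparsely sampled coarse bands) and makes the smoothed
#' map's null behavior match a stationary Gaussian field of the band's
#' effective smoothness.
#'
#' @param prop a [proportion_image()] (or a bare matrix / list of matrices).
#' @param sigma_px smoothing standard deviation in pixels.
#' @param reference `"plane"` or `"sampling"` (requires `acc`).
#' @param acc the [accumulate()] result, needed for
#'   `reference = "sampling"`.
#' @return object of class `z_map`: `planes` (standardized), `sigma_px`,
#'   `defined` (logical planes), and the `reference` mean/sd used per band.
#' @export
smooth_z <- function(prop, sigma_px = 8, reference = c("plane", "sampling"),
                     acc = NULL) {
  reference <- match.arg(reference)
  stop_if_not(sigma_px > 0, "sigma_px must be positive")
  planes <- if (inherits(prop, "proportion_image")) prop$planes
            else if (is.matrix(prop)) list(prop) else prop
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  sm <- make_smoother(H, W, sigma_px)
  if (reference == "sampling") {
    stop_if_not(inherits(acc, "mask_accumulator") && !is.null(acc$sq_sum),
                "reference = \"sampling\" needs the mask accumulator")
    se <- proportion_null_se(acc)
    pbar <- acc$n_correct / (acc$n_correct + acc$n_error)
  }
  defined <- lapply(seq_along(planes), function(k) {
    def <- !is.na(planes[[k]])
    if (reference == "sampling")
      def <- def & is.finite(se[[k]]) & se[[k]] > 0
    def
  })
  ref <- vector("list", length(planes))
  z <- lapply(seq_along(planes), function(k) {
    p <- planes[[k]]; def <- defined[[k]]
    stop_if_not(any(def), "plane has no sampled pixels")
    if (reference == "sampling") {
      e <- (p - pbar) / se[[k]]
      e[!def] <- 0
    } else {
      e <- p
      e[!def] <- mean(p[def])
    }
    s <- sm(e)
    m <- mean(s[def]); sdev <- stats::sd(s[def])
    ref[[k]] <<- c(mean = m, sd = sdev)
    if (!is.finite(sdev) || sdev < 1e-12) matrix(0, H, W) else (s - m) / sdev
  })
  structure(list(planes = z, sigma_px = sigma_px, defined = defined,
                 reference = ref, reference_type = reference),
            class = "z_map")
}

#' Random-field cluster test on z-maps
#'
#' Thresholds each band's z-map at `t_threshold`, groups supra-threshold
#' pixels by 8-connectivity, and assigns each cluster an extent p-value
#' from the Gaussian random-field expected-cluster-size approximation for
#' 2-D fields given the map smoothness (FWHM) and the full-plane search
#' area.  Clusters with p <= alpha are reported significant.  Pixels that
#' were never sampled are excluded from significance.
#'
#' @param z a [smooth_z()] result (standardized planes).
#' @param t_threshold cluster-forming z threshold.
#' @param alpha cluster-level significance level.
#' @param fwhm smoothness in pixels, scalar or one value per band.
#'   Defaults to the applied kernel's FWHM, `sigma_px * sqrt(8 * log(2))`;
#'   pass [effective_fwhm()] when the underlying data carry their own
#'   spatial correlation (e.g. Gaussian bubbles).
#' @param method `"simulation"` (default) takes cluster p-values from the
#'   Monte-Carlo max-extent null of stationary fields with the stated
#'   smoothness ([mc_cluster_null()]; family-wise exact up to Monte-Carlo
#'   error); `"rft"` uses the closed-form random-field expected-cluster-
#'   size approximation ([rft_cluster_p()]), which is mildly conservative
#'   at moderate thresholds.
#' @param n_fields Monte-Carlo replicates for `method = "simulation"`.
#' @return object of class `cluster_result`: `sig` (per-band logical
#'   planes), `clusters` (data frame: band, id, size, p, significant),
#'   plus the parameters used.
#' @export
cluster_test <- function(z, t_threshold = 2.7, alpha = 0.05, fwhm = NULL,
                         method = c("simulation", "rft"),
                         n_fields = 1000) {
  method <- match.arg(method)
  stop_if_not(inherits(z, "z_map"), "z must be a z_map from smooth_z()")
  for (k in seq_along(z$planes)) {
    def <- z$defined[[k]]
    v <- z$planes[[k]][def]
    stop_if_not(abs(mean(v)) < 1e-4 && (stats::sd(v) < 1e-12 ||
                  abs(stats::sd(v) - 1) < 1e-4),
                "z-map is not standardized; run smooth_z() first")
  }
  if (is.null(fwhm)) fwhm <- z$sigma_px * sqrt(8 * log(2))
  fwhm <- rep_len(fwhm, length(z$planes))
  H <- nrow(z$planes[[1]]); W <- ncol(z$planes[[1]])
  area <- H * W
  sig <- vector("list", length(z$planes))
  rows <- list()
  for (k in seq_along(z$planes)) {
    supra <- z$planes[[k]] > t_threshold & z$defined[[k]]
    lab <- label8_cpp(supra)
    sizes <- attr(lab, "sizes")
    sigmask <- matrix(FALSE, H, W)
    if (length(sizes)) {
      p <- cluster_size_p(sizes, t_threshold, fwhm[k], H, W, method,
                          n_fields)
      keep <- p <= alpha
      if (any(keep)) sigmask <- matrix(lab %in% which(keep), H, W)
      rows[[length(rows) + 1L]] <- data.frame(
        band = k, id = seq_along(sizes), size = sizes, p = p,
        significant = keep)
    }
    sig[[k]] <- sigmask
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(band = integer(), id = integer(), size = integer(),
               p = numeric(), significant = logical())
  structure(list(sig = sig, clusters = clusters, t_threshold = t_threshold,
                 alpha = alpha, fwhm = fwhm, area = area, method = method),
            class = "cluster_result")
}

# Family-wise cluster-extent p-values for one band.
cluster_size_p <- function(sizes, t, fwhm, H, W, method, n_fields) {
  if (method == "rft") return(rft_cluster_p(sizes, t, fwhm, H * W))
  null_max <- mc_cluster_null(t, fwhm, H, W, n_fields)
  n <- length(null_max)
  vapply(sizes, function(k)
    (sum(null_max >= k) + 1) / (n + 1), numeric(1))
}

#' Expected smoothness of a bubbles-derived z-map
#'
#' A field built from Gaussian bubbles of standard deviation `sigma_band`
#' and then smoothed with a Gaussian kernel of `sigma_smooth` has the
#' autocorrelation of white noise filtered with a Gaussian of
#' `sqrt(sigma_band^2 + sigma_smooth^2)`; this returns the corresponding
#' FWHM per band, for use as the `fwhm` argument of [cluster_test()].
#'
#' @param spec a [band_spec()] (or a numeric vector of band sigmas in px).
#' @param sigma_smooth the [smooth_z()] kernel standard deviation.
#' @return numeric vector of per-band FWHM values in pixels.
#' @export
effective_fwhm <- function(spec, sigma_smooth = 8) {
  sig <- if (inherits(spec, "band_spec")) spec$sigmas_px else spec
  sqrt(8 * log(2)) * sqrt(sig^2 + sigma_smooth^2)
}

#' Proportion of diagnostic (significant) pixels per SF band
#'
#' Significant-pixel count divided by the total pixel count of each band
#' plane.
#'
#' @param result a [cluster_test()] result.
#' @return named numeric vector, one proportion per band.
#' @export
diagnostic_proportion_by_band <- function(result) {
  stop_if_not(inherits(result, "cluster_result"), "need a cluster_result")
  p <- vapply(result$sig, mean, numeric(1))
  names(p) <- paste0("band", seq_along(p))
  p
}

#' Proportion of diagnostic pixels per body part
#'
#' Pools the significant pixels across bands (pixelwise union) and divides
#' the count inside each body part by the part's pixel count.
#'
#' @param result a [cluster_test()] result.
#' @param part_masks named list of disjoint logical planes.
#' @return named numeric vector of per-part proportions in \[0, 1\].
#' @export
diagnostic_proportion_by_part <- function(result, part_masks) {
  stop_if_not(inherits(result, "cluster_result"), "need a cluster_result")
  pooled <- Reduce(`|`, result$sig)
  vapply(part_masks, function(m) {
    stop_if_not(sum(m) > 0, "empty part mask")
    sum(pooled & m) / sum(m)
  }, numeric(1))
}

#' Classification-image pipeline for one set of trials
#'
#' Convenience wrapper chaining [accumulate()], [proportion_image()],
#' [smooth_z()] and [cluster_test()] with the band-specific effective
#' smoothness.
#'
#' @param session a [run_session()] result.
#' @param subset optional trial subset (e.g. one expression's trials).
#' @param sigma_px smoothing kernel standard deviation.
#' @param t_threshold,alpha cluster-test parameters.
#' @param ... further arguments (e.g. `method`) passed to [cluster_test()].
#' @return list with `accumulator`, `proportion`, `z`, and `clusters`
#'   (the `cluster_result`).
#' @export
classification_image <- function(session, subset = NULL, sigma_px = 8,
                                 t_threshold = 2.7, alpha = 0.05, ...) {
  acc <- accumulate(session, subset)
  prop <- proportion_image(acc)
  z <- smooth_z(prop, sigma_px, reference = "sampling", acc = acc)
  cl <- cluster_test(z, t_threshold, alpha,
                     fwhm = effective_fwhm(session$spec, sigma_px), ...)
  list(accumulator = acc, proportion = prop, z = z, clusters = cl)
}

#' Label-shuffling null for the cluster test
#'
#' Permutes the correct/error labels of the selected trials (preserving
#' the number correct), recomputes the per-band proportion image, smoothed
#' z-map and cluster test for each shuffle, and records whether any
#' significant cluster appears.  Under the null of no association between
#' revealed content and correctness, the per-map rate of significant
#' clusters estimates the cluster test's family-wise false-alarm rate.
#'
#' @param session a [run_session()] result.
#' @param n_shuffles number of label permutations.
#' @param subset optional trial subset.
#' @param sigma_px,t_threshold,alpha as in [classification_image()].
#' @param method,n_fields cluster p-value method, see [cluster_test()].
#' @param seed integer seed for the permutations.
#' @return list with `any_sig` (n_shuffles x n_bands logical matrix) and
#'   `rate` (overall fraction of maps with a significant cluster).
#' @export
shuffle_null <- function(session, n_shuffles = 200, subset = NULL,
                         sigma_px = 8, t_threshold = 2.7, alpha = 0.05,
                         method = c("simulation", "rft"), n_fields = 1000,
                         seed = 1) {
  method <- match.arg(method)
  spec <- session$spec
  H <- spec$height_px; W <- spec$width_px
  idx <- seq_len(nrow(session$log))
  if (!is.null(subset)) idx <- idx[subset]
  n <- length(idx)
  ncorr <- sum(session$log$correct[idx])
  stop_if_not(ncorr > 0 && ncorr < n,
              "need both correct and error trials for the shuffled null")
  sm <- make_smoother(H, W, sigma_px)
  fwhm <- effective_fwhm(spec, sigma_px)
  perms <- local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- logical(n); s[sample.int(n, ncorr)] <- TRUE; s
    }, logical(n))
  })
  any_sig <- matrix(FALSE, n_shuffles, spec$n_bands)
  for (k in seq_len(spec$n_bands)) {
    M <- masks_matrix_cpp(H, W, lapply(session$centers[idx], `[[`, k),
                          spec$sigmas_px[k])
    den <- rowSums(M)
    s2 <- rowSums(M^2)
    num <- M %*% perms
    rm(M)
    v <- ncorr * (n - ncorr) / (n * (n - 1)) * pmax(s2 - den^2 / n, 0)
    se <- sqrt(v) / den
    def <- den > 0 & is.finite(se) & se > 0
    for (i in seq_len(n_shuffles)) {
      e <- (num[, i] / den - ncorr / n) / se
      e[!def] <- 0
      s <- sm(matrix(e, H, W))
      m <- mean(s[def]); sdev <- stats::sd(s[def])
      if (!is.finite(sdev) || sdev < 1e-12) next
      zi <- (s - m) / sdev
      supra <- zi > t_threshold & matrix(def, H, W)
      lab <- label8_cpp(supra)
      sizes <- attr(lab, "sizes")
      if (length(sizes))
        any_sig[i, k] <- any(cluster_size_p(sizes, t_threshold, fwhm[k],
                                            H, W, method, n_fields) <= alpha)
    }
  }
  list(any_sig = any_sig, rate = mean(any_sig))
}
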