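#' Specification for simulated ROI voxel patterns
#'
#' Describes subject x condition x voxel patterns whose condition-pattern
#' correlations follow a chosen candidate model: the target correlation
#' matrix is `C = 1 - signal_scale * R` with `R` the model RDM normalized
#' to \[0, 1\] (an affine, hence monotone, map of the model's dissimilarity
#' ranks), and independent Gaussian voxel noise is added per subject.
#'
#' @param generating_model one of the [candidate_rdms()] names.
#' @param n_subjects,n_voxels,n_conditions design sizes (the 3 x 4 design
#'   has 12 conditions).
#' @param signal_scale between-condition correlation contrast in (0, 1\];
#'   the maximally dissimilar condition pair has correlation
#'   `1 - signal_scale`.
#' @param noise_sd per-voxel noise standard deviation (the noiseless
#'   condition patterns have unit variance).
#' @param seed integer seed.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(generating_model = "emotion_pattern2",
                         n_subjects = 20, n_voxels = 200,
                         n_conditions = 12, signal_scale = 0.6,
                         noise_sd = 1, seed = 1) {
  models <- names(candidate_rdms())
  stop_if_not(generating_model %in% models,
              paste0("generating_model must be one of: ",
                     paste(models, collapse = ", ")))
  stop_if_not(n_conditions == 12,
              "the expression x body-part design has 12 conditions")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(signal_scale > 0 && signal_scale <= 1,
              "signal_scale must be in (0, 1]")
  stop_if_not(n_voxels > n_conditions,
              "need more voxels than conditions")
  structure(list(generating_model = generating_model,
                 n_subjects = n_subjects, n_voxels = n_voxels,
                 n_conditions = n_conditions, signal_scale = signal_scale,
                 noise_sd = noise_sd, seed = seed),
            class = "pattern_spec")
}

#' Simulate covariance-structured ROI voxel patterns
#'
#' Draws, per subject, condition mean patterns whose *sample* Pearson
#' correlations across voxels equal the target matrix
#' `C = 1 - signal_scale * R` exactly (the shared condition means are built
#' from an orthonormalized Gaussian voxel basis times a square root of C),
#' then adds independent Gaussian noise per subject and voxel.  With
#' `noise_sd = 0` every subject's empirical RDM is exactly
#' `signal_scale * R`, so it rank-orders identically to the generating
#' model; with noise, pattern correlations shrink monotonically.
#'
#' @param spec a [pattern_spec()].
#' @return long data frame with columns `subject`, `condition`, `voxel`,
#'   `value`; the spec is attached as attribute `"spec"`.
#' @export
simulate_patterns <- function(spec) {
  stop_if_not(inherits(spec, "pattern_spec"), "spec must be a pattern_spec")
  R <- candidate_rdms(seed = spec$seed)[[spec$generating_model]]
  C <- 1 - spec$signal_scale * unclass(R)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("target correlation matrix is not positive semi-definite; ",
         "lower signal_scale", call. = FALSE)
  sqrtC <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  V <- spec$n_voxels; K <- spec$n_conditions
  local_seed(spec$seed, {
    Z <- matrix(stats::rnorm(V * K), V, K)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z))                       # orthonormal, zero-mean columns
    M <- sqrt(V - 1) * Q %*% sqrtC         # voxels x conditions
    conds <- design_conditions()
    out <- do.call(rbind, lapply(seq_len(spec$n_subjects), function(s) {
      X <- M + spec$noise_sd * matrix(stats::rnorm(V * K), V, K)
      data.frame(subject = s,
                 condition = rep(conds, each = V),
                 voxel = rep(seq_len(V), K),
                 value = as.vector(X))
    }))
    attr(out, "spec") <- spec
    out
  })
}

#' Reshape simulated (or measured) patterns to per-subject matrices
#'
#' @param patterns long data frame with `subject`, `condition`, `voxel`,
#'   `value` columns.
#' @param condition_order row ordering of the output matrices.
#' @return named list, one conditions x voxels matrix per subject.
#' @export
pattern_matrices <- function(patterns,
                             condition_order = design_conditions()) {
  subj <- unique(patterns$subject)
  lapply(stats::setNames(subj, paste0("subject", subj)), function(s) {
    d <- patterns[patterns$subject == s, ]
    vox <- sort(unique(d$voxel))
    m <- matrix(NA_real_, length(condition_order), length(vox),
                dimnames = list(condition_order, vox))
    m[cbind(match(d$condition, condition_order),
            match(d$voxel, vox))] <- d$value
    stop_if_not(!anyNA(m), "incomplete pattern table")
    m
  })
}
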