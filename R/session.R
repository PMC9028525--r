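#' Adaptive sampling-density controller
#'
#' Per-expression multiplicative staircase that adjusts the total number of
#' bubbles to hold categorization accuracy at a target level: after each
#' trial the tracked expression's count is multiplied by
#' `1 + eta * (target - correct)`, so errors raise the density and correct
#' responses lower it.  The count is kept as a continuous state (rounded
#' only when a mask is sampled) and clamped to `bounds`.
#'
#' @param expressions expression labels to track.
#' @param init_count starting total bubble count per expression.
#' @param target target accuracy in (0, 1).
#' @param eta staircase step parameter.
#' @param bounds c(min, max) clamp for the total count.
#' @return object of class `density_state`.
#' @export
density_state <- function(expressions, init_count = 120, target = 0.75,
                          eta = 0.1, bounds = c(1, 500)) {
  stop_if_not(target > 0 && target < 1, "target accuracy must be in (0, 1)")
  stop_if_not(eta > 0, "eta must be positive")
  stop_if_not(bounds[1] >= 0 && bounds[2] > bounds[1], "invalid bounds")
  counts <- rep(min(max(init_count, bounds[1]), bounds[2]),
                length(expressions))
  names(counts) <- expressions
  structure(list(counts = counts, target = target, eta = eta,
                 bounds = bounds),
            class = "density_state")
}

#' Update the density controller after one trial
#'
#' @param state a [density_state()].
#' @param expression the trial's true expression.
#' @param correct logical, whether the response was correct.
#' @return the updated `density_state`.
#' @export
update_density <- function(state, expression, correct) {
  stop_if_not(expression %in% names(state$counts),
              paste0("unknown expression: ", expression))
  c0 <- state$counts[[expression]]
  c1 <- c0 * (1 + state$eta * (state$target - as.numeric(correct)))
  state$counts[[expression]] <- min(max(c1, state$bounds[1]), state$bounds[2])
  state
}

# Split a total bubble count over the bands in proportion to 1 / sigma^2,
# so every band reveals the same expected area per trial (coarse bubbles
# are larger, hence fewer).  Rounds the continuous staircase state; the
# largest fractional remainders receive the leftover bubbles.
allocate_bubbles <- function(total, sigmas_px) {
  n <- max(0L, as.integer(round(total)))
  w <- (1 / sigmas_px^2) / sum(1 / sigmas_px^2)
  exact <- n * w
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Run a closed-loop Bubbles session against a simulated observer
#'
#' Presents the bodies equally often in shuffled order.  On each trial the
#' current density for the body's expression is split across bands in
#' proportion to 1 / sigma^2 (equal expected revealed area per band),
#' a bubbles mask is sampled, the sparse stimulus composed, the observer's
#' response recorded, and the staircase updated from the trial's
#' correctness.  Reproducible given `seed`.
#'
#' @param bodies a [make_body_set()] result.
#' @param observer an [make_observer()] result.
#' @param n_trials number of trials (ideally a multiple of the body count).
#' @param spec a [band_spec()] matching the body image size.
#' @param state a [density_state()] tracking the expressions in `bodies`.
#' @param seed integer seed.
#' @return object of class `bubbles_session`: `log` (data frame with trial,
#'   body_id, expression, response, correct, per-band and total bubble
#'   counts), `centers` (per trial, per band bubble center matrices),
#'   `spec`, `state` (final), and `seed`.
#' @export
run_session <- function(bodies, observer, n_trials, spec, state, seed = 1) {
  stop_if_not(inherits(bodies, "body_set") && length(bodies) > 0,
              "bodies must be a non-empty body_set")
  nb <- length(bodies)
  stop_if_not(n_trials >= 1, "n_trials must be positive")
  K <- spec$n_bands
  stacks <- lapply(bodies, function(b) decompose_sf(b$image, spec))
  local_seed(seed, {
    order_idx <- sample(rep(seq_len(nb), length.out = n_trials))
    centers <- vector("list", n_trials)
    body_id <- response <- expression <- character(n_trials)
    correct <- logical(n_trials)
    nbub <- matrix(0L, n_trials, K)
    for (t in seq_len(n_trials)) {
      b <- bodies[[order_idx[t]]]
      counts <- allocate_bubbles(state$counts[[b$emotion]], spec$sigmas_px)
      mask <- sample_mask(counts, spec)
      stim <- compose_stimulus(stacks[[order_idx[t]]], mask)
      resp <- observer_respond(observer, stim, b$emotion)
      ok <- identical(resp, b$emotion)
      state <- update_density(state, b$emotion, ok)
      centers[[t]] <- mask$centers
      body_id[t] <- b$id; expression[t] <- b$emotion
      response[t] <- resp; correct[t] <- ok; nbub[t, ] <- counts
    }
    log <- data.frame(trial = seq_len(n_trials), body_id = body_id,
                      expression = expression, response = response,
                      correct = correct)
    colnames(nbub) <- paste0("n_bubbles_band", seq_len(K))
    log <- cbind(log, as.data.frame(nbub))
    log$n_bubbles <- rowSums(nbub)
    structure(list(log = log, centers = centers, spec = spec,
                   state = state, seed = seed),
              class = "bubbles_session")
  })
}

#' @export
print.bubbles_session <- function(x, ...) {
  cat("Bubbles session:", nrow(x$log), "trials,",
      length(unique(x$log$body_id)), "bodies,",
      x$spec$n_bands, "bands\n")
  cat(sprintf("overall accuracy %.3f; final densities: %s\n",
              mean(x$log$correct),
              paste(sprintf("%s=%.0f", names(x$state$counts),
                            x$state$counts), collapse = ", ")))
  invisible(x)
}
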