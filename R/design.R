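#' Enumerate the stimulus inventory
#'
#' Full crossing of actors, expressions and body-part types in stable
#' (actor-slowest) order.
#'
#' @param n_actors number of actors.
#' @param expressions expression labels.
#' @param part_types body-part type labels (e.g. whole_body,
#'   torso_with_arms, head, legs).
#' @return data frame with columns `actor`, `expression`, `part_type`,
#'   `stimulus_id`; `n_actors * length(expressions) * length(part_types)`
#'   rows.
#' @export
enumerate_stimuli <- function(n_actors,
                              expressions = c("anger", "fear", "neutral"),
                              part_types = c("whole_body",
                                             "torso_with_arms",
                                             "legs", "head")) {
  stop_if_not(n_actors >= 1 && length(expressions) >= 1 &&
                length(part_types) >= 1, "inputs must be non-empty")
  stop_if_not(!anyDuplicated(expressions) && !anyDuplicated(part_types),
              "duplicate labels")
  out <- expand.grid(part_type = part_types, expression = expressions,
                     actor = seq_len(n_actors),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("actor", "expression", "part_type")]
  out$stimulus_id <- sprintf("actor%02d_%s_%s", out$actor,
                             out$expression, out$part_type)
  rownames(out) <- NULL
  out
}

#' Balanced Bubbles trial schedule with break markers
#'
#' Every body is scheduled `repetitions` times in shuffled order, with a
#' break marker after every `block_size` trials (none after the final
#' trial).
#'
#' @param n_bodies number of distinct bodies.
#' @param repetitions presentations per body.
#' @param block_size trials per block between breaks.
#' @param seed optional seed for the shuffle.
#' @return data frame with `trial`, `body` (index), `break_after`
#'   (logical).
#' @export
bubbles_session_plan <- function(n_bodies, repetitions, block_size,
                                 seed = NULL) {
  stop_if_not(n_bodies >= 1 && repetitions >= 1 && block_size >= 1,
              "counts must be positive")
  n <- n_bodies * repetitions
  body <- local_seed(seed, sample(rep(seq_len(n_bodies), repetitions)))
  trial <- seq_len(n)
  data.frame(trial = trial, body = body,
             break_after = trial %% block_size == 0 & trial < n)
}

# Millisecond-exact run timing container.
run_timing <- function(total_ms, tr_s, parts) {
  total_s <- total_ms / 1000
  volumes <- total_s / tr_s
  if (abs(volumes - round(volumes)) > 1e-9)
    warning(sprintf("run length %.3f s is not a whole number of %g-s volumes (%.2f)",
                    total_s, tr_s, volumes), call. = FALSE)
  structure(list(total_s = total_s, tr_s = tr_s, volumes = volumes,
                 parts = parts),
            class = "run_timing")
}

#' Expected fMRI run timing
#'
#' Lead-in, `n_trials` trials of (mean fixation + stimulus), and a rest
#' insertion after every `rest_every` trials; all arithmetic is exact at
#' the millisecond grain.  With the default design (108 trials, 4 s mean
#' fixation, 2 s stimulus, 6 s lead-in, 10 s rest every 36 trials, TR 2 s)
#' the run lasts 684 s = 342 volumes.
#'
#' @param n_trials trials per run.
#' @param mean_fixation_s mean jittered fixation duration (s).
#' @param stim_s stimulus duration (s).
#' @param lead_in_s initial fixation (s).
#' @param rest_every trials between scheduled rests.
#' @param rest_s rest duration (s).
#' @param tr_s repetition time (s).
#' @return object of class `run_timing` with `total_s`, `volumes` and the
#'   per-component breakdown; a fractional volume count raises a warning.
#' @export
fmri_run_timing <- function(n_trials = 108, mean_fixation_s = 4,
                            stim_s = 2, lead_in_s = 6, rest_every = 36,
                            rest_s = 10, tr_s = 2) {
  ms <- function(x) round(1000 * x)
  n_rests <- if (n_trials == 0) 0 else n_trials %/% rest_every
  total <- ms(lead_in_s) + n_trials * (ms(mean_fixation_s) + ms(stim_s)) +
    n_rests * ms(rest_s)
  run_timing(total, tr_s,
             parts = c(lead_in_s = lead_in_s,
                       trials_s = n_trials * (mean_fixation_s + stim_s),
                       rests_s = n_rests * rest_s))
}

#' Localizer run timing
#'
#' Each block is a fixation cross followed by `images_per_block` images of
#' `image_s` with `isi_s` blanks; one `gap_s` interval follows every
#' block.  With the default design (25 blocks of 14 x 1 s on a 1 s
#' fixation, 6 s lead-in, 4 s gaps) the run lasts 481 s (8 min 1 s), which
#' is not a whole number of 2-s volumes -- the fractional volume count is
#' reported with a warning.
#'
#' @param n_blocks number of category blocks.
#' @param images_per_block images shown per block (including any repeat).
#' @param image_s,isi_s image and inter-stimulus durations (s).
#' @param fix_s block-initial fixation (s).
#' @param lead_in_s initial fixation (s).
#' @param gap_s interval after each block (s).
#' @param tr_s repetition time (s).
#' @return object of class `run_timing`.
#' @export
localizer_timing <- function(n_blocks = 25, images_per_block = 14,
                             image_s = 0.8, isi_s = 0.2, fix_s = 1,
                             lead_in_s = 6, gap_s = 4, tr_s = 2) {
  ms <- function(x) round(1000 * x)
  block <- ms(fix_s) + images_per_block * (ms(image_s) + ms(isi_s))
  total <- ms(lead_in_s) + n_blocks * block + n_blocks * ms(gap_s)
  run_timing(total, tr_s,
             parts = c(lead_in_s = lead_in_s,
                       blocks_s = n_blocks * block / 1000,
                       gaps_s = n_blocks * gap_s))
}

#' @export
print.run_timing <- function(x, ...) {
  cat(sprintf("run timing: %g s (%g min %g s), %.6g volumes at TR %g s\n",
              x$total_s, x$total_s %/% 60, x$total_s %% 60, x$volumes,
              x$tr_s))
  invisible(x)
}
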