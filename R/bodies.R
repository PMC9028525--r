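#' Generate a set of synthetic body images with labeled parts
#'
#' Builds geometric body silhouettes (ellipse head, trapezoid torso with arm
#' bars, two leg bars) on a uniform gray background, one image per actor and
#' expression.  Emotional expressions (any label other than `"neutral"`)
#' carry an expression-specific sinusoidal texture planted inside a fixed
#' sub-region of the torso -- the diagnostic region an observer must reveal
#' to categorize the expression; the neutral expression carries a spatially
#' diffuse texture over the whole silhouette and its diagnostic mask is the
#' full silhouette.  Actors share the silhouette geometry and differ in base
#' gray level and texture amplitude.
#'
#' @param n_actors number of actors (>= 1).
#' @param expressions character vector of expression labels.
#' @param image_size c(height, width) in pixels, at least 64 x 64.
#' @param seed integer seed; the same seed reproduces identical pixel data.
#' @param background background gray level (0--255).
#' @return object of class `body_set`: a list of `synthetic_body` objects,
#'   each with `image` (H x W matrix, 0--255), `part_masks` (logical planes
#'   `head`, `torso_with_arms`, `legs`, mutually disjoint), `emotion`,
#'   `diagnostic_mask`, `actor` and `id`.
#' @export
make_body_set <- function(n_actors = 4,
                          expressions = c("anger", "fear", "neutral"),
                          image_size = c(310, 245),
                          seed = 1,
                          background = 128) {
  stop_if_not(n_actors >= 1, "n_actors must be at least 1")
  H <- image_size[1]; W <- image_size[2]
  stop_if_not(H >= 64 && W >= 64,
              "image too small to contain three body parts (need >= 64 x 64)")
  geom <- body_geometry(H, W)
  parts <- geom$part_masks
  silhouette <- parts$head | parts$torso_with_arms | parts$legs

  # expression-specific gratings: distinct orientations, frequency in the
  # second-finest octave so one spatial-frequency band carries the signal
  freq_cpi <- 0.18 * W          # cycles per image width
  theta <- seq(0, pi / 2, length.out = max(length(expressions), 2))
  names(theta) <- expressions
  xx <- matrix(rep(0:(W - 1), each = H), H, W)
  yy <- matrix(rep(0:(H - 1), W), H, W)
  grating <- function(th) sin(2 * pi * freq_cpi * (xx * cos(th) + yy * sin(th)) / W)

  local_seed(seed, {
    base_gray <- 85 + stats::runif(n_actors, -8, 8)
    amp_mult <- stats::runif(n_actors, 0.85, 1.15)
    bodies <- list()
    for (a in seq_len(n_actors)) {
      for (e in expressions) {
        diag_mask <- if (identical(e, "neutral")) silhouette else geom$diagnostic
        amp <- if (identical(e, "neutral")) 40 else 55
        img <- matrix(background, H, W)
        img[silhouette] <- base_gray[a]
        img[diag_mask] <- img[diag_mask] +
          amp * amp_mult[a] * grating(theta[[e]])[diag_mask]
        img <- pmin(pmax(img, 0), 255)
        bodies[[length(bodies) + 1L]] <- structure(
          list(image = img, part_masks = parts, emotion = e,
               diagnostic_mask = diag_mask, actor = a,
               id = sprintf("actor%02d_%s", a, e)),
          class = "synthetic_body")
      }
    }
    structure(bodies, class = "body_set",
              expressions = expressions, seed = seed, background = background)
  })
}

# Silhouette geometry shared by all actors: disjoint head / torso-with-arms
# / legs masks plus the torso diagnostic sub-region, all as fractions of the
# image size.
body_geometry <- function(H, W) {
  xx <- matrix(rep(0:(W - 1), each = H), H, W)
  yy <- matrix(rep(0:(H - 1), W), H, W)
  cx <- (W - 1) / 2
  ellipse <- function(y0, x0, ry, rx)
    ((yy - y0) / ry)^2 + ((xx - x0) / rx)^2 <= 1
  head <- ellipse(0.12 * H, cx, 0.075 * H, 0.09 * W)
  # trapezoid torso: half-width widening from shoulders to hips
  ty0 <- 0.21 * H; ty1 <- 0.55 * H
  tw <- 0.16 * W + (0.20 - 0.16) * W * (yy - ty0) / (ty1 - ty0)
  torso <- yy >= ty0 & yy <= ty1 & abs(xx - cx) <= tw
  arms <- yy >= 0.23 * H & yy <= 0.31 * H & abs(xx - cx) <= 0.34 * W
  torso_with_arms <- (torso | arms) & !head
  legs <- yy >= 0.57 * H & yy <= 0.95 * H &
    (abs(xx - (cx - 0.09 * W)) <= 0.055 * W |
     abs(xx - (cx + 0.09 * W)) <= 0.055 * W)
  legs <- legs & !torso_with_arms & !head
  diagnostic <- ellipse(0.38 * H, cx, 0.11 * H, 0.13 * W) & torso_with_arms
  list(part_masks = list(head = head, torso_with_arms = torso_with_arms,
                         legs = legs),
       diagnostic = diagnostic)
}

#' Build a template-matching observer from a body set
#'
#' The observer holds one template per expression: the mean, over the bodies
#' of that expression, of the image content inside the diagnostic region
#' (background-subtracted, zero outside the region).  Responses correlate a
#' revealed stimulus with each template over the template's support, add
#' Gaussian internal noise, and take the argmax; with probability
#' `guess_rate` the response is replaced by a uniform guess.
#'
#' @param bodies a [make_body_set()] result covering all expressions.
#' @param internal_noise_sd standard deviation of the Gaussian noise added
#'   to each template correlation (correlation units).
#' @param guess_rate probability of a uniform random guess.
#' @param expressions expression labels the observer must cover; defaults
#'   to those present in `bodies`.
#' @return object of class `observer_template`.
#' @export
make_observer <- function(bodies, internal_noise_sd = 0.25, guess_rate = 0.05,
                          expressions = NULL) {
  stop_if_not(inherits(bodies, "body_set"), "bodies must be a body_set")
  stop_if_not(internal_noise_sd >= 0, "internal_noise_sd must be >= 0")
  stop_if_not(guess_rate >= 0 && guess_rate <= 1,
              "guess_rate must be in [0, 1]")
  have <- unique(vapply(bodies, function(b) b$emotion, character(1)))
  if (is.null(expressions)) expressions <- have
  missing <- setdiff(expressions, have)
  if (length(missing))
    stop("bodies do not cover expression(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  background <- attr(bodies, "background")
  templates <- lapply(expressions, function(e) {
    bs <- Filter(function(b) identical(b$emotion, e), bodies)
    support <- Reduce(`|`, lapply(bs, function(b) b$diagnostic_mask))
    tmpl <- Reduce(`+`, lapply(bs, function(b) (b$image - background) *
                                 b$diagnostic_mask)) / length(bs)
    list(support = support, values = tmpl[support])
  })
  names(templates) <- expressions
  structure(list(templates = templates, expressions = expressions,
                 internal_noise_sd = internal_noise_sd,
                 guess_rate = guess_rate),
            class = "observer_template")
}

#' Categorize a stimulus with a template-matching observer
#'
#' Scores each expression by the Pearson correlation between the stimulus
#' and that expression's template over the template support, perturbed by
#' internal Gaussian noise; returns the argmax (uniform tie-break).  With
#' probability `guess_rate` a uniform guess overrides the decision.  Uses
#' the current RNG stream.
#'
#' @param observer an [make_observer()] result.
#' @param stimulus numeric matrix with the template dimensions.
#' @param true_emotion optional true label, carried through for logging.
#' @return a single expression label.
#' @export
observer_respond <- function(observer, stimulus, true_emotion = NULL) {
  ex <- observer$expressions
  if (observer$guess_rate > 0 && stats::runif(1) < observer$guess_rate)
    return(sample(ex, 1))
  scores <- vapply(ex, function(e) {
    tpl <- observer$templates[[e]]
    s <- stimulus[tpl$support]
    if (stats::sd(s) < 1e-12 || stats::sd(tpl$values) < 1e-12) 0
    else stats::cor(s, tpl$values)
  }, numeric(1))
  if (observer$internal_noise_sd > 0)
    scores <- scores + stats::rnorm(length(scores), 0, observer$internal_noise_sd)
  top <- which(scores >= max(scores) - 1e-12)
  ex[if (length(top) > 1) sample(top, 1) else top]
}
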