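#' Write and read a Bubbles trial log
#'
#' The trial log is a plain CSV with one row per trial: trial, body_id,
#' expression, response, correct, per-band and total bubble counts, and
#' the session seed.
#'
#' @param session a [run_session()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(session, path) {
  log <- session$log
  log$seed <- session$seed
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @return for `read_trial_log`, the trial-log data frame.
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize an RDM as CSV with a JSON header sidecar
#'
#' The matrix goes to `<path>` as CSV (row names = condition order); the
#' sidecar `<path>.json` records the condition order, the RDM kind and any
#' seed.
#'
#' @param rdm an `rdm` matrix.
#' @param path output CSV path.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path, seed = NULL) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  meta <- list(conditions = rownames(rdm),
               kind = attr(rdm, "kind") %||% "true")
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rdm
#' @return for `read_rdm`, the `rdm` matrix (condition order and kind
#'   restored from the sidecar when present).
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  kind <- "true"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    kind <- meta$kind %||% kind
    m <- m[meta$conditions, meta$conditions]
  }
  structure(m, class = c("rdm", "matrix"), kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read long-format pattern tables
#'
#' CSV with columns subject, condition, voxel, value (see
#' [simulate_patterns()]).
#'
#' @param patterns long-format pattern data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_patterns <- function(patterns, path) {
  utils::write.csv(patterns, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a grayscale plane or a binary mask as PNG
#'
#' Planes are written as 8-bit grayscale; gray values are taken on the
#' 0--255 scale and masks as 0/255.
#'
#' @param plane numeric matrix (0--255) or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(plane, path) {
  if (is.logical(plane)) plane <- plane * 255
  png::writePNG(pmin(pmax(plane / 255, 0), 1), path)
  invisible(path)
}

#' Export a synthetic body set to a directory
#'
#' Writes each body image and its part/diagnostic masks as PNG, plus a
#' JSON sidecar naming the parts.
#'
#' @param bodies a [make_body_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_body_set <- function(bodies, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in bodies) {
    write_gray_png(b$image, file.path(dir, paste0(b$id, ".png")))
    for (p in names(b$part_masks))
      write_gray_png(b$part_masks[[p]],
                     file.path(dir, paste0(b$id, "_", p, ".png")))
    write_gray_png(b$diagnostic_mask,
                   file.path(dir, paste0(b$id, "_diagnostic.png")))
    jsonlite::write_json(
      list(id = b$id, emotion = b$emotion, actor = b$actor,
           parts = names(b$part_masks)),
      file.path(dir, paste0(b$id, ".json")), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a session configuration YAML, merging package defaults
#'
#' Recognized keys: image size, visual angle, band count, cycles per
#' bubble, staircase target/eta/bounds, smoothing sigma, cluster test t
#' and alpha.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return named list of configuration values.
#' @export
read_session_config <- function(path = NULL) {
  defaults <- list(
    width_px = 245, height_px = 310, width_deg = 5.47, height_deg = 6.90,
    n_bands = 5, cycles_per_bubble = 3,
    target_accuracy = 0.75, eta = 0.1, min_bubbles = 1, max_bubbles = 500,
    smooth_sigma_px = 8, t_threshold = 2.7, alpha = 0.05)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  stop_if_not(length(unknown) == 0,
              paste0("unknown configuration keys: ",
                     paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, user)
}
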