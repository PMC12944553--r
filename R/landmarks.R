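# 68-point facial landmark containers (iBUG convention, 0-based indices:
# jaw 0-16, brows 17-26, nose 27-35, eyes 36-47, mouth 48-67) and their
# CSV/JSON interchange formats.

#' Construct a single-frame landmark set
#'
#' @param points 68 x 2 numeric matrix of (x, y) pixel coordinates
#'   (x right, y down).
#' @param frame_index integer frame index (>= 0).
#' @return object of class `vacp_landmarks`.
#' @export
landmark_set <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != 68 || ncol(points) != 2)
    stop("a landmark set needs exactly 68 (x, y) points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  structure(list(points = unname(points),
                 frame_index = as.integer(frame_index)),
            class = "vacp_landmarks")
}

#' Construct a per-clip landmark sequence
#'
#' The backbone record of the pipeline: an ordered stream of 68-point
#' frames with clip metadata.
#'
#' @param frames list of [landmark_set()] objects with strictly increasing
#'   frame indices.
#' @param clip_id,subject_id identifiers.
#' @param emotion one of `"happy"`, `"sad"`, `"angry"`, `"neutral"`.
#' @param severity one of `"control"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param fps frames per second (> 0).
#' @return object of class `vacp_sequence`.
#' @export
landmark_sequence <- function(frames, clip_id, subject_id,
                              emotion = c("happy", "sad", "angry", "neutral"),
                              severity = c("control", "mild", "moderate",
                                           "severe"),
                              fps = 30) {
  emotion <- match.arg(emotion)
  severity <- match.arg(severity)
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a nonempty list of landmark sets", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "vacp_landmarks")))
    stop("all frames must be `vacp_landmarks`", call. = FALSE)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (any(diff(idx) <= 0))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (!is.finite(fps) || fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  structure(list(clip_id = clip_id, subject_id = subject_id,
                 emotion = emotion, severity = severity, fps = fps,
                 frames = frames),
            class = "vacp_sequence")
}

#' @export
print.vacp_sequence <- function(x, ...) {
  cat(sprintf("<vacp_sequence> clip %s | subject %s | %s/%s | %d frames @ %g fps (%.2f s)\n",
              x$clip_id, x$subject_id, x$emotion, x$severity,
              length(x$frames), x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.vacp_sequence <- function(x) length(x$frames)

# 68 x 2 coordinate matrix of frame i.
seq_points <- function(seq, i) seq$frames[[i]]$points

#' Facial region index sets
#'
#' Default 0-based iBUG-68 region definitions: brows 17-26, eyes 36-47,
#' nose 27-35, mouth 48-67, whole_face 17-67 (jaw excluded). Any region can
#' be overridden, e.g. to reproduce nonstandard groupings.
#'
#' @param overrides optional named list of integer index vectors (0-based).
#' @return named list of 0-based integer vectors with class
#'   `vacp_regions`.
#' @examples
#' length(face_regions()$eyes)  # 12
#' @export
face_regions <- function(overrides = NULL) {
  regions <- list(
    brows = 17:26,
    eyes = 36:47,
    nose = 27:35,
    mouth = 48:67,
    whole_face = 17:67
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      v <- as.integer(overrides[[nm]])
      if (anyDuplicated(v) || any(v < 0) || any(v > 67))
        stop("region indices must be unique and in [0, 67]", call. = FALSE)
      regions[[nm]] <- v
    }
  }
  structure(regions, class = "vacp_regions")
}

# 1-based row indices into the 68 x 2 matrix for a 0-based region spec.
region_rows <- function(region_idx) as.integer(region_idx) + 1L

#' Read a landmark stream from CSV
#'
#' Expected columns: `clip_id`, `frame`, `point_index` (0-67), `x`, `y`.
#' Metadata columns `subject_id`, `emotion`, `severity`, `fps` are honoured
#' when present (first value per clip), otherwise arguments supply them.
#'
#' @param path CSV file path.
#' @param ... defaults passed to [landmark_sequence()] for clips whose
#'   metadata is absent from the file.
#' @return list of [landmark_sequence()] objects, one per clip.
#' @export
read_landmarks_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_id", "frame", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$clip_id), function(d) {
    frames <- lapply(split(d, d$frame), function(fr) {
      fr <- fr[order(fr$point_index), ]
      if (!identical(as.integer(fr$point_index), 0:67))
        stop("each frame needs point_index 0..67 exactly once", call. = FALSE)
      landmark_set(cbind(fr$x, fr$y), frame_index = fr$frame[1])
    })
    frames <- frames[order(vapply(frames, `[[`, integer(1), "frame_index"))]
    meta <- list(...)
    for (m in c("subject_id", "emotion", "severity", "fps"))
      if (m %in% names(d)) meta[[m]] <- d[[m]][1]
    do.call(landmark_sequence,
            c(list(frames = frames, clip_id = d$clip_id[1]), meta))
  })
}

#' Write landmark sequences to CSV
#'
#' @param seqs list of [landmark_sequence()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    do.call(rbind, lapply(s$frames, function(f) {
      data.frame(clip_id = s$clip_id, subject_id = s$subject_id,
                 emotion = s$emotion, severity = s$severity, fps = s$fps,
                 frame = f$frame_index, point_index = 0:67,
                 x = f$points[, 1], y = f$points[, 2])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
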