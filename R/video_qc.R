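# Frame and clip quality control: luminance histograms, exposure flags,
# occlusion and duration filters applied before any feature extraction.

#' Luminance histogram of a grayscale frame
#'
#' Counts pixels at every gray level `b` in 0..255. The histogram is the
#' basis of the over/under-exposure rules used to discard badly lit clips.
#'
#' @param frame integer-valued matrix with entries in `[0, 255]`.
#' @return an object of class `vacp_lumhist` with fields `counts` (named
#'   integer vector of length 256), `width`, `height` and `n_total`.
#' @examples
#' h <- luminance_histogram(matrix(c(0, 0, 255, 128), 2, 2))
#' h$counts[["0"]]
#' @export
luminance_histogram <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("`frame` must be a nonempty matrix", call. = FALSE)
  v <- as.vector(frame)
  if (anyNA(v) || any(v != floor(v)) || any(v < 0) || any(v > 255))
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  names(counts) <- as.character(0:255)
  structure(
    list(counts = counts, width = ncol(frame), height = nrow(frame),
         n_total = length(v)),
    class = "vacp_lumhist"
  )
}

#' Assess frame exposure from a luminance histogram
#'
#' A frame is overexposed when the fraction of pixels at or above `t_high`
#' strictly exceeds `over_frac`, and underexposed when the fraction at or
#' below `t_low` strictly exceeds `under_frac`.
#'
#' @param hist a [luminance_histogram()] result.
#' @param t_high high-luminance gray level (default 250).
#' @param t_low low-luminance gray level (default 50; the low threshold is a
#'   configurable convention, see the methods vignette).
#' @param over_frac bright-pixel fraction above which a frame is flagged
#'   (default 0.05).
#' @param under_frac dark-pixel fraction above which a frame is flagged
#'   (default 0.10).
#' @return an object of class `vacp_exposure`: list with `p_high`, `p_low`,
#'   `overexposed`, `underexposed`, `t_high`, `t_low`.
#' @examples
#' h <- luminance_histogram(matrix(255L, 4, 4))
#' assess_exposure(h)$overexposed
#' @export
assess_exposure <- function(hist, t_high = 250L, t_low = 50L,
                            over_frac = 0.05, under_frac = 0.10) {
  stopifnot(inherits(hist, "vacp_lumhist"))
  if (!(t_low < t_high)) stop("`t_low` must be < `t_high`", call. = FALSE)
  if (over_frac <= 0 || over_frac >= 1 || under_frac <= 0 || under_frac >= 1)
    stop("exposure fractions must lie in (0, 1)", call. = FALSE)
  cnt <- hist$counts
  p_high <- sum(cnt[(t_high + 1L):256L]) / hist$n_total
  p_low <- sum(cnt[1L:(t_low + 1L)]) / hist$n_total
  structure(
    list(p_high = p_high, p_low = p_low,
         overexposed = p_high > over_frac, underexposed = p_low > under_frac,
         t_high = t_high, t_low = t_low),
    class = "vacp_exposure"
  )
}

#' Clip-level quality-control verdict
#'
#' Applies the clip retention rules: duration must lie in
#' `duration_range` seconds, at most `max_occluded` frames may be occluded,
#' and no sampled frame may be flagged for exposure. A clip is kept only if
#' all rules pass; failed rules are listed in `reasons`.
#'
#' @param clip_id clip identifier.
#' @param fps frames per second (> 0).
#' @param occluded logical vector, one flag per frame.
#' @param frames optional list of grayscale matrices; when given,
#'   `n_sample_frames` equally spaced frames are exposure-checked.
#' @param n_sample_frames number of frames sampled for exposure QC.
#' @param max_occluded maximum tolerated occluded frame count (default 10).
#' @param duration_range permitted clip duration in seconds (default `c(2, 6)`).
#' @param ... passed to [assess_exposure()].
#' @return object of class `vacp_clip_qc`: list with `clip_id`, `duration`,
#'   `n_occluded_frames`, `exposure` (per sampled frame), `keep`, `reasons`.
#' @export
apply_clip_filters <- function(clip_id, fps, occluded, frames = NULL,
                               n_sample_frames = 5L, max_occluded = 10L,
                               duration_range = c(2, 6), ...) {
  if (missing(fps) || is.null(fps) || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a positive number", call. = FALSE)
  stopifnot(is.logical(occluded), length(occluded) >= 1)
  n_frames <- length(occluded)
  duration <- n_frames / fps
  n_occ <- sum(occluded)
  reasons <- character(0)
  if (duration < duration_range[1] || duration > duration_range[2])
    reasons <- c(reasons, "duration")
  if (n_occ > max_occluded)
    reasons <- c(reasons, "occlusion")
  exposure <- NULL
  if (!is.null(frames) && length(frames) > 0) {
    pick <- unique(round(seq(1L, length(frames),
                             length.out = min(n_sample_frames, length(frames)))))
    exposure <- lapply(frames[pick],
                       function(f) assess_exposure(luminance_histogram(f), ...))
    if (any(vapply(exposure, function(e) e$overexposed || e$underexposed,
                   logical(1))))
      reasons <- c(reasons, "exposure")
  }
  structure(
    list(clip_id = clip_id, duration = duration, n_occluded_frames = n_occ,
         exposure = exposure, keep = length(reasons) == 0L, reasons = reasons),
    class = "vacp_clip_qc"
  )
}

#' Convert an RGB array to grayscale (BT.601 luma)
#'
#' @param rgb numeric array `h x w x 3` with values in `[0, 255]`.
#' @return integer-valued grayscale matrix (rounded luma).
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
}

#' @export
print.vacp_clip_qc <- function(x, ...) {
  cat(sprintf("clip %s: %.2f s, %d occluded frame(s) -> %s\n",
              x$clip_id, x$duration, x$n_occluded_frames,
              if (x$keep) "keep" else paste("drop:",
                                            paste(x$reasons, collapse = ", "))))
  invisible(x)
}
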