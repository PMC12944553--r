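# Motion-amplitude keyframe (apex) annotation: neutral reference set,
# per-region relative length changes, overall amplitude, smoothing,
# end-trimming, top-5 peak selection, and MAE evaluation.

#' Build a neutral reference frame set
#'
#' Extracts five frames at equal intervals (indices `round(k*(T-1)/4)`,
#' `k = 0..4`, 0-based) from a neutral-emotion clip and averages their
#' region reference lengths to form the per-region baselines `L0`.
#'
#' @param neutral a [landmark_sequence()] with at least 5 frames (typically
#'   `emotion == "neutral"`).
#' @return object of class `vacp_reference`: list with `frames` (the five
#'   [landmark_set()]s), `frame_positions` (1-based positions used), and
#'   `L0` (named numeric: nose, mouth, left_eye, right_eye).
#' @export
build_reference <- function(neutral) {
  stopifnot(inherits(neutral, "vacp_sequence"))
  n <- length(neutral$frames)
  if (n < 5) stop("a reference clip needs at least 5 frames", call. = FALSE)
  pos <- round((0:4) * (n - 1) / 4) + 1L
  frames <- neutral$frames[pos]
  lens <- t(vapply(frames, function(f) anchor_points(f)$lengths, numeric(4)))
  L0 <- colMeans(lens)
  if (any(L0 <= 0))
    stop("degenerate geometry: nonpositive reference length", call. = FALSE)
  structure(list(frames = frames, frame_positions = pos, L0 = L0),
            class = "vacp_reference")
}

#' Per-frame motion amplitude of a clip
#'
#' For each frame t and region X in {nose, mouth, left_eye, right_eye},
#' computes the relative length change
#' `Delta_t^X = |L_t^X - L0^X| / L0^X`, averages the four regions into
#' `Amplitude(t)`, smooths with a centered moving average (reflect
#' padding), and marks the first and last `trim_frac` of frames as
#' ineligible for keyframe candidacy.
#'
#' @param seq a [landmark_sequence()].
#' @param ref a [build_reference()] result.
#' @param smooth_window odd moving-average window in frames (default 9,
#'   i.e. 0.3 s at 30 fps).
#' @param trim_frac fraction of frames trimmed at each end (default 0.3,
#'   must be in `[0, 0.5)`).
#' @return object of class `vacp_amplitude`: list with `frame_index`,
#'   `delta` (T x 4 matrix), `amplitude`, `smoothed`, `candidate`
#'   (logical mask), `clip_id`, `smooth_window`.
#' @export
amplitude_series <- function(seq, ref, smooth_window = 9L, trim_frac = 0.3) {
  stopifnot(inherits(seq, "vacp_sequence"), inherits(ref, "vacp_reference"))
  if (trim_frac < 0 || trim_frac >= 0.5)
    stop("`trim_frac` must lie in [0, 0.5)", call. = FALSE)
  L0 <- ref$L0
  lens <- t(vapply(seq$frames, function(f) anchor_points(f)$lengths,
                   numeric(4)))
  delta <- sweep(abs(sweep(lens, 2, L0)), 2, L0, "/")
  colnames(delta) <- names(L0)
  amplitude <- rowMeans(delta)
  smoothed <- smooth_moving_average(amplitude, smooth_window)
  n <- length(amplitude)
  cut <- floor(n * trim_frac)
  candidate <- rep(TRUE, n)
  if (cut > 0) {
    candidate[seq_len(cut)] <- FALSE
    candidate[(n - cut + 1L):n] <- FALSE
  }
  structure(list(frame_index = vapply(seq$frames, `[[`, integer(1),
                                      "frame_index"),
                 delta = delta, amplitude = amplitude, smoothed = smoothed,
                 candidate = candidate, clip_id = seq$clip_id,
                 smooth_window = as.integer(smooth_window)),
            class = "vacp_amplitude")
}

#' Select the keyframes of a clip
#'
#' Picks the `k` highest smoothed-amplitude local peaks among candidate
#' (untrimmed) frames, enforcing a pairwise index gap of at least
#' `min_gap`; ties break toward the earlier frame. If fewer than `k` local
#' peaks exist, the remaining slots are filled with the next-highest
#' candidate frames (gap still enforced, then relaxed as a last resort).
#' When fewer than `k` candidate frames exist, all of them are returned
#' with a warning.
#'
#' @param series a [amplitude_series()] result.
#' @param k number of keyframes (default 5).
#' @param min_gap minimum index gap between selected frames; default
#'   `max(3, ceiling(0.05 * T))`.
#' @return object of class `vacp_keyframes`: list with `clip_id`,
#'   `frames` (selected frame indices, increasing), `positions` (1-based
#'   positions in the series), `amplitudes` (smoothed amplitude at
#'   selection), `top_frame` (selected frame with maximal smoothed
#'   amplitude).
#' @export
select_keyframes <- function(series, k = 5L, min_gap = NULL) {
  stopifnot(inherits(series, "vacp_amplitude"))
  n <- length(series$amplitude)
  if (is.null(min_gap)) min_gap <- max(3L, ceiling(0.05 * n))
  cand <- which(series$candidate)
  if (length(cand) == 0)
    stop("no candidate frames survive trimming", call. = FALSE)
  s <- series$smoothed
  is_peak <- vapply(cand, function(i) {
    left <- if (i > 1) s[i - 1] else -Inf
    right <- if (i < n) s[i + 1] else -Inf
    s[i] > left && s[i] >= right  # strict rise, plateau breaks to the left
  }, logical(1))
  pick_greedy <- function(pool, chosen, quota, enforce_gap = TRUE) {
    ord <- pool[order(-s[pool], pool)]
    for (i in ord) {
      if (length(chosen) >= quota) break
      if (!enforce_gap || all(abs(i - chosen) >= min_gap) ||
          length(chosen) == 0)
        chosen <- c(chosen, i)
    }
    chosen
  }
  chosen <- pick_greedy(cand[is_peak], integer(0), k)
  if (length(chosen) < k)
    chosen <- pick_greedy(setdiff(cand, chosen), chosen, k)
  if (length(chosen) < k && length(cand) >= k)
    chosen <- pick_greedy(setdiff(cand, chosen), chosen, k,
                          enforce_gap = FALSE)
  if (length(chosen) < k)
    warning(sprintf("clip %s: only %d candidate frame(s) available for %d keyframe slots",
                    series$clip_id, length(chosen), k))
  chosen <- sort(chosen)
  structure(list(clip_id = series$clip_id,
                 frames = series$frame_index[chosen],
                 positions = chosen,
                 amplitudes = s[chosen],
                 top_frame = series$frame_index[chosen[which.max(s[chosen])]]),
            class = "vacp_keyframes")
}

#' Mean absolute error of apex predictions
#'
#' `MAE = (1/N) * sum(|e_i|)` where `e_i` is the frame error between the
#' predicted and annotated apex of sample i.
#'
#' @param predicted,truth equal-length numeric vectors of apex frame
#'   indices.
#' @return object of class `vacp_mae`: list with `errors`, `mae`, `n`.
#' @examples
#' evaluate_mae(c(10, 20), c(12, 17))$mae  # 2.5
#' @export
evaluate_mae <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) == 0)
    stop("`predicted` and `truth` must be nonempty and of equal length",
         call. = FALSE)
  e <- as.numeric(predicted) - as.numeric(truth)
  structure(list(errors = e, mae = mean(abs(e)), n = length(e)),
            class = "vacp_mae")
}

#' @export
print.vacp_keyframes <- function(x, ...) {
  cat(sprintf("clip %s keyframes: %s (top %d)\n", x$clip_id,
              paste(x$frames, collapse = ", "), x$top_frame))
  invisible(x)
}

#' Plot an amplitude series and its selected keyframes
#'
#' @param x a [amplitude_series()] result.
#' @param keyframes optional [select_keyframes()] result to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vacp_amplitude <- function(x, keyframes = NULL, ...) {
  graphics::plot(x$frame_index, x$amplitude, type = "l", col = "grey60",
                 xlab = "frame", ylab = "amplitude",
                 main = paste("clip", x$clip_id), ...)
  graphics::lines(x$frame_index, x$smoothed, col = "black", lwd = 2)
  trimmed <- !x$candidate
  if (any(trimmed))
    graphics::rug(x$frame_index[trimmed], col = "grey80")
  if (!is.null(keyframes))
    graphics::abline(v = keyframes$frames, col = "red3", lty = 2)
  invisible(x)
}
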