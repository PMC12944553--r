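# Anchor points, angular pose measures (phi, gamma), similarity alignment
# to a 200 px canonical frame, and alignment-quality reporting.

# 1-based row helpers for the named anchor landmarks (0-based ids in docs).
LM <- function(points, idx0) points[idx0 + 1L, , drop = FALSE]

#' Anchor points and reference lengths of a landmark set
#'
#' Computes the four region centers and reference lengths used by the
#' motion-amplitude measure:
#' * nose center = landmark 30; nasal length =
#'   `dist(nc, 27) + dist(nc, 31) + dist(nc, 35)`
#' * mouth center = midpoint of 48 and 54; oral length =
#'   `dist(mc, 48) + dist(mc, 54)`
#' * eye centers = midpoints of (36, 39) and (42, 45); eye lengths =
#'   sum of distances from the center to the two corners.
#'
#' @param lm a [landmark_set()].
#' @return list with `centers` (named list of length-2 vectors) and
#'   `lengths` (named numeric: `nose`, `mouth`, `left_eye`, `right_eye`).
#' @examples
#' p <- matrix(0, 68, 2); p[, 1] <- seq_len(68); p[, 2] <- rev(seq_len(68))
#' anchor_points(landmark_set(p))$lengths
#' @export
anchor_points <- function(lm) {
  stopifnot(inherits(lm, "vacp_landmarks"))
  p <- lm$points
  nc <- as.numeric(LM(p, 30))
  mc <- as.numeric((LM(p, 48) + LM(p, 54)) / 2)
  lec <- as.numeric((LM(p, 36) + LM(p, 39)) / 2)
  rec <- as.numeric((LM(p, 42) + LM(p, 45)) / 2)
  lengths <- c(
    nose = euclid(nc, LM(p, 27)) + euclid(nc, LM(p, 31)) + euclid(nc, LM(p, 35)),
    mouth = euclid(mc, LM(p, 48)) + euclid(mc, LM(p, 54)),
    left_eye = euclid(lec, LM(p, 36)) + euclid(lec, LM(p, 39)),
    right_eye = euclid(rec, LM(p, 42)) + euclid(rec, LM(p, 45))
  )
  if (any(lengths <= 0))
    stop("degenerate geometry: coincident anchor landmarks", call. = FALSE)
  list(centers = list(nose = nc, mouth = mc, left_eye = lec, right_eye = rec),
       lengths = lengths)
}

# Signed angle (degrees, in (-90, 90]) of the segment a -> b against the
# horizontal (image x axis, y down).
angle_to_horizontal <- function(a, b) {
  d <- b - a
  if (all(abs(d) < .Machine$double.eps))
    stop("degenerate geometry: zero-length defining segment", call. = FALSE)
  ang <- atan2(d[2], d[1]) * 180 / pi
  # fold to (-90, 90]: the line, not the direction, carries the pose
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Pose angles phi and gamma of a landmark set
#'
#' `phi` is the signed angle between the line through the two eye centers
#' and the horizontal; `gamma` is the signed angle between the nose-bridge
#' line (landmarks 27 to 30) and the vertical. Both are in degrees, in
#' `(-90, 90]`.
#'
#' @param lm a [landmark_set()].
#' @return named numeric vector `c(phi = , gamma = )`.
#' @export
compute_phi_gamma <- function(lm) {
  stopifnot(inherits(lm, "vacp_landmarks"))
  p <- lm$points
  lec <- as.numeric((LM(p, 36) + LM(p, 39)) / 2)
  rec <- as.numeric((LM(p, 42) + LM(p, 45)) / 2)
  phi <- angle_to_horizontal(lec, rec)
  brg <- as.numeric(LM(p, 30)) - as.numeric(LM(p, 27))
  if (all(abs(brg) < .Machine$double.eps))
    stop("degenerate geometry: zero-length nose bridge", call. = FALSE)
  gamma <- atan2(brg[1], brg[2]) * 180 / pi  # angle vs vertical (y down)
  if (gamma <= -90) gamma <- gamma + 180
  if (gamma > 90) gamma <- gamma - 180
  c(phi = phi, gamma = gamma)
}

#' Align a face to the 200 px canonical frame
#'
#' Applies the similarity transform (rotation by `-phi` about the
#' inter-ocular midpoint, uniform scale, translation) that puts both eye
#' centers on a horizontal line, maps the inter-ocular distance to
#' `eye_frac * size` pixels, and centers the eye midline at
#' (`size/2`, `0.4 * size`). When an image is supplied it is resampled with
#' the same transform (bilinear inverse warp) to a `size x size` canvas.
#'
#' @param lm a [landmark_set()].
#' @param image optional grayscale matrix in source coordinates.
#' @param size output canvas side in pixels (default 200).
#' @param eye_frac inter-ocular distance as a fraction of `size`
#'   (default 0.4).
#' @param normalize_gray min-max stretch the image to `[0, 255]` before
#'   warping (default TRUE).
#' @return object of class `vacp_aligned`: list with `landmarks` (aligned
#'   [landmark_set()]), `phi`, `gamma` (post-alignment angles), `image`
#'   (or NULL), `transform` (list `R`, `s`, `t` mapping source to aligned).
#' @export
align_face <- function(lm, image = NULL, size = 200L, eye_frac = 0.4,
                       normalize_gray = TRUE) {
  stopifnot(inherits(lm, "vacp_landmarks"))
  p <- lm$points
  lec <- as.numeric((LM(p, 36) + LM(p, 39)) / 2)
  rec <- as.numeric((LM(p, 42) + LM(p, 45)) / 2)
  iod <- euclid(lec, rec)
  if (iod < .Machine$double.eps)
    stop("degenerate geometry: coincident eye centers", call. = FALSE)
  mid <- (lec + rec) / 2
  phi_rad <- atan2(rec[2] - lec[2], rec[1] - lec[1])
  s <- eye_frac * size / iod
  R <- matrix(c(cos(-phi_rad), -sin(-phi_rad),
                sin(-phi_rad), cos(-phi_rad)), 2, 2, byrow = TRUE)
  target_mid <- c(size / 2, 0.4 * size)
  # aligned = s * R (x - mid) + target_mid
  q <- t(s * (R %*% t(sweep(p, 2, mid))) + target_mid)
  out_lm <- landmark_set(q, frame_index = lm$frame_index)
  ang <- compute_phi_gamma(out_lm)
  img <- NULL
  if (!is.null(image)) {
    stopifnot(is.matrix(image))
    if (normalize_gray) image <- normalize_grayscale(image)
    img <- warp_similarity(image, R = R, s = s, center = mid,
                           target = target_mid, size = size)
  }
  structure(list(landmarks = out_lm, phi = unname(ang["phi"]),
                 gamma = unname(ang["gamma"]), image = img,
                 transform = list(R = R, s = s, center = mid,
                                  target = target_mid)),
            class = "vacp_aligned")
}

#' Min-max grayscale normalization
#'
#' Linearly stretches a frame to `[0, 255]`; a constant frame maps to 0.
#'
#' @param frame numeric matrix.
#' @return numeric matrix in `[0, 255]`.
#' @export
normalize_grayscale <- function(frame) {
  rng <- range(frame)
  if (diff(rng) == 0) return(matrix(0, nrow(frame), ncol(frame)))
  (frame - rng[1]) / diff(rng) * 255
}

# Bilinear inverse warp of `image` under aligned = s R (x - center) + target.
# Output pixel (r, c) maps to source x = center + R' (q - target) / s with
# q = (c, r) in (x, y) convention; out-of-range samples take the border value.
warp_similarity <- function(image, R, s, center, target, size) {
  h <- nrow(image); w <- ncol(image)
  grid <- expand.grid(col = seq_len(size), row = seq_len(size))
  q <- rbind(grid$col - target[1], grid$row - target[2])
  src <- (t(R) %*% q) / s + center
  x <- pmin(pmax(src[1, ], 1), w)
  y <- pmin(pmax(src[2, ], 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  at <- function(r, c) image[cbind(r, c)]
  val <- at(y0, x0) * (1 - fx) * (1 - fy) + at(y0, x0 + 1) * fx * (1 - fy) +
    at(y0 + 1, x0) * (1 - fx) * fy + at(y0 + 1, x0 + 1) * fx * fy
  matrix(val, nrow = size, ncol = size, byrow = TRUE)
}

#' Alignment-quality report
#'
#' Per-subject mean and variance of the pose angles phi and gamma before and
#' after alignment, the standard verification that alignment tightened the
#' pose distribution.
#'
#' @param before,after lists of [landmark_sequence()] objects, matched by
#'   clip id (same clips, landmarks in source vs aligned coordinates).
#' @return data.frame with one row per subject: `subject_id`,
#'   `phi_mean_before`, `phi_var_before`, `phi_mean_after`, `phi_var_after`,
#'   and the four `gamma_*` analogues. Means/variances are over the absolute
#'   angles of all frames of the subject.
#' @export
alignment_report <- function(before, after) {
  collect <- function(seqs) {
    do.call(rbind, lapply(seqs, function(s) {
      ang <- t(vapply(s$frames, compute_phi_gamma, numeric(2)))
      data.frame(subject_id = s$subject_id, phi = abs(ang[, "phi"]),
                 gamma = abs(ang[, "gamma"]))
    }))
  }
  db <- collect(before); da <- collect(after)
  subjects <- unique(db$subject_id)
  out <- do.call(rbind, lapply(subjects, function(sj) {
    b <- db[db$subject_id == sj, ]; a <- da[da$subject_id == sj, ]
    var0 <- function(x) if (length(x) > 1) stats::var(x) else 0
    data.frame(subject_id = sj,
               phi_mean_before = mean(b$phi), phi_var_before = var0(b$phi),
               phi_mean_after = mean(a$phi), phi_var_after = var0(a$phi),
               gamma_mean_before = mean(b$gamma),
               gamma_var_before = var0(b$gamma),
               gamma_mean_after = mean(a$gamma),
               gamma_var_after = var0(a$gamma))
  }))
  rownames(out) <- NULL
  out
}
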