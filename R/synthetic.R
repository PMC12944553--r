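# Seeded synthetic cohort generator: emotion-specific action-unit drives
# deform a canonical 68-point face along fixed per-AU displacement fields,
# scaled by severity (perioral AUs decrease stepwise with severity; the
# brow/eyelid AU4/AU7 pattern under negative emotions is non-monotonic,
# severe > moderate), under a rise-peak-fall temporal envelope with a
# recorded apex, landmark jitter, global pose perturbations, a static
# severity-scaled mouth-corner droop (resting facial asymmetry), and
# class-conditioned acoustic feature shifts. All ground truth (apex frames,
# AU drive signals, labels) is retained.

#' Canonical 68-point mean face shape
#'
#' A synthetic neutral face template on the 200 px canvas (iBUG-68
#' ordering, x right, y down), built from geometric primitives; it is not
#' derived from any face dataset.
#'
#' @return 68 x 2 numeric matrix.
#' @export
mean_face_shape <- function() {
  p <- matrix(NA_real_, 68, 2)
  u <- seq(0, pi, length.out = 17)
  p[1:17, ] <- cbind(100 - 60 * cos(u), 100 + 88 * sin(u))       # jaw 0-16
  bx <- seq(55, 92, length.out = 5)
  p[18:22, ] <- cbind(bx, 72 - 6 * sin(seq(0, pi, length.out = 5)))  # brow L
  p[23:27, ] <- cbind(216 - rev(bx), 72 - 6 * sin(seq(0, pi, length.out = 5)))
  p[23:27, 1] <- seq(108, 145, length.out = 5)                   # brow R
  p[28:31, ] <- cbind(rep(100, 4), seq(78, 114, length.out = 4)) # bridge 27-30
  p[32:36, ] <- cbind(c(88, 94, 100, 106, 112),
                      c(122, 124, 126, 124, 122))                # nostrils 31-35
  p[37:42, ] <- cbind(c(60, 67, 75, 82, 75, 67),
                      c(90, 86, 86, 90, 94, 94))                 # left eye 36-41
  p[43:48, ] <- cbind(c(118, 125, 133, 140, 133, 125),
                      c(90, 86, 86, 90, 94, 94))                 # right eye 42-47
  p[49:60, ] <- cbind(c(78, 85, 93, 100, 107, 115, 122,
                        115, 107, 100, 93, 85),
                      c(148, 143, 140, 141, 140, 143, 148,
                        154, 158, 159, 158, 154))                # outer lips 48-59
  p[61:68, ] <- cbind(c(82, 93, 100, 107, 118, 107, 100, 93),
                      c(148, 146, 147, 146, 148, 151, 152, 151)) # inner lips 60-67
  p
}

# Sparse per-AU displacement fields: 68 x 2 matrices in pixels at full
# intensity (5). Indices in comments are 0-based landmark ids.
au_displacement_fields <- function() {
  f <- function(...) {
    rows <- list(...)
    m <- matrix(0, 68, 2)
    for (r in rows) m[r[[1]] + 1L, ] <- m[r[[1]] + 1L, ] + c(r[[2]], r[[3]])
    m
  }
  list(
    AU01 = f(list(21, 0, -3), list(22, 0, -3), list(20, 0, -1.5),
             list(23, 0, -1.5)),                       # inner brow raiser
    AU02 = f(list(17, 0, -2.5), list(18, 0, -2.5), list(25, 0, -2.5),
             list(26, 0, -2.5)),                       # outer brow raiser
    AU04 = f(list(19, 0.5, 2.5), list(20, 1, 3), list(21, 2, 3.5),
             list(22, -2, 3.5), list(23, -1, 3), list(24, -0.5, 2.5)),
    AU05 = f(list(37, 0, -1.5), list(38, 0, -1.5), list(43, 0, -1.5),
             list(44, 0, -1.5)),                       # upper lid raiser
    AU06 = f(list(40, 0, -1.5), list(41, 0, -1.5), list(46, 0, -1.5),
             list(47, 0, -1.5), list(1, 0, -1), list(15, 0, -1),
             list(36, 0.5, -0.3), list(39, -0.5, -0.3),
             list(42, 0.5, -0.3), list(45, -0.5, -0.3)),
    AU07 = f(list(37, 0, 1.2), list(38, 0, 1.2), list(40, 0, -1.2),
             list(41, 0, -1.2), list(43, 0, 1.2), list(44, 0, 1.2),
             list(46, 0, -1.2), list(47, 0, -1.2),
             list(36, 1, 0), list(39, -1, 0),
             list(42, 1, 0), list(45, -1, 0)),         # lid tightener
    AU09 = f(list(31, 0, -2), list(32, 0, -2), list(33, 0, -2),
             list(34, 0, -2), list(35, 0, -2)),        # nose wrinkler
    AU10 = f(list(50, 0, -2), list(51, 0, -2), list(52, 0, -2),
             list(61, 0, -1.5), list(62, 0, -1.5), list(63, 0, -1.5)),
    AU12 = f(list(48, -8, -4), list(54, 8, -4), list(49, -3, -2),
             list(53, 3, -2), list(59, -3, -2), list(55, 3, -2),
             list(60, -3, -2), list(64, 3, -2)),       # lip corner puller
    AU14 = f(list(48, 2, -1), list(54, -2, -1)),       # dimpler
    AU15 = f(list(48, 8, 4), list(54, -8, 4), list(59, 0, 2),
             list(55, 0, 2)),            # corner depressor (down + medial)
    AU17 = f(list(56, 0, -2), list(57, 0, -2), list(58, 0, -2),
             list(8, 0, -2)),                          # chin raiser
    AU20 = f(list(48, -4, 1), list(54, 4, 1)),         # lip stretcher
    AU23 = f(list(48, 6, 0), list(54, -6, 0), list(49, 2, 0),
             list(53, -2, 0), list(59, 2, 0), list(55, -2, 0),
             list(60, 2, 0), list(64, -2, 0)),         # lip tightener
    AU25 = f(list(61, 0, -1.5), list(62, 0, -1.5), list(63, 0, -1.5),
             list(65, 0, 1.5), list(66, 0, 1.5), list(67, 0, 1.5)),
    AU26 = f(list(7, 0, 4), list(8, 0, 4), list(9, 0, 4), list(56, 0, 3),
             list(57, 0, 3), list(58, 0, 3), list(65, 0, 2.5),
             list(66, 0, 2.5), list(67, 0, 2.5)),      # jaw drop
    AU28 = f(list(60, 1.5, 0), list(64, -1.5, 0), list(61, 0.5, 0.5),
             list(63, -0.5, 0.5), list(65, -0.5, -0.5),
             list(67, 0.5, -0.5)),                     # lip suck
    AU45 = f(list(37, 0, 2.5), list(38, 0, 2.5), list(40, 0, -2.5),
             list(41, 0, -2.5), list(43, 0, 2.5), list(44, 0, 2.5),
             list(46, 0, -2.5), list(47, 0, -2.5))     # blink
  )
}

# One-sided resting droop (central facial asymmetry), per px of droop.
# The jaw share is AU-free in the emotion recipes, so it stays a clean
# severity marker in emotional clips too.
droop_field <- function() {
  m <- matrix(0, 68, 2)
  m[c(54, 55, 53, 64) + 1L, 2] <- 1        # right mouth corner region
  m[c(10, 11, 12, 13) + 1L, 2] <- 0.5      # right lower jaw
  m[(22:26) + 1L, 2] <- 0.2                # right brow
  m
}

# Peak AU intensities per emotion; `scale` says which severity profile
# modulates the AU ("mouth" = stepwise decrease, "eye" = the non-monotonic
# negative-emotion profile, "fixed" = severity-independent).
emotion_recipes <- function() {
  list(
    happy = data.frame(au = c("AU06", "AU12", "AU25"),
                       peak = c(3.0, 3.5, 1.5),
                       scale = c("mouth", "mouth", "mouth")),
    angry = data.frame(au = c("AU04", "AU07", "AU23"),
                       peak = c(3.0, 2.8, 2.0),
                       scale = c("eye", "eye", "mouth")),
    sad = data.frame(au = c("AU01", "AU15", "AU04", "AU07"),
                     peak = c(1.0, 2.5, 1.2, 1.5),
                     scale = c("fixed", "mouth", "eye", "eye")),
    neutral = data.frame(au = character(0), peak = numeric(0),
                         scale = character(0))
  )
}

#' Synthetic cohort configuration
#'
#' Defaults encode the emulated study conditions: 30 fps clips of 2-6 s,
#' four emotions (happy, sad, angry, neutral), four balanced severity
#' classes, a stepwise perioral amplitude decrease with severity, the
#' non-monotonic brow/eyelid profile under negative emotions
#' (severe > moderate), a severity-scaled resting mouth droop, 0.5 px
#' landmark jitter, 2 degree pose jitter, an apex in the middle 40% of the
#' clip, and moderate class-conditioned acoustic shifts.
#'
#' @param n_subjects_per_class subjects per severity class (default 5).
#' @param clips_per_subject clips per subject (default 10; emotions are
#'   cycled so every subject has at least one neutral clip).
#' @param fps frames per second (default 30).
#' @param duration_range clip duration range in seconds, within `[2, 6]`.
#' @param landmark_jitter_sd per-coordinate Gaussian landmark noise (px).
#' @param pose_jitter_sd global rotation jitter (degrees).
#' @param apex_range apex position as a fraction of the clip.
#' @param mouth_scale named severity multipliers for perioral AUs.
#' @param eye_negative_scale named severity multipliers for AU4/AU7 under
#'   anger and sadness.
#' @param droop_px named resting mouth-corner droop per class (px).
#' @param subject_amp_sd relative SD of the per-subject amplitude effect.
#' @param droop_sd SD of the per-subject droop deviation (px).
#' @param acoustic_shift per-severity-step mean shift (SD units) on the
#'   shifted acoustic slots.
#' @param n_acoustic_slots number of acoustic slots carrying the shift.
#' @param acoustic_noise_sd per-clip acoustic noise SD.
#' @param acoustic_subject_sd per-subject acoustic offset SD.
#' @param seed mandatory integer seed.
#' @return list of class `vacp_cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_class = 5L, clips_per_subject = 10L,
                          fps = 30, duration_range = c(2, 6),
                          landmark_jitter_sd = 0.5, pose_jitter_sd = 2,
                          apex_range = c(0.35, 0.6),
                          mouth_scale = c(control = 1, mild = 0.75,
                                          moderate = 0.5, severe = 0.3),
                          eye_negative_scale = c(control = 1, mild = 0.65,
                                                 moderate = 0.45,
                                                 severe = 0.7),
                          droop_px = c(control = 0, mild = 1.5,
                                       moderate = 2.8, severe = 4),
                          subject_amp_sd = 0.05, droop_sd = 0.3,
                          acoustic_shift = 0.85, n_acoustic_slots = 12L,
                          acoustic_noise_sd = 1, acoustic_subject_sd = 0.2,
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (duration_range[1] < 2 || duration_range[2] > 6 ||
      duration_range[1] > duration_range[2])
    stop("`duration_range` must lie within [2, 6] seconds", call. = FALSE)
  stopifnot(landmark_jitter_sd >= 0, pose_jitter_sd >= 0,
            n_subjects_per_class >= 1, clips_per_subject >= 1)
  structure(as.list(environment()), class = "vacp_cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given `cfg$seed`. Each clip carries its landmark sequence,
#' the planted apex frame (NA for neutral clips), the per-frame AU drive
#' matrix (0-5 scale), and an 88-slot acoustic vector with class-conditioned
#' shifts.
#'
#' @param cfg a [cohort_config()].
#' @return object of class `vacp_cohort`: list with `clips` (each a list
#'   `seq`, `apex`, `drives`, `acoustic`), `config`, `manifest`
#'   (data.frame).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "vacp_cohort_config"))
  base <- mean_face_shape()
  fields <- au_displacement_fields()
  slots <- au_slots()
  recipes <- emotion_recipes()
  droopf <- droop_field()
  severities <- c("control", "mild", "moderate", "severe")
  prefix <- c(control = "C", mild = "m", moderate = "M", severe = "S")
  emotions <- c("happy", "sad", "angry", "neutral")
  shift_slots <- round(seq(3, 86, length.out = cfg$n_acoustic_slots))
  clips <- list()
  with_seed(cfg$seed, {
    for (sev in severities) {
      sev_idx <- match(sev, severities) - 1L
      for (sj in seq_len(cfg$n_subjects_per_class)) {
        subject_id <- sprintf("%s%02d", prefix[sev], sj)
        amp_subj <- 1 + stats::rnorm(1, 0, cfg$subject_amp_sd)
        droop_subj <- max(0, cfg$droop_px[sev] + stats::rnorm(1, 0, cfg$droop_sd))
        ac_subj <- stats::rnorm(88, 0, cfg$acoustic_subject_sd)
        emo_cycle <- rep(emotions, length.out = cfg$clips_per_subject)
        for (ci in seq_len(cfg$clips_per_subject)) {
          emotion <- emo_cycle[ci]
          clip_id <- sprintf("%s_c%02d_%s", subject_id, ci, emotion)
          dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
          n <- max(ceiling(2 * cfg$fps),
                   min(floor(6 * cfg$fps), round(dur * cfg$fps)))
          rec <- recipes[[emotion]]
          drives <- matrix(0, n, length(slots$intensity),
                           dimnames = list(NULL, slots$intensity))
          apex <- NA_integer_
          if (nrow(rec) > 0) {
            apex_pos <- round(stats::runif(1, cfg$apex_range[1],
                                           cfg$apex_range[2]) * (n - 1)) + 1L
            env <- exp(-0.5 * ((seq_len(n) - apex_pos) / (0.07 * n))^2)
            for (r in seq_len(nrow(rec))) {
              sc <- switch(rec$scale[r],
                           mouth = cfg$mouth_scale[sev],
                           eye = cfg$eye_negative_scale[sev],
                           fixed = 1)
              drives[, rec$au[r]] <- pmin(5, pmax(0,
                rec$peak[r] * sc * amp_subj * env))
            }
            apex <- apex_pos - 1L  # frame indices are 0-based
          }
          theta0 <- stats::rnorm(1, 0, cfg$pose_jitter_sd)
          frames <- vector("list", n)
          for (t in seq_len(n)) {
            pts <- base + droop_subj * droopf
            active <- which(drives[t, ] > 0)
            for (a in active)
              pts <- pts + drives[t, a] / 5 * fields[[slots$intensity[a]]]
            th <- (theta0 + stats::rnorm(1, 0, cfg$pose_jitter_sd / 4)) * pi / 180
            R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                        byrow = TRUE)
            ctr <- colMeans(pts)
            pts <- t(R %*% t(sweep(pts, 2, ctr))) + rep(ctr, each = 68)
            if (cfg$landmark_jitter_sd > 0)
              pts <- pts + matrix(stats::rnorm(136, 0, cfg$landmark_jitter_sd),
                                  68, 2)
            frames[[t]] <- landmark_set(pts, frame_index = t - 1L)
          }
          acoustic <- stats::rnorm(88, 0, cfg$acoustic_noise_sd) + ac_subj
          acoustic[shift_slots] <- acoustic[shift_slots] +
            cfg$acoustic_shift * sev_idx
          clips[[clip_id]] <- list(
            seq = landmark_sequence(frames, clip_id = clip_id,
                                    subject_id = subject_id,
                                    emotion = emotion, severity = sev,
                                    fps = cfg$fps),
            apex = apex,
            drives = drives,
            acoustic = new_acoustic_feature(acoustic, clip_id))
        }
      }
    }
  })
  manifest <- do.call(rbind, lapply(clips, function(cl)
    data.frame(clip_id = cl$seq$clip_id, subject_id = cl$seq$subject_id,
               emotion = cl$seq$emotion, severity = cl$seq$severity,
               n_frames = length(cl$seq$frames), fps = cl$seq$fps,
               apex = cl$apex)))
  rownames(manifest) <- NULL
  structure(list(clips = clips, config = cfg, manifest = manifest),
            class = "vacp_cohort")
}

#' @export
print.vacp_cohort <- function(x, ...) {
  cat(sprintf("<vacp_cohort> %d clips | %d subjects | seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              x$config$seed))
  print(table(x$manifest$severity, x$manifest$emotion))
  invisible(x)
}

# Vectorized even-odd point-in-polygon (ray casting).
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-12) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

fill_poly <- function(img, poly, value) {
  xs <- max(1, floor(min(poly[, 1]))):min(ncol(img), ceiling(max(poly[, 1])))
  ys <- max(1, floor(min(poly[, 2]))):min(nrow(img), ceiling(max(poly[, 2])))
  grid <- expand.grid(x = xs, y = ys)
  sel <- point_in_poly(grid$x, grid$y, poly)
  if (any(sel)) img[cbind(grid$y[sel], grid$x[sel])] <- value
  img
}

draw_polyline <- function(img, pts, value, close = FALSE) {
  if (close) pts <- rbind(pts, pts[1, ])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- max(1, ceiling(euclid(a, b) * 2))
    s <- seq(0, 1, length.out = len + 1)
    x <- round(a[1] + s * (b[1] - a[1]))
    y <- round(a[2] + s * (b[2] - a[2]))
    for (dx in -1:0) for (dy in -1:0) {
      xi <- pmin(pmax(x + dx, 1), ncol(img))
      yi <- pmin(pmax(y + dy, 1), nrow(img))
      img[cbind(yi, xi)] <- value
    }
  }
  img
}

#' Render grayscale frames from a landmark sequence
#'
#' Draws facial contours and filled eye/mouth polygons from the landmarks
#' on a uniform background, on a `size x size` canvas. `brightness_offset`
#' shifts all gray levels (clipped to `[0, 255]`), which permits
#' constructing over/under-exposed fixtures for the exposure QC.
#'
#' @param seq a [landmark_sequence()] (landmarks on the canvas).
#' @param size canvas side (default 200).
#' @param background background gray level (default 128).
#' @param line_gray contour gray level (default 40).
#' @param brightness_offset additive offset applied to the final image.
#' @return list of integer-valued `size x size` matrices, one per frame.
#' @export
render_frames <- function(seq, size = 200L, background = 128,
                          line_gray = 40, brightness_offset = 0) {
  stopifnot(inherits(seq, "vacp_sequence"))
  lapply(seq$frames, function(f) {
    p <- f$points
    img <- matrix(background, size, size)
    img <- draw_polyline(img, p[1:17, ], line_gray)              # jaw
    img <- draw_polyline(img, p[18:22, ], line_gray)             # brows
    img <- draw_polyline(img, p[23:27, ], line_gray)
    img <- draw_polyline(img, p[28:31, ], line_gray)             # nose
    img <- draw_polyline(img, p[32:36, ], line_gray)
    img <- fill_poly(img, p[37:42, ], line_gray + 20)            # eyes
    img <- fill_poly(img, p[43:48, ], line_gray + 20)
    img <- fill_poly(img, p[49:60, ], line_gray + 40)            # lips
    img <- draw_polyline(img, p[61:68, ], line_gray, close = TRUE)
    img <- pmin(pmax(img + brightness_offset, 0), 255)
    matrix(as.integer(round(img)), size, size)
  })
}
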