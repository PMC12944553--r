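mk_neutral <- function(n, shape = mean_face_shape(), fps = 30) {
  frames <- lapply(seq_len(n), function(i)
    landmark_set(shape, frame_index = i - 1L))
  landmark_sequence(frames, clip_id = "neutral", subject_id = "s",
                    emotion = "neutral", severity = "control", fps = fps)
}

test_that("reference set takes five equally spaced frames", {
  ref <- build_reference(mk_neutral(9))
  expect_equal(ref$frame_positions, c(1, 3, 5, 7, 9))

  ref5 <- build_reference(mk_neutral(5))
  expect_equal(ref5$frame_positions, 1:5)

  # frozen clip: L0 equals any single frame's reference lengths
  expect_equal(ref$L0,
               anchor_points(landmark_set(mean_face_shape()))$lengths)

  expect_error(build_reference(mk_neutral(4)), "at least 5")
})

test_that("amplitude follows the relative-length-change formulas", {
  ref <- build_reference(mk_neutral(5))
  shape <- mean_face_shape()
  ctr <- colMeans(shape)
  scaled_seq <- function(s) {
    frames <- lapply(seq_len(6), function(i)
      landmark_set(sweep(shape, 2, ctr) * s + rep(ctr, each = 68),
                   frame_index = i - 1L))
    landmark_sequence(frames, clip_id = "x", subject_id = "s",
                      emotion = "happy", severity = "control")
  }
  # all region lengths at 1.1 * L0 -> every delta 0.1, amplitude 0.1
  a <- amplitude_series(scaled_seq(1.1), ref, smooth_window = 1,
                        trim_frac = 0)
  expect_equal(unname(a$delta[1, ]), rep(0.1, 4), tolerance = 1e-9)
  expect_equal(a$amplitude[1], 0.1, tolerance = 1e-9)

  # identical to reference -> zero amplitude
  a0 <- amplitude_series(scaled_seq(1), ref, smooth_window = 1,
                         trim_frac = 0)
  expect_equal(max(abs(a0$amplitude)), 0, tolerance = 1e-12)

  # uniform 1.2x scale -> every delta 0.2
  a2 <- amplitude_series(scaled_seq(1.2), ref, smooth_window = 1,
                         trim_frac = 0)
  expect_equal(unname(a2$delta[3, ]), rep(0.2, 4), tolerance = 1e-9)
})

test_that("amplitude is invariant to rigid motion of whole frames", {
  set.seed(21)
  co <- tiny_cohort()
  cl <- co$clips[[grep("happy", names(co$clips))[1]]]
  neut <- co$clips[[grep("neutral", names(co$clips))[1]]]
  ref <- build_reference(neut$seq)
  a <- amplitude_series(cl$seq, ref)
  moved <- lapply(cl$seq$frames, function(f) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    landmark_set(t(R %*% t(f$points)) + rep(runif(2, -30, 30), each = 68),
                 frame_index = f$frame_index)
  })
  seq2 <- landmark_sequence(moved, clip_id = "m", subject_id = "s",
                            emotion = "happy", severity = "control")
  a2 <- amplitude_series(seq2, ref)
  expect_equal(a2$amplitude, a$amplitude, tolerance = 1e-9)
})

test_that("smoothing never raises the maximum and window 1 is identity", {
  set.seed(2)
  ref <- build_reference(mk_neutral(5))
  co <- tiny_cohort(seed = 9)
  cl <- co$clips[[grep("angry", names(co$clips))[1]]]
  a1 <- amplitude_series(cl$seq, ref, smooth_window = 1)
  expect_equal(a1$smoothed, a1$amplitude)
  a9 <- amplitude_series(cl$seq, ref, smooth_window = 9)
  expect_lte(max(a9$smoothed), max(a9$amplitude) + 1e-12)
  expect_error(amplitude_series(cl$seq, ref, smooth_window = 4), "odd")
  expect_error(amplitude_series(cl$seq, ref, trim_frac = 0.5), "trim_frac")
})

test_that("keyframe selection returns five ordered candidate frames", {
  co <- tiny_cohort(seed = 13)
  man <- co$manifest
  neut <- co$clips[[man$clip_id[man$emotion == "neutral"][1]]]
  ref <- build_reference(neut$seq)
  for (id in man$clip_id[man$emotion != "neutral"]) {
    k <- select_keyframes(amplitude_series(co$clips[[id]]$seq, ref))
    expect_length(k$frames, 5)
    expect_true(all(diff(k$frames) > 0))
    s <- amplitude_series(co$clips[[id]]$seq, ref)
    expect_true(all(s$candidate[k$positions]))
  }
})

test_that("a flat series breaks ties toward the earliest frames", {
  ref <- build_reference(mk_neutral(5))
  flat <- amplitude_series(mk_neutral(100, fps = 30), ref, trim_frac = 0.3)
  k <- select_keyframes(flat, min_gap = 1)
  expect_equal(k$positions, which(flat$candidate)[1:5])
})

test_that("apex MAE follows the mean absolute frame error", {
  expect_equal(evaluate_mae(c(10, 20), c(12, 17))$mae, 2.5)
  expect_equal(evaluate_mae(1:5, 1:5)$mae, 0)
  expect_equal(evaluate_mae(0, 7)$mae, 7)
  expect_error(evaluate_mae(1:3, 1:2), "equal length")
})
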