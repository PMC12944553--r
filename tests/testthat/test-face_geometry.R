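test_that("region index sets follow the 68-point convention", {
  rg <- face_regions()
  expect_length(rg$eyes, 12)
  expect_length(rg$whole_face, 51)
  core <- rg[c("brows", "eyes", "nose", "mouth")]
  expect_equal(anyDuplicated(unlist(core)), 0)        # pairwise disjoint
  expect_setequal(unlist(core), rg$whole_face)        # union = whole face
  expect_error(face_regions(list(eyes = c(1, 1, 2))), "unique")
  custom <- face_regions(list(mouth = 48:68 - 1L))
  expect_length(custom$mouth, 21)
})

test_that("anchor points and reference lengths follow the stated formulas", {
  lm <- lm_with(`48` = c(40, 120), `54` = c(60, 120))
  expect_equal(anchor_points(lm)$centers$mouth, c(50, 120))

  lm <- lm_with(`30` = c(0, 0), `27` = c(0, -3), `31` = c(-4, 0),
                `35` = c(4, 0))
  expect_equal(unname(anchor_points(lm)$lengths["nose"]), 11)

  lm <- lm_with(`36` = c(0, 0), `39` = c(6, 0))
  expect_equal(unname(anchor_points(lm)$lengths["left_eye"]), 6)

  # coincident mouth corners make the oral length degenerate
  lm <- lm_with(`48` = c(10, 10), `54` = c(10, 10))
  expect_error(anchor_points(lm), "degenerate")
})

test_that("phi and gamma measure eye-line and nose-bridge pose", {
  lm <- lm_with(`36` = c(48, 100), `39` = c(52, 100),
                `42` = c(148, 100), `45` = c(152, 100),
                `27` = c(100, 40), `30` = c(100, 90))
  ang <- compute_phi_gamma(lm)
  expect_equal(unname(ang["phi"]), 0)
  expect_equal(unname(ang["gamma"]), 0)

  lm2 <- lm_with(`36` = c(48, 100), `39` = c(52, 100),
                 `42` = c(148, 120), `45` = c(152, 120),
                 `27` = c(100, 40), `30` = c(100, 90))
  expect_equal(unname(compute_phi_gamma(lm2)["phi"]),
               atan(20 / 100) * 180 / pi, tolerance = 1e-8)

  bad <- lm_with(`27` = c(5, 5), `30` = c(5, 5))
  expect_error(compute_phi_gamma(bad), "degenerate")
})

test_that("alignment removes rotation and is idempotent", {
  base <- landmark_set(mean_face_shape())
  al1 <- align_face(base)
  expect_lt(abs(al1$phi), 1e-6)

  # rotate by +15 degrees about the face center, then align
  th <- 15 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  ctr <- colMeans(base$points)
  rot <- landmark_set(t(R %*% t(sweep(base$points, 2, ctr))) +
                        rep(ctr, each = 68))
  al2 <- align_face(rot)
  expect_lt(abs(al2$phi), 1e-6)
  expect_equal(al2$landmarks$points, al1$landmarks$points, tolerance = 1e-6)

  # idempotence
  al3 <- align_face(al1$landmarks)
  expect_equal(al3$landmarks$points, al1$landmarks$points, tolerance = 1e-6)
})

test_that("aligned images are resampled to the 200 px canvas", {
  base <- landmark_set(mean_face_shape())
  img <- matrix(runif(240 * 240, 0, 255), 240, 240)
  al <- align_face(base, image = img)
  expect_equal(dim(al$image), c(200, 200))
})

test_that("reference lengths are rigid-invariant and scale linearly", {
  set.seed(11)
  base <- landmark_set(mean_face_shape() +
                         matrix(rnorm(136, 0, 0.3), 68, 2))
  L <- anchor_points(base)$lengths
  for (i in 1:5) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    shift <- runif(2, -50, 50)
    moved <- landmark_set(t(R %*% t(base$points)) + rep(shift, each = 68))
    expect_equal(anchor_points(moved)$lengths, L, tolerance = 1e-9)
    s <- runif(1, 0.5, 2)
    scaled <- landmark_set(base$points * s)
    expect_equal(anchor_points(scaled)$lengths, L * s, tolerance = 1e-9)
  }
})

test_that("alignment report contracts the pose distribution", {
  mk_seq <- function(angles, clip, subj) {
    base <- mean_face_shape()
    ctr <- colMeans(base)
    frames <- lapply(seq_along(angles), function(i) {
      th <- angles[i] * pi / 180
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
      landmark_set(t(R %*% t(sweep(base, 2, ctr))) + rep(ctr, each = 68),
                   frame_index = i - 1L)
    })
    landmark_sequence(frames, clip_id = clip, subject_id = subj,
                      emotion = "neutral", severity = "control")
  }
  set.seed(5)
  angles <- rnorm(20, 0, 5)
  before <- mk_seq(angles, "c1", "s1")
  after <- landmark_sequence(
    lapply(before$frames, function(f) align_face(f)$landmarks),
    clip_id = "c1", subject_id = "s1", emotion = "neutral",
    severity = "control")
  rep1 <- alignment_report(list(before), list(after))
  expect_lt(rep1$phi_var_after, rep1$phi_var_before)
  expect_lt(rep1$phi_mean_after, rep1$phi_mean_before)

  # constant +10 degree offset: mean 10, variance 0
  const <- mk_seq(rep(10, 8), "c2", "s2")
  rep2 <- alignment_report(list(const), list(const))
  expect_equal(rep2$phi_mean_before, 10, tolerance = 1e-6)
  expect_equal(rep2$phi_var_before, 0, tolerance = 1e-9)
})
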