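test_that("HOG has the fixed layout and expected sensitivities", {
  flat <- extract_hog(matrix(128, 200, 200))
  expect_length(flat, 4464)
  expect_equal(max(abs(flat)), 0)

  # a diagonal edge image differs from its 180-degree rotation
  img <- outer(1:200, 1:200, function(r, c) ifelse(r + c < 220, 40, 200))
  h1 <- extract_hog(img)
  h2 <- extract_hog(img[200:1, 200:1])
  expect_length(h1, 4464)
  expect_false(isTRUE(all.equal(h1, h2)))

  expect_error(extract_hog(matrix(0, 100, 100)), "200 x 200")
})

test_that("PCA reduction caps dimensions and standardizes scores", {
  set.seed(4)
  # rank-3 data: first three components carry essentially all variance
  basis <- matrix(rnorm(3 * 50), 3, 50)
  x <- matrix(rnorm(40 * 3), 40, 3) %*% basis +
    matrix(rnorm(40 * 50, 0, 1e-4), 40, 50)
  m <- fit_reduce(x, n_components = 10)
  expect_equal(m$k, 10)
  expect_gte(sum(m$score_scale[1:3]^2) / sum(m$score_scale^2), 0.999)
  expect_equal(unname(colMeans(m$scores)), rep(0, 10), tolerance = 1e-9)

  # cap at sample count
  m2 <- fit_reduce(matrix(rnorm(5 * 30), 5, 30), n_components = 1379)
  expect_equal(m2$k, 5)

  expect_warning(fit_reduce(matrix(1, 4, 6), n_components = 2),
                 "zero-variance")
  expect_error(fit_reduce(x, n_components = 0), "n_components")

  # projection reproduces the training scores
  expect_equal(predict(m, x), m$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("geometric features localize controlled perturbations", {
  base <- geometric_features(landmark_set(mean_face_shape()))
  expect_length(base, 146)

  p <- mean_face_shape()
  p[c(49, 55), 1] <- p[c(49, 55), 1] + c(-4, 4)  # symmetric corner spread
  pert <- geometric_features(landmark_set(p))
  changed <- which(abs(pert - base) > 1e-9)
  expect_true(all(grepl("48|54|mouth", names(base)[changed])))

  shifted <- geometric_features(landmark_set(mean_face_shape() +
                                               rep(c(30, -10), each = 68)))
  dist_slots <- grep("len_|dist_", names(base))
  expect_equal(shifted[dist_slots], base[dist_slots], tolerance = 1e-9)
})

test_that("per-AU models recover planted drives and stay in range", {
  set.seed(6)
  fields <- vacp:::au_displacement_fields()
  slots <- au_slots()
  n <- 160
  # drives clear of the 0.5 presence threshold: separable presence classes
  drive12 <- sample(c(runif(n / 2, 0, 0.1), runif(n / 2, 1.5, 5)))
  feats <- t(vapply(seq_len(n), function(i) {
    p <- mean_face_shape() + drive12[i] / 5 * fields$AU12 +
      matrix(rnorm(136, 0, 0.3), 68, 2)
    geometric_features(landmark_set(p))
  }, numeric(146)))
  ints <- matrix(0, n, 18, dimnames = list(NULL, slots$intensity))
  ints[, "AU12"] <- drive12
  pres <- (ints[, slots$presence] >= 0.5) + 0
  tr <- 1:120; te <- 121:160
  models <- fit_au_models(feats[tr, ], ints[tr, ], pres[tr, ])
  pred <- predict_au(models, feats[te, ])
  rmse <- sqrt(mean((pred$intensities[, "AU12"] - drive12[te])^2))
  expect_lt(rmse, 0.5)
  expect_true(all(pred$intensities >= 0 & pred$intensities <= 5))
  expect_true(all(pred$presence %in% c(0, 1)))
  expect_equal(dim(pred$intensities), c(40, 18))
  expect_equal(dim(pred$presence), c(40, 17))
  # separable presence: held-out accuracy 1 for AU12
  expect_equal(mean(pred$presence[, "AU12"] == pres[te, "AU12"]), 1)
})

test_that("FAUF is the 35-d frame mean, invariant to frame order", {
  slots <- au_slots()
  set.seed(8)
  ints <- matrix(runif(5 * 18, 0, 5), 5, 18,
                 dimnames = list(NULL, slots$intensity))
  pres <- matrix(rbinom(5 * 17, 1, 0.5), 5, 17,
                 dimnames = list(NULL, slots$presence))
  au <- structure(list(intensities = ints, presence = pres, slots = slots),
                  class = "vacp_au")
  f <- assemble_faufs(au)
  expect_length(f, 35)
  expect_equal(unname(f[1:18]), unname(colMeans(ints)))

  perm <- structure(list(intensities = ints[5:1, ], presence = pres[5:1, ],
                         slots = slots), class = "vacp_au")
  expect_equal(assemble_faufs(perm), f)

  # presence on 3 of 5 keyframes -> rate 0.6
  pres2 <- pres; pres2[, 1] <- c(1, 1, 1, 0, 0)
  au2 <- structure(list(intensities = ints, presence = pres2, slots = slots),
                   class = "vacp_au")
  expect_equal(unname(assemble_faufs(au2)[19]), 0.6)

  # constant vector: FAUF equals that vector
  one <- structure(list(intensities = ints[c(1, 1, 1), ],
                        presence = pres[c(1, 1, 1), ], slots = slots),
                   class = "vacp_au")
  expect_equal(unname(assemble_faufs(one)),
               unname(c(ints[1, ], pres[1, ])))
})

test_that("group statistics apply rank-sum tests with Bonferroni families", {
  set.seed(10)
  mk_table <- function(shift, values = rnorm(8, 3, 0.3)) {
    sev <- rep(c("control", "severe"), each = 8)
    data.frame(subject_id = paste0("s", 1:16), emotion = "happy",
               severity = sev,
               AU12_r = c(values, values - shift),
               AU12_c = rep(runif(8), 2))
  }
  # two identical groups: adjusted p ~ 1, nothing flagged
  null <- group_statistics(mk_table(0))
  expect_true(all(null$p_adj > 0.9, na.rm = TRUE))
  expect_false(any(null$sig05))

  sep <- group_statistics(mk_table(2.5))
  row <- sep[sep$slot == "AU12_r" & sep$group1 == "control" &
               sep$group2 == "severe", ]
  expect_true(row$sig05)

  # Bonferroni arithmetic: adjusted p = min(1, p * m) within the family
  four <- data.frame(subject_id = paste0("s", 1:24), emotion = "sad",
                     severity = rep(c("control", "mild", "moderate",
                                      "severe"), each = 6),
                     AU04_r = rnorm(24))
  st <- group_statistics(four)
  expect_equal(st$p_adj, pmin(1, st$p * 6), tolerance = 1e-12)
})
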