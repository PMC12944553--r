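test_that("small configurations triangulate as expected", {
  sq <- delaunay_triangulate(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(nrow(sq), 2)
  edges <- unique(do.call(rbind, apply(sq, 1, function(tr)
    rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)])),
    simplify = FALSE)))
  expect_equal(nrow(edges), 5)  # four sides plus one diagonal

  tri <- delaunay_triangulate(rbind(c(0, 0), c(2, 0), c(1, 2)))
  expect_equal(tri, matrix(1:3, 1))

  expect_error(delaunay_triangulate(rbind(c(0, 0), c(1, 1), c(2, 2),
                                          c(3, 3))), "collinear")
  expect_error(delaunay_triangulate(rbind(c(0, 0), c(0, 0), c(1, 0),
                                          c(0, 1)),
                                    duplicate_action = "error"), "duplicate")
  # default duplicate handling perturbs and succeeds
  expect_silent(delaunay_triangulate(rbind(c(0, 0), c(0, 0), c(1, 0),
                                           c(0, 1))))
})

test_that("triangulation matches the brute-force circumcircle oracle", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(4:25, 1)
    pts <- matrix(runif(2 * n, 0, 100), n, 2)
    expect_equal(delaunay_triangulate(pts), bf_delaunay(pts),
                 info = sprintf("rep %d n %d", rep, n))
  }
})

test_that("the empty-circumcircle property holds on face graphs", {
  lm <- landmark_set(mean_face_shape())
  g <- triangulate_region(lm, "whole_face")
  pts <- g$coords
  for (r in seq_len(nrow(g$triangles))) {
    tr <- g$triangles[r, ]
    cc <- vacp:::circumcircle(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
    others <- setdiff(seq_len(nrow(pts)), tr)
    d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, cc$center)^2)
    expect_true(all(d2 > cc$r2 * (1 - 1e-9)))
  }
})

test_that("the produced diagonal maximizes the minimum angle", {
  set.seed(23)
  for (rep in 1:50) {
    # convex quadrilateral from a random circle ordering
    ang <- sort(runif(4, 0, 2 * pi))
    pts <- cbind(cos(ang), sin(ang)) * runif(4, 0.8, 1.2)
    tri <- tryCatch(delaunay_triangulate(pts), error = function(e) NULL)
    if (is.null(tri) || nrow(tri) != 2) next
    diag_used <- intersect(tri[1, ], tri[2, ])
    diag_alt <- setdiff(1:4, diag_used)
    ma <- function(d) {
      others <- setdiff(1:4, d)
      min(min_angle(pts[d[1], ], pts[d[2], ], pts[others[1], ]),
          min_angle(pts[d[1], ], pts[d[2], ], pts[others[2], ]))
    }
    expect_gte(ma(diag_used), ma(diag_alt) - 1e-9)
  }
})

test_that("flipping the Delaunay diagonal breaks local Delaunayhood", {
  # convex quadrilateral whose Delaunay diagonal is unique
  pts <- rbind(c(0, 0), c(4, 0.2), c(4.2, 3.8), c(-0.3, 3))
  tri <- delaunay_triangulate(pts)
  diag_used <- intersect(tri[1, ], tri[2, ])
  diag_alt <- setdiff(1:4, diag_used)
  # the alternative diagonal's triangles violate the empty circumcircle
  t1 <- c(diag_alt, diag_used[1]); t2 <- c(diag_alt, diag_used[2])
  cc <- vacp:::circumcircle(pts[t1[1], ], pts[t1[2], ], pts[t1[3], ])
  d2 <- sum((pts[diag_used[2], ] - cc$center)^2)
  expect_lt(d2, cc$r2)
  # and re-triangulating the flipped configuration restores the original
  expect_equal(delaunay_triangulate(pts), tri)
})

test_that("region graphs carry positive distance weights and locality", {
  lm <- landmark_set(mean_face_shape())
  gr <- build_multiregion(lm)
  expect_named(gr, c("whole_face", "brows", "eyes", "mouth"))
  expect_equal(nrow(gr$eyes$coords), 12)
  expect_equal(nrow(gr$whole_face$coords), 51)
  expect_true(all(gr$whole_face$edges$weight > 0))

  # edge weights equal the Euclidean node distances
  e <- gr$mouth$edges
  d <- sqrt(rowSums((gr$mouth$coords[e$i, ] - gr$mouth$coords[e$j, ])^2))
  expect_equal(e$weight, d)

  # perturbing mouth landmarks leaves the brows and eyes graphs unchanged
  p2 <- mean_face_shape()
  p2[49:68, ] <- p2[49:68, ] + 3
  gr2 <- build_multiregion(landmark_set(p2))
  expect_equal(gr2$brows, gr$brows)
  expect_equal(gr2$eyes, gr$eyes)
})
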