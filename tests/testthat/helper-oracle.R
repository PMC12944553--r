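# Brute-force Delaunay oracle: enumerate all point triples and keep those
# whose circumcircle contains no other point (strict, with a relative
# tolerance). For points in general position this is exactly the Delaunay
# triangle set. O(n^4), independent of the package's incremental algorithm.
bf_delaunay <- function(pts) {
  n <- nrow(pts)
  tris <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next  # collinear triple
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 > r2 * (1 - 1e-9)))
      tris[[length(tris) + 1L]] <- c(i, j, k)
  }
  out <- do.call(rbind, tris)
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# Minimum interior angle of triangle (a, b, c), degrees.
min_angle <- function(a, b, c) {
  side <- function(p, q) sqrt(sum((p - q)^2))
  A <- side(b, c); B <- side(a, c); C <- side(a, b)
  angs <- c(acos(pmin(1, pmax(-1, (B^2 + C^2 - A^2) / (2 * B * C)))),
            acos(pmin(1, pmax(-1, (A^2 + C^2 - B^2) / (2 * A * C)))),
            acos(pmin(1, pmax(-1, (A^2 + B^2 - C^2) / (2 * A * B)))))
  min(angs) * 180 / pi
}

# A small deterministic cohort for unit tests (not the acceptance cohort).
tiny_cohort <- function(seed = 7, ...) {
  generate_cohort(cohort_config(n_subjects_per_class = 1L,
                                clips_per_subject = 4L, seed = seed, ...))
}

# Landmark set with the named 0-based points placed and all others spread
# on a circle so no two coincide.
lm_with <- function(...) {
  pts <- list(...)
  p <- cbind(300 + 50 * cos(seq_len(68)), 300 + 50 * sin(seq_len(68)))
  for (nm in names(pts)) p[as.integer(nm) + 1L, ] <- pts[[nm]]
  landmark_set(p)
}
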