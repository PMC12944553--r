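# Delaunay triangulation of facial landmark regions (Bowyer-Watson) and
# the region-restricted weighted face graphs built from it.

# Circumcenter and squared circumradius of triangle (a, b, c); returns NULL
# for (near-)collinear triples.
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12 * max(1, sum(abs(c(a, b, c))))^2) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, r2 = sum((a - ctr)^2))
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. The result satisfies the
#' empty-circumcircle property: no input point lies strictly inside the
#' circumcircle of any output triangle (equivalently, the triangulation
#' maximizes the minimum angle).
#'
#' @param pts n x 2 numeric matrix, n >= 3.
#' @param duplicate_action `"jitter"` (default) perturbs exact duplicates by
#'   1e-6 px with a deterministic seeded offset; `"error"` stops.
#' @return integer matrix with 3 columns; each row is a triangle as 1-based
#'   row indices into `pts`, vertex indices sorted increasingly, rows sorted
#'   lexicographically.
#' @examples
#' delaunay_triangulate(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#' @export
delaunay_triangulate <- function(pts, duplicate_action = c("jitter", "error")) {
  duplicate_action <- match.arg(duplicate_action)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2, all(is.finite(pts)))
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (anyDuplicated(round(pts, 9))) {
    if (duplicate_action == "error")
      stop("duplicate points in triangulation input", call. = FALSE)
    dup <- duplicated(round(pts, 9))
    pts[dup, ] <- pts[dup, , drop = FALSE] +
      with_seed(20231L, matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6),
                               ncol = 2))
  }
  # collinearity check via the largest absolute triple cross-product
  v <- sweep(pts, 2, pts[1, ])
  cross <- v[, 1] * v[which.max(rowSums(v^2)), 2] -
    v[, 2] * v[which.max(rowSums(v^2)), 1]
  if (all(abs(cross) < 1e-9 * max(1, max(abs(pts)))^2))
    stop("degenerate geometry: all points are collinear", call. = FALSE)

  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  m <- 10 * max(rng[2, ] - rng[1, ], 1)
  super <- rbind(ctr + c(-20 * m, -m), ctr + c(20 * m, -m), ctr + c(0, 20 * m))
  P <- rbind(pts, super)
  orient2 <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  make_ccw <- function(tr)
    if (orient2(P[tr[1], ], P[tr[2], ], P[tr[3], ]) < 0) tr[c(1, 3, 2)] else tr
  tris <- matrix(make_ccw(c(n + 1L, n + 2L, n + 3L)), 1)

  # Generalized in-circle test for one CCW triangle, treating the three
  # super vertices as points at infinity (symbolic convention): a triangle
  # with one infinite vertex owns the half-plane left of its finite edge,
  # with two infinite vertices the half-plane through its finite vertex
  # parallel to the infinite edge. This keeps hull slivers whose true
  # circumradius exceeds any finite super-triangle size.
  incircle_one <- function(tr, p) {
    sup <- tr > n
    k <- sum(sup)
    if (k == 0L) {
      ax <- P[tr[1], 1] - p[1]; ay <- P[tr[1], 2] - p[2]
      bx <- P[tr[2], 1] - p[1]; by <- P[tr[2], 2] - p[2]
      cx <- P[tr[3], 1] - p[1]; cy <- P[tr[3], 2] - p[2]
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
      return(ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) +
               a2 * (bx * cy - by * cx) > 0)
    }
    if (k == 3L) return(TRUE)
    if (k == 1L) {
      # rotate so the triangle reads (a, b, s) with s infinite, CCW kept
      shift <- which(sup) %% 3L + 1L
      ord <- ((shift - 1L + 0:2) %% 3L) + 1L
      a <- P[tr[ord[1]], ]; b <- P[tr[ord[2]], ]
      return(orient2(a, b, p) > 0)
    }
    # k == 2: rotate to (a, s1, s2); the limiting disk is the half-plane
    # through a parallel to the infinite edge, on the infinite side, which
    # for a CCW triangle is the right of the directed line a -> a + (s2-s1)
    shift <- which(!sup)
    ord <- ((shift - 1L + 0:2) %% 3L) + 1L
    a <- P[tr[ord[1]], ]
    d <- P[tr[ord[3]], ] - P[tr[ord[2]], ]
    orient2(a, a + d, p) < 0
  }

  for (ip in seq_len(n)) {
    p <- P[ip, ]
    has_super <- tris[, 1] > n | tris[, 2] > n | tris[, 3] > n
    fin <- which(!has_super)
    det <- rep(FALSE, nrow(tris))
    if (length(fin)) {
      ax <- P[tris[fin, 1], 1] - p[1]; ay <- P[tris[fin, 1], 2] - p[2]
      bx <- P[tris[fin, 2], 1] - p[1]; by <- P[tris[fin, 2], 2] - p[2]
      cx <- P[tris[fin, 3], 1] - p[1]; cy <- P[tris[fin, 3], 2] - p[2]
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
      det[fin] <- ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) +
        a2 * (bx * cy - by * cx) > 0
    }
    for (r in which(has_super)) det[r] <- incircle_one(tris[r, ], p)
    bad <- which(det)
    if (length(bad) == 0) next  # numerically outside everything; skip
    # boundary polygon = edges of bad triangles that occur exactly once
    edges <- do.call(rbind, lapply(bad, function(r) {
      tr <- tris[r, ]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    fresh <- t(apply(boundary, 1, function(e) make_ccw(c(e, ip))))
    tris <- rbind(tris[-bad, , drop = FALSE], fresh)
  }
  out <- tris[rowSums(tris <= n) == 3L, , drop = FALSE]
  if (nrow(out) == 0)
    stop("triangulation produced no triangles", call. = FALSE)
  out <- t(apply(out, 1, sort))
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

#' Triangulate one facial region into a weighted graph
#'
#' Builds the Delaunay graph of a region's landmarks: nodes are the
#' region's landmark coordinates, edges are the union of triangle sides
#' (undirected, deduplicated) weighted by Euclidean distance in pixels.
#'
#' @param lm a [landmark_set()] (typically aligned).
#' @param region region name (one of `names(face_regions())`) or a 0-based
#'   integer index vector.
#' @param regions region table from [face_regions()].
#' @param duplicate_action see [delaunay_triangulate()].
#' @return object of class `vacp_face_graph`: list with `region`,
#'   `node_index` (0-based landmark ids), `coords` (k x 2), `triangles`
#'   (rows index into the region's nodes), `edges` (data.frame `i`, `j`,
#'   `weight`; `i`/`j` are region-node positions).
#' @export
triangulate_region <- function(lm, region = "whole_face",
                               regions = face_regions(),
                               duplicate_action = "jitter") {
  stopifnot(inherits(lm, "vacp_landmarks"))
  if (is.character(region)) {
    name <- region
    idx0 <- regions[[region]]
    if (is.null(idx0)) stop("unknown region: ", region, call. = FALSE)
  } else {
    name <- "custom"
    idx0 <- as.integer(region)
  }
  coords <- lm$points[region_rows(idx0), , drop = FALSE]
  if (nrow(coords) < 3)
    stop("a region needs at least 3 landmarks", call. = FALSE)
  tri <- delaunay_triangulate(coords, duplicate_action = duplicate_action)
  e <- unique(do.call(rbind, apply(tri, 1, function(tr)
    rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)])),
    simplify = FALSE)))
  w <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                       coords[e[, 2], , drop = FALSE])^2))
  structure(list(region = name, node_index = as.integer(idx0),
                 coords = coords, triangles = tri,
                 edges = data.frame(i = e[, 1], j = e[, 2], weight = w)),
            class = "vacp_face_graph")
}

#' Multi-region face graphs
#'
#' Triangulates the whole face and the brows, eyes and mouth sub-regions
#' independently, giving the four graphs used by the region ablation and
#' the landmark-graph embedding.
#'
#' @inheritParams triangulate_region
#' @return named list of [triangulate_region()] graphs:
#'   `whole_face`, `brows`, `eyes`, `mouth`.
#' @export
build_multiregion <- function(lm, regions = face_regions(),
                              duplicate_action = "jitter") {
  nm <- c("whole_face", "brows", "eyes", "mouth")
  stats::setNames(lapply(nm, triangulate_region, lm = lm, regions = regions,
                         duplicate_action = duplicate_action), nm)
}

#' @export
print.vacp_face_graph <- function(x, ...) {
  cat(sprintf("<vacp_face_graph> %s: %d nodes, %d edges, %d triangles\n",
              x$region, nrow(x$coords), nrow(x$edges), nrow(x$triangles)))
  invisible(x)
}

#' Serialize a face graph to JSON
#'
#' @param graph a [triangulate_region()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_face_graph <- function(graph, path) {
  jsonlite::write_json(
    list(region = graph$region, node_index = graph$node_index,
         coords = graph$coords, triangles = graph$triangles,
         edges = graph$edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
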