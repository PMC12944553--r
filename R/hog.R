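# Histogram-of-oriented-gradients appearance descriptor for the aligned
# 200 x 200 face: 12 x 12 cells x 31 unsigned orientation bins = 4464 values.

#' Extract the HOG appearance feature of an aligned face
#'
#' Central-difference gradients are binned by unsigned orientation
#' (31 bins over `[0, pi)`) into a 12 x 12 cell grid, weighted by gradient
#' magnitude; each cell histogram is L2-normalized. A constant image yields
#' the zero vector.
#'
#' @param face an [align_face()] result with an image, or a square grayscale
#'   matrix of side `size`.
#' @param cells cells per side (default 12).
#' @param bins orientation bins (default 31).
#' @param size expected image side (default 200).
#' @return numeric vector of length `cells^2 * bins` (4464 by default),
#'   ordered cell-row major, orientation fastest.
#' @export
extract_hog <- function(face, cells = 12L, bins = 31L, size = 200L) {
  img <- if (inherits(face, "vacp_aligned")) face$image else face
  if (!is.matrix(img) || nrow(img) != size || ncol(img) != size)
    stop(sprintf("`face` must carry a %d x %d grayscale image", size, size),
         call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
  gy <- (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / pi * bins), bins - 1L)
  row <- (seq_len(h) - 1L)[row(img)]
  col <- (seq_len(w) - 1L)[col(img)]
  cy <- floor(row * cells / h)
  cx <- floor(col * cells / w)
  idx <- cy * cells * bins + cx * bins + bin + 1L
  feat <- numeric(cells^2 * bins)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  feat[as.integer(rownames(acc))] <- acc
  m <- matrix(feat, nrow = cells^2, byrow = TRUE)
  nrm <- sqrt(rowSums(m^2))
  m <- m / (nrm + 1e-6)
  as.numeric(t(m))
}
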