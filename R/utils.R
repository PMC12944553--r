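# Internal numeric and RNG helpers shared across the pipeline.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (weight
#' initialisation, jitter, splits) never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Mirror-reflected index for positions outside 1..n (scipy-style 'reflect',
# the edge sample is not repeated). Degenerates to 1 when n == 1.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(pmin(j, p - j) + 1L)
}

#' Centered moving average with reflect padding
#'
#' @param x numeric vector.
#' @param window odd integer window length (>= 1); `window = 1` returns `x`.
#' @return smoothed numeric vector of the same length.
#' @keywords internal
smooth_moving_average <- function(x, window) {
  stopifnot(is.numeric(x), length(x) >= 1)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), (-h):h, `+`)
  m <- matrix(x[reflect_index(as.vector(idx), n)], nrow = n)
  rowMeans(m)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Stratified index split: returns list(train=, test=) with a `test_frac`
# share of every class rounded to the nearest count (at least one test
# sample per class when the class is non-empty).
stratified_split <- function(labels, test_frac, seed) {
  stopifnot(test_frac > 0, test_frac < 1)
  labels <- as.factor(labels)
  with_seed(seed, {
    test <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      k <- max(1L, round(length(idx) * test_frac))
      test <- c(test, sample(idx, k))
    }
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
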