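# Facial action unit (AU) estimation and the 35-d per-clip AU feature
# (FAUF): appearance (HOG -> PCA) and geometric features feed per-AU SVR
# intensity regressors (0-5 scale) and SVM presence classifiers; per-clip
# means of the 18 intensity and 17 presence slots form the FAUF, and
# rank-sum group statistics with Bonferroni correction compare severity
# groups per emotion.

#' AU slot configuration
#'
#' The default partition carries 18 intensity slots and 17 presence slots
#' (the intensity list minus AU28, which common FACS toolkits score for
#' presence only in the opposite convention; any 18/17 split can be
#' declared).
#'
#' @param intensity character vector of intensity AU ids (length 18).
#' @param presence character vector of presence AU ids (length 17).
#' @return list with `intensity` and `presence`.
#' @export
au_slots <- function(intensity = c("AU01", "AU02", "AU04", "AU05", "AU06",
                                   "AU07", "AU09", "AU10", "AU12", "AU14",
                                   "AU15", "AU17", "AU20", "AU23", "AU25",
                                   "AU26", "AU28", "AU45"),
                     presence = setdiff(intensity, "AU28")) {
  stopifnot(!anyDuplicated(intensity), !anyDuplicated(presence))
  list(intensity = intensity, presence = presence)
}

#' Fit a PCA reduction of HOG features, then standardize
#'
#' Principal component reduction of the 4464-d HOG vectors (default target
#' 1379 components, capped at the sample and feature counts) followed by
#' per-component standardization of the scores.
#'
#' @param x n x p feature matrix (n >= 2).
#' @param n_components target dimensionality (default 1379).
#' @return object of class `vacp_pca`: list with `center`, `rotation`,
#'   `k`, `score_center`, `score_scale`, and `scores` (the standardized
#'   training scores, n x k).
#' @export
fit_reduce <- function(x, n_components = 1379L) {
  x <- as.matrix(x)
  if (n_components < 1) stop("`n_components` must be >= 1", call. = FALSE)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  k <- min(n_components, nrow(x), ncol(x))
  if (all(apply(x, 2, stats::var) == 0)) {
    warning("zero-variance input: PCA reduction falls back to zero scores")
    scores <- matrix(0, nrow(x), k)
    return(structure(list(center = colMeans(x),
                          rotation = matrix(0, ncol(x), k), k = k,
                          score_center = rep(0, k), score_scale = rep(1, k),
                          scores = scores),
                     class = "vacp_pca"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  sc <- pc$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(sc)
  sdv <- apply(sc, 2, stats::sd)
  sdv[sdv == 0] <- 1
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE], k = k,
                 score_center = mu, score_scale = sdv,
                 scores = sweep(sweep(sc, 2, mu), 2, sdv, "/")),
            class = "vacp_pca")
}

#' Project new features through a fitted PCA reduction
#'
#' @param object a [fit_reduce()] model.
#' @param newdata matrix or vector of raw features.
#' @param ... unused.
#' @return standardized score matrix (n x k).
#' @export
predict.vacp_pca <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  sc <- sweep(newdata, 2, object$center) %*% object$rotation
  sweep(sweep(sc, 2, object$score_center), 2, object$score_scale, "/")
}

#' Geometric feature vector of a landmark set
#'
#' Deterministic concatenation of the 68 aligned landmark coordinates, the
#' four region reference lengths, and the six pairwise distances among the
#' region anchor centers (nose, mouth, left and right eye). Distances and
#' lengths are translation invariant; coordinates are not, which is why the
#' input should be aligned.
#'
#' @param lm a [landmark_set()] (aligned coordinates).
#' @return named numeric vector of length 146.
#' @export
geometric_features <- function(lm) {
  stopifnot(inherits(lm, "vacp_landmarks"))
  a <- anchor_points(lm)
  ctrs <- do.call(rbind, a$centers)
  pairs <- utils::combn(rownames(ctrs), 2)
  pd <- apply(pairs, 2, function(p) euclid(ctrs[p[1], ], ctrs[p[2], ]))
  names(pd) <- paste0("dist_", pairs[1, ], "_", pairs[2, ])
  coords <- as.numeric(t(lm$points))
  names(coords) <- paste0(rep(c("x", "y"), 68), rep(0:67, each = 2))
  c(coords, stats::setNames(a$lengths, paste0("len_", names(a$lengths))), pd)
}

# Constant-prediction stub used when presence training data has one class.
constant_model <- function(value) structure(list(value = value),
                                            class = "vacp_constant")

#' @export
predict.vacp_constant <- function(object, newdata, ...) {
  rep(object$value, if (is.null(dim(newdata))) 1L else nrow(newdata))
}

#' Fit per-AU intensity (SVR) and presence (SVM) models
#'
#' One linear support vector regressor per intensity slot (predictions
#' clipped to the 0-5 FACS scale) and one linear SVM per presence slot.
#' Presence slots whose training labels are single-class fall back to a
#' constant model.
#'
#' @param features n x d numeric matrix (geometric features, optionally
#'   augmented with PCA-reduced HOG scores).
#' @param intensities n x 18 matrix of AU intensity targets in `[0, 5]`.
#' @param presence n x 17 binary matrix of AU presence targets.
#' @param slots slot configuration from [au_slots()].
#' @param cost SVM/SVR cost parameter (default 1).
#' @return object of class `vacp_au_models`.
#' @export
fit_au_models <- function(features, intensities, presence,
                          slots = au_slots(), cost = 1) {
  features <- as.matrix(features)
  intensities <- as.matrix(intensities)
  presence <- as.matrix(presence)
  stopifnot(ncol(intensities) == length(slots$intensity),
            ncol(presence) == length(slots$presence),
            nrow(features) == nrow(intensities),
            nrow(features) == nrow(presence))
  keep <- apply(features, 2, stats::sd) > 0
  reg <- lapply(seq_along(slots$intensity), function(j) {
    if (stats::sd(intensities[, j]) == 0)
      return(constant_model(intensities[1, j]))
    e1071::svm(x = features[, keep, drop = FALSE], y = intensities[, j],
               type = "eps-regression", kernel = "linear", cost = cost,
               scale = TRUE)
  })
  cls <- lapply(seq_along(slots$presence), function(j) {
    y <- factor(presence[, j], levels = c(0, 1))
    if (length(unique(presence[, j])) < 2)
      return(constant_model(presence[1, j]))
    e1071::svm(x = features[, keep, drop = FALSE], y = y,
               type = "C-classification", kernel = "linear", cost = cost,
               scale = TRUE)
  })
  structure(list(regressors = stats::setNames(reg, slots$intensity),
                 classifiers = stats::setNames(cls, slots$presence),
                 feature_mask = keep, slots = slots),
            class = "vacp_au_models")
}

#' Predict the AU vector of one or more frames
#'
#' @param models a [fit_au_models()] fit.
#' @param features feature matrix (rows = frames) or a single feature
#'   vector.
#' @return object of class `vacp_au`: list with `intensities` (n x 18,
#'   clipped to `[0, 5]`), `presence` (n x 17, 0/1), `slots`.
#' @export
predict_au <- function(models, features) {
  stopifnot(inherits(models, "vacp_au_models"))
  features <- if (is.null(dim(features))) matrix(features, nrow = 1)
              else as.matrix(features)
  features <- features[, models$feature_mask, drop = FALSE]
  ints <- vapply(models$regressors, function(m)
    pmin(pmax(as.numeric(stats::predict(m, features)), 0), 5),
    numeric(nrow(features)))
  pres <- vapply(models$classifiers, function(m) {
    p <- stats::predict(m, features)
    as.numeric(as.character(p))
  }, numeric(nrow(features)))
  ints <- matrix(ints, nrow = nrow(features),
                 dimnames = list(NULL, models$slots$intensity))
  pres <- matrix(pres, nrow = nrow(features),
                 dimnames = list(NULL, models$slots$presence))
  structure(list(intensities = ints, presence = pres, slots = models$slots),
            class = "vacp_au")
}

#' Assemble the per-clip 35-d AU feature (FAUF)
#'
#' Per-slot mean over a clip's frames (typically its five keyframes): 18
#' mean intensities followed by 17 presence rates, the latter interpretable
#' as per-AU occurrence probabilities.
#'
#' @param au a `vacp_au` prediction for the clip's frames (rows = frames),
#'   or a list of such objects to be row-bound.
#' @return named numeric vector of length 35 (`<AU>_r` intensity slots,
#'   then `<AU>_c` presence slots).
#' @export
assemble_faufs <- function(au) {
  if (is.list(au) && !inherits(au, "vacp_au")) {
    ints <- do.call(rbind, lapply(au, `[[`, "intensities"))
    pres <- do.call(rbind, lapply(au, `[[`, "presence"))
    slots <- au[[1]]$slots
  } else {
    stopifnot(inherits(au, "vacp_au"))
    ints <- au$intensities; pres <- au$presence; slots <- au$slots
  }
  if (nrow(ints) == 0) stop("FAUF needs at least one frame", call. = FALSE)
  c(stats::setNames(colMeans(ints), paste0(slots$intensity, "_r")),
    stats::setNames(colMeans(pres), paste0(slots$presence, "_c")))
}

#' Severity group statistics of FAUF slots
#'
#' Aggregates the FAUF table to one mean vector per subject x emotion, then
#' compares severity groups per (emotion, slot) with two-sided
#' Mann-Whitney rank-sum tests over all severity pairs; p-values are
#' Bonferroni-adjusted within each (emotion, slot) family and flagged at
#' alpha = 0.05 and 0.01.
#'
#' @param fauf_table data.frame with columns `subject_id`, `emotion`,
#'   `severity` plus one column per FAUF slot.
#' @param slots character vector of slot columns to test (default: all
#'   `_r`/`_c` columns).
#' @return data.frame with one row per emotion x slot x severity pair:
#'   group means, `p`, `p_adj`, `sig05`, `sig01`.
#' @export
group_statistics <- function(fauf_table, slots = NULL) {
  stopifnot(all(c("subject_id", "emotion", "severity") %in%
                  names(fauf_table)))
  if (is.null(slots))
    slots <- grep("_(r|c)$", names(fauf_table), value = TRUE)
  sev_levels <- c("control", "mild", "moderate", "severe")
  agg <- stats::aggregate(fauf_table[slots],
                          by = fauf_table[c("subject_id", "emotion",
                                            "severity")],
                          FUN = mean)
  rows <- list()
  for (emo in unique(agg$emotion)) {
    sub <- agg[agg$emotion == emo, ]
    groups <- intersect(sev_levels, unique(sub$severity))
    if (length(groups) < 2) next
    pairs <- utils::combn(groups, 2)
    for (sl in slots) {
      gm <- vapply(sev_levels, function(g) {
        v <- sub[sub$severity == g, sl]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      p <- apply(pairs, 2, function(pr) {
        a <- sub[sub$severity == pr[1], sl]
        b <- sub[sub$severity == pr[2], sl]
        if (length(a) < 2 || length(b) < 2) return(NA_real_)
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      })
      p_adj <- stats::p.adjust(p, method = "bonferroni")
      rows[[length(rows) + 1L]] <- data.frame(
        emotion = emo, slot = sl,
        group1 = pairs[1, ], group2 = pairs[2, ],
        mean_control = gm["control"], mean_mild = gm["mild"],
        mean_moderate = gm["moderate"], mean_severe = gm["severe"],
        p = p, p_adj = p_adj,
        sig05 = !is.na(p_adj) & p_adj < 0.05,
        sig01 = !is.na(p_adj) & p_adj < 0.01,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
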