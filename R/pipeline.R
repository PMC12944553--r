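# End-to-end orchestration: quality control -> alignment -> keyframes ->
# {FAUF, DFLGF, acoustic} -> fusion -> classifier evaluation, with a
# validated configuration object and reproducible on-disk artifacts.

#' Extract the three feature blocks of a cohort
#'
#' Runs the full visual pipeline on every clip: neutral-reference
#' construction (the subject's first neutral clip by clip id), motion
#' amplitude and keyframe selection, similarity alignment of the keyframe
#' landmarks, AU prediction (SVR/SVM over geometric features, trained on
#' the cohort's recorded AU drives, i.e. the synthetic stand-in for an
#' externally pre-trained AU model) assembled into per-clip FAUF vectors,
#' graph-convolutional embedding of the whole-face Delaunay graphs into
#' DFLGF vectors, and collection of the acoustic block.
#'
#' @param cohort a [generate_cohort()] result.
#' @param encoder a [gcn_encoder()] (default seeded encoder).
#' @param smooth_window,trim_frac,k keyframe parameters
#'   (see [amplitude_series()] and [select_keyframes()]).
#' @param au_mode `"model"` (default) predicts AUs with SVR/SVM models
#'   trained on the recorded drives; `"oracle"` uses the recorded drives
#'   directly (useful to isolate downstream stages).
#' @param au_train_max maximum keyframes used to train the AU models.
#' @param regions also embed the brows/eyes/mouth region graphs
#'   (for the region ablation).
#' @param seed seed for the AU training subsample.
#' @return list with `fauf` (n x 35), `dflgf` (n x 128), `acoustic`
#'   (n x 88), `labels` (severity factor), `manifest`, `keyframes` (list),
#'   `top_frames`, `apex_truth`, and optionally `dflgf_regions`.
#' @export
extract_cohort_features <- function(cohort, encoder = gcn_encoder(seed = 1L),
                                    smooth_window = 9L, trim_frac = 0.3,
                                    k = 5L,
                                    au_mode = c("model", "oracle"),
                                    au_train_max = 600L, regions = FALSE,
                                    seed = 0L) {
  stopifnot(inherits(cohort, "vacp_cohort"))
  au_mode <- match.arg(au_mode)
  clips <- cohort$clips
  man <- cohort$manifest

  # neutral reference per subject (first neutral clip by clip id)
  refs <- list()
  for (sid in unique(man$subject_id)) {
    neut <- man$clip_id[man$subject_id == sid & man$emotion == "neutral"]
    if (length(neut) == 0) {
      warning("subject ", sid, " has no neutral clip; using its first clip")
      neut <- man$clip_id[man$subject_id == sid]
    }
    refs[[sid]] <- build_reference(clips[[sort(neut)[1]]]$seq)
  }

  kf <- lapply(clips, function(cl) {
    series <- amplitude_series(cl$seq, refs[[cl$seq$subject_id]],
                               smooth_window = smooth_window,
                               trim_frac = trim_frac)
    select_keyframes(series, k = k)
  })

  aligned <- lapply(names(clips), function(id) {
    lapply(kf[[id]]$positions, function(pos)
      align_face(clips[[id]]$seq$frames[[pos]])$landmarks)
  })
  names(aligned) <- names(clips)

  geo <- lapply(aligned, function(frames)
    t(vapply(frames, geometric_features, numeric(146))))

  slots <- au_slots()
  truth_int <- lapply(names(clips), function(id)
    clips[[id]]$drives[kf[[id]]$positions, , drop = FALSE])
  names(truth_int) <- names(clips)

  if (au_mode == "oracle") {
    fauf <- t(vapply(names(clips), function(id) {
      ints <- truth_int[[id]]
      pres <- (ints[, slots$presence, drop = FALSE] >= 0.5) + 0
      c(stats::setNames(colMeans(ints), paste0(slots$intensity, "_r")),
        stats::setNames(colMeans(pres), paste0(slots$presence, "_c")))
    }, numeric(35)))
  } else {
    X <- do.call(rbind, geo)
    Yi <- do.call(rbind, truth_int)
    Yp <- (Yi[, slots$presence, drop = FALSE] >= 0.5) + 0
    take <- if (nrow(X) > au_train_max)
      with_seed(seed, sample(nrow(X), au_train_max)) else seq_len(nrow(X))
    models <- fit_au_models(X[take, , drop = FALSE],
                            Yi[take, , drop = FALSE],
                            Yp[take, , drop = FALSE], slots = slots)
    fauf <- t(vapply(names(clips), function(id)
      assemble_faufs(predict_au(models, geo[[id]])), numeric(35)))
  }
  rownames(fauf) <- names(clips)

  embed_region <- function(region) {
    t(vapply(names(clips), function(id) {
      graphs <- lapply(aligned[[id]], triangulate_region, region = region)
      encode_dflgf(graphs, encoder)
    }, numeric(128)))
  }
  dflgf <- embed_region("whole_face")
  dflgf_regions <- NULL
  if (regions)
    dflgf_regions <- stats::setNames(
      lapply(c("whole_face", "brows", "eyes", "mouth"), embed_region),
      c("whole_face", "brows", "eyes", "mouth"))

  acoustic <- t(vapply(clips, function(cl) cl$acoustic$vector, numeric(88)))
  rownames(acoustic) <- names(clips)

  list(fauf = fauf, dflgf = dflgf, dflgf_regions = dflgf_regions,
       acoustic = acoustic,
       labels = factor(man$severity,
                       levels = c("control", "mild", "moderate", "severe")),
       manifest = man, keyframes = kf,
       top_frames = vapply(kf, `[[`, numeric(1), "top_frame"),
       apex_truth = man$apex)
}

#' Pre-train the graph encoder on a disjoint synthetic cohort
#'
#' Generates a small cohort (disjoint seed, hence disjoint subjects from any
#' evaluation cohort), builds whole-face Delaunay graphs for three
#' mid-clip frames of every clip, and trains the encoder to discriminate
#' severity from single-frame graph geometry. The returned encoder is
#' frozen; downstream embeddings remain deterministic.
#'
#' @param seed seed of the pre-training cohort and optimisation.
#' @param n_subjects_per_class,clips_per_subject size of the pre-training
#'   cohort (defaults 6 and 6, i.e. 432 training graphs).
#' @param epochs training epochs (default 40).
#' @param encoder architecture to start from (default [gcn_encoder()]).
#' @return a trained `vacp_gcn` encoder.
#' @export
pretrained_gcn_encoder <- function(seed, n_subjects_per_class = 6L,
                                   clips_per_subject = 6L, epochs = 40L,
                                   encoder = gcn_encoder(seed = seed)) {
  co <- generate_cohort(cohort_config(
    n_subjects_per_class = n_subjects_per_class,
    clips_per_subject = clips_per_subject, seed = seed))
  graphs <- list(); labels <- character(0)
  for (cl in co$clips) {
    n <- length(cl$seq$frames)
    for (pos in unique(round(n * c(0.35, 0.5, 0.65)))) {
      al <- align_face(cl$seq$frames[[max(1, pos)]])$landmarks
      graphs[[length(graphs) + 1L]] <- triangulate_region(al, "whole_face")
      labels <- c(labels, cl$seq$severity)
    }
  }
  train_gcn_encoder(graphs, factor(labels), encoder = encoder,
                    epochs = epochs, seed = seed)
}

#' Pipeline configuration
#'
#' Single validated configuration governing all stages; unknown keys are
#' rejected. `cohort` accepts [cohort_config()] overrides (its seed
#' defaults to the pipeline seed).
#'
#' @param seed global seed.
#' @param out_dir optional artifact directory (created if needed).
#' @param cohort named list of [cohort_config()] overrides.
#' @param encoder_seed seed of the landmark-graph encoder; when
#'   `encoder_pretrain` is TRUE the encoder is pre-trained on a disjoint
#'   cohort seeded with `encoder_seed + 1000`.
#' @param encoder_pretrain pre-train the graph encoder (default TRUE).
#' @param smooth_window,trim_frac,keyframes keyframe-stage parameters.
#' @param channels feature blocks used for classification.
#' @param classifier named list of [classifier_spec()] overrides.
#' @param n_repeats,train_frac evaluation protocol.
#' @param au_mode AU source, see [extract_cohort_features()].
#' @param render render frames and run exposure QC (slower; default FALSE —
#'   landmark streams, not videos, are the pipeline's native input).
#' @param resume reuse artifacts already present in `out_dir`.
#' @return list of class `vacp_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, cohort = list(),
                            encoder_seed = 1L, encoder_pretrain = TRUE,
                            smooth_window = 9L,
                            trim_frac = 0.3, keyframes = 5L,
                            channels = c("fauf", "dflgf", "acoustic"),
                            classifier = list(), n_repeats = 5L,
                            train_frac = 0.8, au_mode = "model",
                            render = FALSE, resume = TRUE) {
  structure(as.list(environment()), class = "vacp_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments; unknown keys raise an error.
#' @return a [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], tmp,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline
#'
#' Generates (or accepts) a cohort, applies clip-level quality control,
#' extracts and fuses the feature blocks, and evaluates the classifier
#' under repeated stratified splits. Artifacts (manifest, QC report,
#' feature matrices, evaluation report with provenance) are written to
#' `cfg$out_dir` when set; with `resume = TRUE`, stages whose artifact
#' files already exist are not rewritten (all stages are deterministic
#' given the configuration, so a deleted intermediate is reproduced
#' identically).
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optional pre-built [generate_cohort()] cohort; by default
#'   one is generated from `cfg`.
#' @return list with `cohort`, `qc` (data.frame), `features`, `fused`,
#'   `eval` (a `vacp_eval`), `provenance`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "vacp_pipeline_config"))
  if (is.null(cohort)) {
    cargs <- cfg$cohort
    if (is.null(cargs$seed)) cargs$seed <- cfg$seed
    cohort <- generate_cohort(do.call(cohort_config, cargs))
  }
  qc <- do.call(rbind, lapply(cohort$clips, function(cl) {
    frames <- if (isTRUE(cfg$render)) render_frames(cl$seq) else NULL
    r <- apply_clip_filters(cl$seq$clip_id, fps = cl$seq$fps,
                            occluded = rep(FALSE, length(cl$seq$frames)),
                            frames = frames)
    data.frame(clip_id = r$clip_id, duration = r$duration,
               keep = r$keep,
               reasons = paste(r$reasons, collapse = ";"))
  }))
  rownames(qc) <- NULL
  kept <- qc$clip_id[qc$keep]
  cohort$clips <- cohort$clips[kept]
  cohort$manifest <- cohort$manifest[cohort$manifest$clip_id %in% kept, ]

  encoder <- if (isTRUE(cfg$encoder_pretrain))
    pretrained_gcn_encoder(seed = cfg$encoder_seed + 1000L)
  else gcn_encoder(seed = cfg$encoder_seed)
  features <- extract_cohort_features(
    cohort, encoder = encoder,
    smooth_window = cfg$smooth_window, trim_frac = cfg$trim_frac,
    k = cfg$keyframes, au_mode = cfg$au_mode, seed = cfg$seed)

  fused <- fuse_features(
    fauf = if ("fauf" %in% cfg$channels) features$fauf,
    dflgf = if ("dflgf" %in% cfg$channels) features$dflgf,
    acoustic = if ("acoustic" %in% cfg$channels) features$acoustic,
    channels = cfg$channels)

  cl_args <- cfg$classifier
  cl_args$seed <- cl_args$seed %||% cfg$seed
  spec <- do.call(classifier_spec, cl_args)
  ev <- evaluate_model(fused, features$labels, spec,
                       n_repeats = cfg$n_repeats,
                       train_frac = cfg$train_frac)

  provenance <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("vacp")),
                     r_version = R.version.string)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    put <- function(name, writer) {
      path <- file.path(cfg$out_dir, name)
      if (!(isTRUE(cfg$resume) && file.exists(path))) writer(path)
      path
    }
    put("manifest.csv",
        function(p) utils::write.csv(cohort$manifest, p, row.names = FALSE))
    put("qc.csv", function(p) utils::write.csv(qc, p, row.names = FALSE))
    put("features_fused.csv", function(p)
      utils::write.csv(data.frame(clip_id = rownames(fused), fused,
                                  check.names = FALSE), p, row.names = FALSE))
    put("evaluation.json", function(p)
      jsonlite::write_json(list(per_split = ev$per_split,
                                mean_accuracy = ev$mean_accuracy,
                                mean_f1 = ev$mean_f1,
                                confusion = ev$confusion,
                                provenance = provenance),
                           p, auto_unbox = TRUE, digits = NA))
  }
  list(cohort = cohort, qc = qc, features = features, fused = fused,
       eval = ev, provenance = provenance)
}
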