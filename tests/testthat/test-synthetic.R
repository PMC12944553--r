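test_that("cohorts are deterministic given the seed", {
  a <- tiny_cohort(seed = 5)
  b <- tiny_cohort(seed = 5)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$clips[[1]]$seq$frames[[3]]$points,
                   b$clips[[1]]$seq$frames[[3]]$points)
  expect_identical(a$clips[[2]]$acoustic$vector,
                   b$clips[[2]]$acoustic$vector)
  c2 <- tiny_cohort(seed = 6)
  expect_false(identical(a$clips[[1]]$seq$frames[[3]]$points,
                         c2$clips[[1]]$seq$frames[[3]]$points))
})

test_that("generated clips respect the study's structural rules", {
  co <- generate_cohort(cohort_config(n_subjects_per_class = 2,
                                      clips_per_subject = 5, seed = 3))
  man <- co$manifest
  expect_true(all(man$n_frames / man$fps >= 2 & man$n_frames / man$fps <= 6))
  expect_true(all(table(man$severity) == 10))
  # every subject has a neutral clip; apexes recorded only for emotional
  for (sid in unique(man$subject_id))
    expect_true("neutral" %in% man$emotion[man$subject_id == sid])
  expect_true(all(is.na(man$apex[man$emotion == "neutral"])))
  emo <- man[man$emotion != "neutral", ]
  expect_true(all(emo$apex >= 0 & emo$apex < emo$n_frames))
  # 68 landmarks per frame, AU drives within the FACS scale
  cl <- co$clips[[1]]
  expect_true(all(vapply(cl$seq$frames,
                         function(f) nrow(f$points) == 68, logical(1))))
  expect_true(all(co$clips[[5]]$drives >= 0 & co$clips[[5]]$drives <= 5))
  expect_error(cohort_config(seed = 1, duration_range = c(1, 6)), "2, 6")
  expect_error(cohort_config(clips_per_subject = 2), "seed")
})

test_that("planted perioral attenuation orders the severity classes", {
  co <- generate_cohort(cohort_config(n_subjects_per_class = 3,
                                      clips_per_subject = 5, seed = 8))
  man <- co$manifest
  mean_au12 <- vapply(c("control", "mild", "moderate", "severe"),
                      function(sev) {
    ids <- man$clip_id[man$severity == sev & man$emotion == "happy"]
    mean(vapply(ids, function(id) max(co$clips[[id]]$drives[, "AU12"]),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_au12) < 0))  # control > mild > moderate > severe

  # AU4 under sadness: severe exceeds moderate, both below control
  mean_au4 <- vapply(c("control", "moderate", "severe"), function(sev) {
    ids <- man$clip_id[man$severity == sev & man$emotion == "sad"]
    mean(vapply(ids, function(id) max(co$clips[[id]]$drives[, "AU04"]),
                numeric(1)))
  }, numeric(1))
  expect_gt(mean_au4["severe"], mean_au4["moderate"])
  expect_gt(mean_au4["control"], mean_au4["severe"])
})

test_that("a noiseless clip's amplitude peaks exactly at the planted apex", {
  co <- generate_cohort(cohort_config(n_subjects_per_class = 1,
                                      clips_per_subject = 8,
                                      landmark_jitter_sd = 0, seed = 12))
  man <- co$manifest
  neut <- sort(man$clip_id[man$emotion == "neutral"])[1]
  ref <- build_reference(co$clips[[neut]]$seq)
  for (id in man$clip_id[man$emotion != "neutral"]) {
    a <- amplitude_series(co$clips[[id]]$seq, ref, trim_frac = 0)
    expect_equal(which.max(a$amplitude) - 1L, co$clips[[id]]$apex,
                 info = id)
  }
})

test_that("rendered frames are deterministic and QC-compatible", {
  co <- tiny_cohort(seed = 15)
  neut <- co$clips[[grep("neutral", names(co$clips))[1]]]
  short <- landmark_sequence(neut$seq$frames[1:2], clip_id = "r",
                             subject_id = "s", emotion = "neutral",
                             severity = "control")
  f1 <- render_frames(short)
  f2 <- render_frames(short)
  expect_identical(f1, f2)
  expect_equal(dim(f1[[1]]), c(200, 200))
  expect_true(all(f1[[1]] >= 0 & f1[[1]] <= 255))

  # default rendering passes exposure QC
  e <- assess_exposure(luminance_histogram(f1[[1]]))
  expect_false(e$overexposed || e$underexposed)

  # pushing the background into the bright band crosses the 5% rule
  bright <- render_frames(short, background = 255, brightness_offset = 0)
  eb <- assess_exposure(luminance_histogram(bright[[1]]))
  expect_true(eb$overexposed)
})
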