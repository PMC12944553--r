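test_that("the acoustic slot schema has 88 unique names", {
  slots <- egemaps_slots()
  expect_length(slots, 88)
  expect_equal(anyDuplicated(slots), 0)
})

test_that("functional CSV ingestion validates the slot contract", {
  slots <- egemaps_slots()
  row <- as.data.frame(as.list(stats::setNames(rnorm(88), slots)),
                       check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(clip_id = "c1", row), path, row.names = FALSE)
  got <- ingest_egemaps(path)
  expect_length(got$c1$vector, 88)
  expect_named(got$c1$vector, slots)

  # missing slot named in the error
  bad <- row[, -5]
  utils::write.csv(cbind(clip_id = "c1", bad), path, row.names = FALSE)
  expect_error(ingest_egemaps(path), slots[5], fixed = TRUE)

  # extra column warns, duplicate clip keeps the last row
  two <- rbind(cbind(clip_id = "c1", row, junk = 1),
               cbind(clip_id = "c1", row + 1, junk = 1))
  utils::write.csv(two, path, row.names = FALSE)
  expect_warning(expect_warning(got2 <- ingest_egemaps(path), "extra"),
                 "duplicated")
  expect_equal(unname(got2$c1$vector[1]), row[[1]] + 1, tolerance = 1e-9)
})

test_that("write/ingest round-trips the slot vectors", {
  f <- vacp:::new_acoustic_feature(seq_len(88) / 10, "clipA")
  path <- tempfile(fileext = ".csv")
  write_egemaps(list(f), path)
  back <- ingest_egemaps(path)
  expect_equal(back$clipA$vector, f$vector)
})

test_that("the built-in extractor recovers a pure tone's pitch", {
  sr <- 16000
  t <- seq(0, 1, length.out = sr)
  wave <- 0.5 * sin(2 * pi * 440 * t)
  f <- extract_builtin(wave, sr)
  expect_length(f$vector, 88)
  f0_hz <- 27.5 * 2^(f$vector[["F0semitoneFrom27.5Hz_sma3nz_amean"]] / 12)
  expect_equal(f0_hz, 440, tolerance = 1)

  silent <- extract_builtin(rep(0, sr), sr)
  expect_true(attr(silent, "silent"))
  expect_equal(unname(silent$vector[["loudness_sma3_amean"]]), 0)

  expect_error(extract_builtin(wave, 4000), "8000")
  expect_error(extract_builtin(wave[1:100], sr), "0.1 s")
})

test_that("amplitude scaling leaves pitch slots fixed, raises energy", {
  sr <- 16000
  t <- seq(0, 0.8, length.out = round(0.8 * sr))
  wave <- 0.3 * sin(2 * pi * 220 * t) * (1 + 0.3 * sin(2 * pi * 3 * t))
  a <- extract_builtin(wave, sr)
  b <- extract_builtin(2 * wave, sr)
  expect_equal(b$vector[["F0semitoneFrom27.5Hz_sma3nz_amean"]],
               a$vector[["F0semitoneFrom27.5Hz_sma3nz_amean"]],
               tolerance = 1e-6)
  expect_gt(b$vector[["loudness_sma3_amean"]],
            a$vector[["loudness_sma3_amean"]])
  expect_gt(b$vector[["equivalentSoundLevel_dBp"]],
            a$vector[["equivalentSoundLevel_dBp"]])
})

test_that("the minimal WAV reader round-trips PCM16 audio", {
  sr <- 8000
  wave <- round(sin(2 * pi * 100 * seq(0, 0.2, length.out = 1600)) * 20000)
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(wave)), con, size = 4,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(wave)), con, size = 4, endian = "little")
  writeBin(as.integer(wave), con, size = 2, endian = "little")
  close(con)
  got <- read_wav(path)
  expect_equal(got$sr, sr)
  expect_equal(got$wave, wave / 32768, tolerance = 1e-9)
})
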