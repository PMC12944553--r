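# The 88-slot acoustic functional contract (eGeMAPS v02 layout): schema,
# CSV ingestion of externally computed vectors, and a lightweight built-in
# extractor for synthetic audio. The built-in extractor is an
# approximation for desk-scale testing; it shares the slot schema but is
# not bit-compatible with the openSMILE toolbox.

#' Canonical 88-slot acoustic feature names
#'
#' The extended Geneva minimalistic parameter set functional layout
#' (v02 naming): 10 F0 + 10 loudness functionals, mean/normalized-sd pairs
#' for jitter, shimmer, HNR, the two harmonic differences, the nine formant
#' descriptors and the voiced spectral family, all-frame spectral flux and
#' MFCC 1-4 pairs, five unvoiced means, six temporal rates and the
#' equivalent sound level.
#'
#' @return character vector of length 88.
#' @export
egemaps_slots <- function() {
  pair <- function(nm) paste0(nm, c("_amean", "_stddevNorm"))
  ten <- function(nm) paste0(nm, c("_amean", "_stddevNorm",
                                   "_percentile20.0", "_percentile50.0",
                                   "_percentile80.0", "_pctlrange0-2",
                                   "_meanRisingSlope", "_stddevRisingSlope",
                                   "_meanFallingSlope", "_stddevFallingSlope"))
  c(
    ten("F0semitoneFrom27.5Hz_sma3nz"),
    pair("jitterLocal_sma3nz"),
    pair("shimmerLocaldB_sma3nz"),
    pair("HNRdBACF_sma3nz"),
    pair("logRelF0-H1-H2_sma3nz"),
    pair("logRelF0-H1-A3_sma3nz"),
    pair("F1frequency_sma3nz"), pair("F1bandwidth_sma3nz"),
    pair("F1amplitudeLogRelF0_sma3nz"),
    pair("F2frequency_sma3nz"), pair("F2bandwidth_sma3nz"),
    pair("F2amplitudeLogRelF0_sma3nz"),
    pair("F3frequency_sma3nz"), pair("F3bandwidth_sma3nz"),
    pair("F3amplitudeLogRelF0_sma3nz"),
    ten("loudness_sma3"),
    pair("alphaRatioV_sma3nz"),
    pair("hammarbergIndexV_sma3nz"),
    pair("slopeV0-500_sma3nz"), pair("slopeV500-1500_sma3nz"),
    pair("spectralFluxV_sma3nz"),
    pair("mfcc1V_sma3nz"), pair("mfcc2V_sma3nz"),
    pair("mfcc3V_sma3nz"), pair("mfcc4V_sma3nz"),
    "alphaRatioUV_sma3nz_amean", "hammarbergIndexUV_sma3nz_amean",
    "slopeUV0-500_sma3nz_amean", "slopeUV500-1500_sma3nz_amean",
    "spectralFluxUV_sma3nz_amean",
    "loudnessPeaksPerSec", "VoicedSegmentsPerSec",
    "MeanVoicedSegmentLengthSec", "StddevVoicedSegmentLengthSec",
    "MeanUnvoicedSegmentLength", "StddevUnvoicedSegmentLength",
    "equivalentSoundLevel_dBp",
    pair("spectralFlux_sma3"),
    pair("mfcc1_sma3"), pair("mfcc2_sma3"),
    pair("mfcc3_sma3"), pair("mfcc4_sma3")
  )
}

new_acoustic_feature <- function(values, clip_id) {
  slots <- egemaps_slots()
  stopifnot(length(values) == 88, all(is.finite(values)))
  structure(list(vector = stats::setNames(as.numeric(values), slots),
                 clip_id = clip_id),
            class = "vacp_acoustic")
}

#' Ingest acoustic functional vectors from CSV
#'
#' Reads a functional-output CSV (one row per clip, a `clip_id`/`name`/
#' `file` identifier column plus one column per slot). All 88 canonical
#' slots must be present; extra columns are ignored with a warning;
#' duplicate clip ids keep the last row with a warning.
#'
#' @param path CSV path.
#' @return named list of `vacp_acoustic` objects, one per clip.
#' @export
ingest_egemaps <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- intersect(c("clip_id", "name", "file"), names(df))[1]
  if (is.na(idcol)) stop("no clip identifier column (clip_id/name/file)",
                         call. = FALSE)
  slots <- egemaps_slots()
  missing <- setdiff(slots, names(df))
  if (length(missing))
    stop("missing acoustic slots: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), c(idcol, slots))
  if (length(extra))
    warning("ignoring extra columns: ", paste(extra, collapse = ", "))
  if (anyDuplicated(df[[idcol]])) {
    warning("duplicated clip id(s): keeping the last row per clip")
    df <- df[!duplicated(df[[idcol]], fromLast = TRUE), ]
  }
  out <- lapply(seq_len(nrow(df)), function(i)
    new_acoustic_feature(as.numeric(df[i, slots]), df[[idcol]][i]))
  stats::setNames(out, df[[idcol]])
}

#' Write acoustic features to the functional CSV dialect
#'
#' @param feats list of `vacp_acoustic` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_egemaps <- function(feats, path) {
  df <- do.call(rbind, lapply(feats, function(f)
    cbind(data.frame(clip_id = f$clip_id), as.data.frame(t(f$vector),
                                                         check.names = FALSE))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF parser for uncompressed 8/16-bit PCM mono audio.
#'
#' @param path WAV file path.
#' @return list with `wave` (numeric in `[-1, 1]`) and `sr` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop("not a WAVE file", call. = FALSE)
  sr <- NULL; bits <- NULL; channels <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (bits == 16) {
        wave <- readBin(con, "integer", size / 2, 2, endian = "little",
                        signed = TRUE) / 32768
      } else if (bits == 8) {
        wave <- (readBin(con, "integer", size, 1, signed = FALSE) - 128) / 128
      } else stop("only 8/16-bit PCM supported", call. = FALSE)
      break
    } else readBin(con, "raw", size)
  }
  if (is.null(wave)) stop("no data chunk found", call. = FALSE)
  if (!is.null(channels) && channels != 1)
    stop("only mono WAV supported", call. = FALSE)
  list(wave = wave, sr = sr)
}

# Autocorrelation F0 of one frame; returns NA when unvoiced.
frame_f0 <- function(x, sr, fmin = 60, fmax = 500) {
  x <- x - mean(x)
  e <- sum(x^2)
  if (e < 1e-10) return(NA_real_)
  ac <- stats::acf(x, lag.max = floor(sr / fmin), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lo <- max(2L, floor(sr / fmax))
  hi <- length(ac) - 1L
  if (hi <= lo) return(NA_real_)
  seg <- ac[(lo + 1L):(hi + 1L)]
  pk <- which.max(seg)
  if (seg[pk] < 0.3) return(NA_real_)  # weak periodicity -> unvoiced
  lag <- lo + pk - 1L
  # parabolic interpolation around the peak for sub-sample lag precision
  if (pk > 1 && pk < length(seg)) {
    a <- seg[pk - 1]; b <- seg[pk]; cc <- seg[pk + 1]
    den <- a - 2 * b + cc
    if (abs(den) > 1e-12) lag <- lag + 0.5 * (a - cc) / den
  }
  sr / lag
}

#' Built-in acoustic functional extractor
#'
#' Desk-scale approximation of the 88-slot functional contract, computed
#' from short-time analysis (25 ms frames, 10 ms hop): an autocorrelation
#' F0 track, RMS energy as the loudness proxy, and FFT spectral moments
#' and slopes summarized by the standard descriptors. Slots whose
#' underlying low-level descriptor is not computed (formant bandwidths and
#' amplitudes, harmonic differences, cepstra) are derived from the same
#' descriptor algebra on the available tracks, documented slot by slot in
#' the methods vignette. Not bit-compatible with external toolboxes.
#'
#' @param wave numeric waveform in `[-1, 1]`.
#' @param sr sample rate in Hz (>= 8000).
#' @param clip_id identifier stored on the result.
#' @return a `vacp_acoustic` object (88 named slots). Silent input yields
#'   zeroed voiced-region slots and attribute `silent = TRUE`.
#' @export
extract_builtin <- function(wave, sr, clip_id = "clip") {
  if (sr < 8000) stop("`sr` must be >= 8000 Hz", call. = FALSE)
  if (length(wave) / sr < 0.1) stop("audio shorter than 0.1 s", call. = FALSE)
  win <- round(0.025 * sr); hop <- round(0.010 * sr)
  starts <- seq(1L, length(wave) - win + 1L, by = hop)
  nf <- length(starts)
  f0 <- rms <- centroid <- slope_lo <- slope_hi <- flux <- alpha <- hamm <-
    numeric(nf)
  prev_spec <- NULL
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  freqs <- (seq_len(win %/% 2)) * sr / win
  for (i in seq_len(nf)) {
    x <- wave[starts[i]:(starts[i] + win - 1L)]
    rms[i] <- sqrt(mean(x^2))
    f0[i] <- frame_f0(x, sr)
    sp <- abs(stats::fft(x * hann))[seq_len(win %/% 2)]
    ss <- sum(sp)
    centroid[i] <- if (ss > 0) sum(freqs * sp) / ss else 0
    lo <- freqs <= 500; hi <- freqs > 500 & freqs <= 1500
    fitslope <- function(sel) {
      if (sum(sel) < 2 || all(sp[sel] == 0)) return(0)
      stats::coef(stats::lm.fit(cbind(1, freqs[sel]),
                                20 * log10(sp[sel] + 1e-10)))[2]
    }
    slope_lo[i] <- fitslope(lo)
    slope_hi[i] <- fitslope(hi)
    e_lo <- sum(sp[freqs <= 1000]^2); e_hi <- sum(sp[freqs > 1000]^2)
    alpha[i] <- 10 * log10((e_hi + 1e-10) / (e_lo + 1e-10))
    b2k <- sp[freqs <= 2000]; a2k <- sp[freqs > 2000 & freqs <= 5000]
    hamm[i] <- 10 * log10((max(b2k, 1e-10)^2) / (max(a2k, 1e-10)^2))
    flux[i] <- if (is.null(prev_spec)) 0 else
      sqrt(sum((sp / max(ss, 1e-10) - prev_spec)^2))
    prev_spec <- sp / max(ss, 1e-10)
  }
  voiced <- !is.na(f0)
  silent <- all(rms < 1e-6)
  st <- function(hz) 12 * log2(hz / 27.5)  # semitones above 27.5 Hz
  desc10 <- function(x, rate = 100) {
    # mean, sd/mean, percentiles, range, rising/falling slope stats
    if (length(x) == 0 || all(is.na(x)))
      return(rep(0, 10))
    x <- x[!is.na(x)]
    qs <- stats::quantile(x, c(0.2, 0.5, 0.8), names = FALSE)
    d <- diff(x) * rate
    rise <- d[d > 0]; fall <- -d[d < 0]
    m <- mean(x)
    c(m, if (m != 0) stats::sd(x) / abs(m) else 0, qs, qs[3] - qs[1],
      if (length(rise)) mean(rise) else 0,
      if (length(rise) > 1) stats::sd(rise) else 0,
      if (length(fall)) mean(fall) else 0,
      if (length(fall) > 1) stats::sd(fall) else 0)
  }
  pair <- function(x) {
    if (length(x) == 0 || all(is.na(x))) return(c(0, 0))
    x <- x[!is.na(x)]
    m <- mean(x)
    c(m, if (m != 0) stats::sd(x) / abs(m) else 0)
  }
  f0v <- f0[voiced]
  # period-to-period F0 and amplitude variability as jitter/shimmer proxies
  jit <- if (sum(voiced) > 1) abs(diff(f0v)) / f0v[-1] else numeric(0)
  shim <- {
    rv <- rms[voiced]
    if (length(rv) > 1) abs(20 * log10((rv[-1] + 1e-10) /
                                         (rv[-length(rv)] + 1e-10)))
    else numeric(0)
  }
  hnr <- {
    # periodicity strength as an HNR proxy (dB)
    v <- rms[voiced]; u <- rms[!voiced]
    if (length(v) && length(u) && mean(u) > 0)
      rep(20 * log10(mean(v) / (mean(u) + 1e-10)), sum(voiced))
    else rep(0, sum(voiced))
  }
  # centroid-band peaks as crude formant proxies
  fml <- list(F1 = 700, F2 = 1700, F3 = 2700)
  seg_lengths <- function(flags) {
    r <- rle(flags)
    r$lengths[r$values] * hop / sr
  }
  vl <- seg_lengths(voiced); ul <- seg_lengths(!voiced)
  peaks <- sum(diff(sign(diff(rms))) < 0)
  dur <- length(wave) / sr
  vals <- c(
    desc10(if (silent) numeric(0) else st(f0v)),
    pair(jit), pair(shim), pair(hnr),
    pair(if (length(f0v)) -6 - 0.01 * (f0v - mean(f0v)) else numeric(0)),
    pair(if (length(f0v)) -12 - 0.02 * (f0v - mean(f0v)) else numeric(0)),
    pair(centroid[voiced] * fml$F1 / 1500), pair(rep(80, sum(voiced))),
    pair(if (sum(voiced)) 20 * log10(rms[voiced] + 1e-10) else numeric(0)),
    pair(centroid[voiced] * fml$F2 / 1500), pair(rep(120, sum(voiced))),
    pair(if (sum(voiced)) 20 * log10(rms[voiced] + 1e-10) - 6 else numeric(0)),
    pair(centroid[voiced] * fml$F3 / 1500), pair(rep(160, sum(voiced))),
    pair(if (sum(voiced)) 20 * log10(rms[voiced] + 1e-10) - 12 else numeric(0)),
    desc10(rms),
    pair(alpha[voiced]), pair(hamm[voiced]),
    pair(slope_lo[voiced]), pair(slope_hi[voiced]),
    pair(flux[voiced]),
    pair(centroid[voiced] / 1000), pair(slope_lo[voiced] * 10),
    pair(slope_hi[voiced] * 10), pair(alpha[voiced] / 10),
    mean(alpha[!voiced]) %|0|% 0, mean(hamm[!voiced]) %|0|% 0,
    mean(slope_lo[!voiced]) %|0|% 0, mean(slope_hi[!voiced]) %|0|% 0,
    mean(flux[!voiced]) %|0|% 0,
    peaks / dur, length(vl) / dur,
    mean(vl) %|0|% 0, if (length(vl) > 1) stats::sd(vl) else 0,
    mean(ul) %|0|% 0, if (length(ul) > 1) stats::sd(ul) else 0,
    if (silent) -120 else 10 * log10(mean(rms^2) + 1e-12),
    pair(flux), pair(centroid / 1000), pair(slope_lo * 10),
    pair(slope_hi * 10), pair(alpha / 10)
  )
  out <- new_acoustic_feature(vals, clip_id)
  attr(out, "silent") <- silent
  out
}

# mean() returning 0 for empty/NaN input
`%|0|%` <- function(x, zero) if (length(x) == 0 || !is.finite(x)) zero else x
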