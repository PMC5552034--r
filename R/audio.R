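#' Mono audio clips
#'
#' An audio clip is a lightweight container for a mono amplitude sequence in
#' \[-1, 1\] and its sample rate. Duration is derived as
#' `length(samples) / sample_rate`.
#'
#' @param samples Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `duration`.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0) {
    abort("samples must be a non-empty numeric vector")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("sample_rate must be a single positive number")
  }
  if (!all(is.finite(samples))) abort("samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9) {
    warn("samples exceed [-1, 1]; clipping")
    samples <- pmin(pmax(samples, -1), 1)
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration = length(samples) / sample_rate),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %g Hz (%d samples)\n",
              x$duration, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Read / write a mono WAV file
#'
#' Minimal RIFF/WAVE codec for PCM 16-bit and IEEE float 32-bit files.
#' Stereo input is down-mixed to mono by channel averaging, with a warning.
#'
#' @param path File path.
#' @return `read_wav()` returns an [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") abort("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") abort("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    chunk <- rawToChar(id)
    if (chunk == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (chunk == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("missing fmt or data chunk")
  n <- length(data_raw)
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n / 2, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n / 4, size = 4, endian = "little")
  } else {
    abort(sprintf("unsupported WAV encoding (format %d, %d bit); use PCM16 or float32",
                  fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels == 2L) {
    warn("stereo WAV down-mixed to mono")
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
  } else if (fmt$n_channels != 1L) {
    abort("only mono or stereo WAV is supported")
  }
  audio_clip(pmin(pmax(x, -1), 1), fmt$sample_rate)
}

#' @rdname read_wav
#' @param clip An [audio_clip()].
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(clip, path, bits = 16) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16, 32))
  sr <- as.integer(round(clip$sample_rate))
  n <- length(clip$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmin(pmax(clip$samples, -1), 1) * 32767)),
             con, size = 2, endian = "little")
  } else {
    writeBin(clip$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Prosody extraction configuration
#'
#' Operational definitions of the prosodic features (all tunable):
#' fundamental frequency by short-time autocorrelation with parabolic peak
#' interpolation, searched in `f0_min..f0_max` Hz over `frame_s`-long
#' windows advanced by `hop_s`; silence detected on non-overlapping `hop_s`
#' frames below `silence_db` dBFS; a pause is a silent interval of at least
#' `min_pause_s` seconds.
#'
#' @param frame_s Analysis window for F0, seconds (default 0.04, long
#'   enough for two periods at `f0_min` = 75 Hz).
#' @param hop_s Hop between frames, seconds (default 0.01).
#' @param f0_min,f0_max F0 search range, Hz (default 75-500).
#' @param silence_db Silence threshold, dB relative to full scale
#'   (default -35).
#' @param min_pause_s Minimum silent-interval length counted as a pause,
#'   seconds (default 0.3).
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.5).
#' @return A list of class `prosody_config`.
#' @export
prosody_config <- function(frame_s = 0.04, hop_s = 0.01, f0_min = 75,
                           f0_max = 500, silence_db = -35, min_pause_s = 0.3,
                           voicing_threshold = 0.5) {
  stopifnot(frame_s > 0, hop_s > 0, f0_min > 0, f0_max > f0_min,
            min_pause_s > 0, voicing_threshold > 0, voicing_threshold < 1)
  structure(list(frame_s = frame_s, hop_s = hop_s, f0_min = f0_min,
                 f0_max = f0_max, silence_db = silence_db,
                 min_pause_s = min_pause_s,
                 voicing_threshold = voicing_threshold),
            class = "prosody_config")
}

# frame a signal into a (frame_len x n_frames) matrix, zero-padding the tail
frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  n_frames <- max(1L, 1L + floor((n - frame_len) / hop))
  idx <- outer(seq_len(frame_len) - 1L, (seq_len(n_frames) - 1L) * hop, "+") + 1L
  m <- matrix(0, frame_len, n_frames)
  ok <- idx <= n
  m[ok] <- x[idx[ok]]
  m
}

# normalized autocorrelation of each column via FFT; returns (frame_len x n) matrix
frame_autocorr <- function(frames) {
  frame_len <- nrow(frames)
  frames <- sweep(frames, 2, colMeans(frames))
  nfft <- 2^ceiling(log2(2 * frame_len))
  padded <- rbind(frames, matrix(0, nfft - frame_len, ncol(frames)))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(Mod(spec)^2, inverse = TRUE)) / nfft
  r0 <- ac[1, ]
  r0[r0 <= 0] <- Inf  # silent frame: normalized autocorr -> 0
  sweep(ac[seq_len(frame_len), , drop = FALSE], 2, r0, "/")
}

# per-frame F0 by autocorrelation peak with parabolic interpolation
frame_f0 <- function(frames, sample_rate, cfg) {
  ac <- frame_autocorr(frames)
  lag_min <- max(2L, floor(sample_rate / cfg$f0_max))
  lag_max <- min(nrow(ac) - 2L, ceiling(sample_rate / cfg$f0_min))
  if (lag_max <= lag_min) abort("frame too short for the requested F0 range")
  lags <- lag_min:lag_max
  window <- ac[lags + 1L, , drop = FALSE]  # row 1 is lag 0
  best <- apply(window, 2, which.max)
  n <- ncol(ac)
  peak <- window[cbind(best, seq_len(n))]
  lag_best <- lags[best]
  # parabolic interpolation around the integer-lag peak
  y1 <- ac[cbind(lag_best, seq_len(n))]
  y2 <- peak
  y3 <- ac[cbind(lag_best + 2L, seq_len(n))]
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  f0 <- sample_rate / (lag_best + delta)
  list(f0 = f0, strength = peak)
}

#' Extract prosodic features from an audio clip
#'
#' Computes the four prosodic narrative features:
#'
#' * `f0_variation` — standard deviation, in semitones, of the per-frame
#'   fundamental frequency over voiced frames.
#' * `amplitude` — mean frame RMS level in dB relative to full scale,
#'   over frames with non-zero energy.
#' * `voice_quality` — a jitter-like index: the mean absolute
#'   period-to-period change of the F0 period between consecutive voiced
#'   frames, relative to the mean period (unitless; 0 for a steady tone).
#' * `pause_ratio` — fraction of the clip occupied by silent intervals at
#'   least `min_pause_s` long, in \[0, 1\].
#'
#' For an all-silent clip, `f0_variation` and `voice_quality` are undefined
#' and returned as `NA` (explicitly missing, never silent zeros).
#'
#' @param clip An [audio_clip()].
#' @param cfg A [prosody_config()].
#' @return A one-row tibble with the four features plus `n_voiced_frames`
#'   and `n_frames`.
#' @export
#' @examples
#' clip <- audio_clip(sin(2 * pi * 220 * seq(0, 1, by = 1 / 16000)), 16000)
#' extract_prosody(clip)
extract_prosody <- function(clip, cfg = prosody_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  sr <- clip$sample_rate
  x <- clip$samples

  # --- silence / amplitude / pauses on non-overlapping hop-length frames
  hop_len <- max(1L, round(cfg$hop_s * sr))
  n_hops <- floor(length(x) / hop_len)
  if (n_hops == 0) abort("clip shorter than one analysis frame")
  hop_mat <- matrix(x[seq_len(n_hops * hop_len)], hop_len, n_hops)
  rms <- sqrt(colMeans(hop_mat^2))
  db <- ifelse(rms > 0, 20 * log10(rms), -Inf)
  amplitude <- if (any(rms > 0)) mean(db[rms > 0]) else NA_real_

  silent <- db < cfg$silence_db
  runs <- rle(silent)
  run_secs <- runs$lengths * hop_len / sr
  pause_time <- sum(run_secs[runs$values & run_secs >= cfg$min_pause_s])
  pause_ratio <- min(1, pause_time / clip$duration)

  # --- F0 on overlapping frame_s windows
  frame_len <- max(2L, round(cfg$frame_s * sr))
  frames <- frame_signal(x, frame_len, hop_len)
  frame_rms <- sqrt(colMeans(frames^2))
  loud <- frame_rms > 0 & 20 * log10(pmax(frame_rms, 1e-12)) >= cfg$silence_db
  f0_variation <- NA_real_
  voice_quality <- NA_real_
  n_voiced <- 0L
  if (any(loud)) {
    est <- frame_f0(frames[, loud, drop = FALSE], sr, cfg)
    voiced <- est$strength >= cfg$voicing_threshold
    f0 <- rep(NA_real_, ncol(frames))
    f0[which(loud)[voiced]] <- est$f0[voiced]
    n_voiced <- sum(voiced)
    if (n_voiced >= 2) {
      semitones <- 12 * log2(f0[!is.na(f0)])
      f0_variation <- sd(semitones)
      # consecutive voiced frames only, so pauses do not fake perturbation
      idx <- which(!is.na(f0))
      adj <- idx[which(diff(idx) == 1L)]
      if (length(adj) >= 1) {
        periods <- 1 / f0
        dp <- abs(periods[adj + 1L] - periods[adj])
        voice_quality <- mean(dp) / mean(periods[!is.na(f0)])
      }
    }
  }

  tibble::tibble(
    f0_variation = f0_variation,
    amplitude = amplitude,
    voice_quality = voice_quality,
    pause_ratio = pause_ratio,
    n_voiced_frames = n_voiced,
    n_frames = ncol(frames)
  )
}
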