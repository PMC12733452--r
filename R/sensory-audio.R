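#' MIDI note number to frequency
#'
#' @param pitch MIDI note number (69 = A4 = 440 Hz).
#' @return frequency in Hz.
#' @export
midi_to_hz <- function(pitch) 440 * 2^((pitch - 69) / 12)

# additive tone: `harmonic_count` partials at amplitudes 1/n, with short
# cosine attack/release ramps to avoid clicks
additive_tone <- function(freq, n_samples, sample_rate, harmonics) {
  t <- seq_len(n_samples) / sample_rate
  x <- 0
  for (h in seq_len(harmonics)) {
    x <- x + sin(2 * pi * freq * h * t) / h
  }
  ramp <- min(round(0.01 * sample_rate), floor(n_samples / 2))
  if (ramp > 0) {
    env <- rep(1, n_samples)
    up <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
    env[seq_len(ramp)] <- up
    env[n_samples + 1 - seq_len(ramp)] <- rev(up)
    x <- x * env
  }
  x
}

#' Render an anomaly report as a stereo sonification
#'
#' Regions are rendered in descending-area order, one time slot of
#' `duration_per_region` seconds each.  Within a slot the region's melody
#' (pitches from its [region_to_musical_scale()] mapping) is played with
#' additive synthesis (`harmonic_count` partials at `1/n` amplitudes); the
#' inter-onset interval is one beat at `tempo` divided by the region count,
#' so denser pathology produces denser rhythm.  A severity dyad
#' ([anomaly_to_dissonance()]) sounds underneath the melody, tremolo
#' (amplitude modulation) depth grows with severity, overall region gain
#' follows its normalized mean z-score, and the region is panned with the
#' constant-power law from its centroid column (column 1 = full left).  The
#' final mix is peak-normalized to 0.9.  Synthesis is fully deterministic.
#'
#' @param image unit-interval intensity matrix (used for the slot layout
#'   and panning geometry).
#' @param mask binary predicted mask the report was derived from.
#' @param report a [anomaly_report()] result.
#' @param config a [sonification_config()].
#' @return an object of class `sonoseg_audio`: list with `left`, `right`
#'   (equal-length samples in `[-1, 1]`) and `sample_rate`.  An empty
#'   report yields `duration_per_region` seconds of silence.
#' @export
create_advanced_brain_sonification <- function(image, mask, report,
                                               config = sonification_config()) {
  stopifnot(inherits(report, "sonoseg_anomaly_report"))
  sr <- config$sample_rate
  regions <- report$regions
  n_regions <- nrow(regions)
  slot <- round(config$duration_per_region * sr)
  if (n_regions == 0L) {
    z <- numeric(slot)
    return(new_audio(z, z, sr, config))
  }
  W <- ncol(to_gray(image))
  npx <- prod(report$image_size)
  total <- slot * n_regions
  left <- numeric(total)
  right <- numeric(total)
  beat <- 60 / config$tempo
  ioi <- beat / n_regions
  for (r in seq_len(n_regions)) {
    reg <- regions[r, ]
    sc <- region_to_musical_scale(reg, config, npx)
    pitches <- phrase_pitches(reg, sc)
    zr <- reg$mean_zscore
    gain <- 0.4 + 0.6 * min(max(ifelse(is.na(zr), 0.5, zr / 5), 0), 1)
    sev <- reg$severity %||% "none"
    trem_depth <- switch(sev, high = 0.6, moderate = 0.3, 0)
    mono <- numeric(slot)
    note_len <- max(16L, round(0.9 * ioi * sr))
    for (i in seq_along(pitches)) {
      at <- round((i - 1) * ioi * sr) + 1L
      if (at > slot) break
      len <- min(note_len, slot - at + 1L)
      mono[at:(at + len - 1L)] <- mono[at:(at + len - 1L)] +
        additive_tone(midi_to_hz(pitches[i]), len, sr, config$harmonic_count)
    }
    dyad <- anomaly_to_dissonance(sev, sc$root_pitch)
    for (p in dyad) {
      mono <- mono + 0.25 * additive_tone(midi_to_hz(p - 12L), slot, sr,
                                          config$harmonic_count)
    }
    if (trem_depth > 0) {
      tt <- seq_len(slot) / sr
      mono <- mono * (1 - trem_depth / 2 + (trem_depth / 2) *
                        sin(2 * pi * 6 * tt))
    }
    mono <- mono * gain
    pan <- if (W > 1) (reg$centroid_col - 1) / (W - 1) else 0.5
    lo <- (r - 1L) * slot
    left[lo + seq_len(slot)] <- mono * cos(pan * pi / 2)
    right[lo + seq_len(slot)] <- mono * sin(pan * pi / 2)
  }
  peak <- max(abs(c(left, right)))
  if (peak > 0) {
    left <- left / peak * 0.9
    right <- right / peak * 0.9
  }
  new_audio(left, right, sr, config)
}

new_audio <- function(left, right, sample_rate, config = NULL) {
  structure(list(left = left, right = right,
                 sample_rate = as.integer(sample_rate),
                 seed = if (!is.null(config)) config$seed),
            class = "sonoseg_audio")
}

#' @export
print.sonoseg_audio <- function(x, ...) {
  cat(sprintf("<sonoseg_audio> %.2f s stereo @ %d Hz, peak %.3f\n",
              length(x$left) / x$sample_rate, x$sample_rate,
              max(abs(c(x$left, x$right, 0)))))
  invisible(x)
}

# ---- WAV I/O ---------------------------------------------------------------

#' Write a stereo 16-bit PCM WAV file
#'
#' @param audio a [sonoseg_audio][create_advanced_brain_sonification()]
#'   object.
#' @param path output `.wav` file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(length(audio$left) == length(audio$right))
  n <- length(audio$left)
  inter <- numeric(2L * n)
  inter[seq.int(1L, 2L * n, 2L)] <- audio$left
  inter[seq.int(2L, 2L * n, 2L)] <- audio$right
  smp <- as.integer(round(pmin(pmax(inter, -1), 1) * 32767))
  data_size <- 2L * length(smp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(as.integer(16L), con, size = 4, endian = "little")    # fmt size
  writeBin(as.integer(1L), con, size = 2, endian = "little")     # PCM
  writeBin(as.integer(2L), con, size = 2, endian = "little")     # stereo
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * 4L), con, size = 4,
           endian = "little")                                    # byte rate
  writeBin(as.integer(4L), con, size = 2, endian = "little")     # block align
  writeBin(as.integer(16L), con, size = 2, endian = "little")    # bit depth
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(smp, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' A minimal chunk-walking reader used for round-trip verification.
#'
#' @param path `.wav` file.
#' @return a `sonoseg_audio` object (samples in `[-1, 1]`, scaled by
#'   1/32767).
#' @export
read_wav <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  le <- function(i, n) sum(as.integer(raw[i:(i + n - 1)]) * 256^(0:(n - 1)))
  stopifnot(rawToChar(raw[1:4]) == "RIFF", rawToChar(raw[9:12]) == "WAVE")
  pos <- 13
  sr <- NULL; channels <- NULL; bits <- NULL; data <- NULL
  while (pos + 8 <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3)])
    sz <- le(pos + 4, 4)
    body <- pos + 8
    if (id == "fmt ") {
      channels <- le(body + 2, 2)
      sr <- le(body + 4, 4)
      bits <- le(body + 14, 2)
    } else if (id == "data") {
      data <- readBin(raw[body:(body + sz - 1)], "integer", n = sz / 2,
                      size = 2, endian = "little", signed = TRUE)
    }
    pos <- body + sz + sz %% 2
  }
  stopifnot(!is.null(data), bits == 16, channels == 2)
  x <- data / 32767
  new_audio(x[seq.int(1L, length(x), 2L)], x[seq.int(2L, length(x), 2L)], sr)
}

# ---- spectrogram -----------------------------------------------------------

#' Short-time Fourier magnitude spectrogram
#'
#' Computed on the mean of the two channels with a Hann window; used for
#' documentation and quality-control rendering of sonifications.
#'
#' @param audio a `sonoseg_audio` object.
#' @param window window length in samples (power of two recommended).
#' @param hop hop size in samples.
#' @return an object of class `sonoseg_spectrogram`: list with `magnitude`
#'   (`window/2 + 1` frequency rows x frames), `freq_hz`, `time_s`,
#'   `window`, `hop`, `sample_rate`.
#' @export
compute_spectrogram <- function(audio, window = 1024L, hop = 512L) {
  x <- (audio$left + audio$right) / 2
  n <- length(x)
  if (n < window) x <- c(x, numeric(window - n))
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / window)
  starts <- seq.int(1L, n - window + 1L, by = hop)
  nb <- window %/% 2L + 1L
  mag <- matrix(0, nb, length(starts))
  for (f in seq_along(starts)) {
    seg <- x[starts[f]:(starts[f] + window - 1L)] * win
    sp <- stats::fft(seg)
    mag[, f] <- Mod(sp[seq_len(nb)])
  }
  structure(list(magnitude = mag,
                 freq_hz = (seq_len(nb) - 1L) * audio$sample_rate / window,
                 time_s = (starts - 1L + window / 2) / audio$sample_rate,
                 window = window, hop = hop,
                 sample_rate = audio$sample_rate),
            class = "sonoseg_spectrogram")
}
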