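#' Sonification configuration
#'
#' Parameters shared by the audio and MIDI back-ends, including the feature
#' thresholds of the region-to-scale mapping.
#'
#' @param sample_rate audio sample rate in Hz.
#' @param duration_per_region seconds of audio allotted to each region.
#' @param base_pitch root MIDI note of all scale mappings (60 = C4).
#' @param tempo beats per minute.
#' @param harmonic_count additive-synthesis partials (amplitudes 1/n).
#' @param intensity_high,intensity_low unit-interval mean-intensity cuts for
#'   major/minor scale selection.
#' @param area_large_frac region area (fraction of image pixels) above which
#'   a region counts as large (pentatonic).
#' @param area_small_frac area fraction below which a region counts as
#'   small.
#' @param complexity_high shape-complexity cut for the blues branch.
#' @param small_complex_conjunction if `TRUE` (default) the blues branch
#'   requires small AND complex; `FALSE` switches to OR.
#' @param seed integer seed recorded with every render (synthesis itself is
#'   deterministic).
#' @return an object of class `sonoseg_sonification_config`.
#' @export
sonification_config <- function(sample_rate = 44100L,
                                duration_per_region = 1.5,
                                base_pitch = 60L,
                                tempo = 90,
                                harmonic_count = 4L,
                                intensity_high = 0.66,
                                intensity_low = 0.33,
                                area_large_frac = 0.02,
                                area_small_frac = 0.005,
                                complexity_high = 1.8,
                                small_complex_conjunction = TRUE,
                                seed = 1L) {
  stopifnot(sample_rate > 0, intensity_low < intensity_high,
            harmonic_count >= 1)
  structure(list(sample_rate = as.integer(sample_rate),
                 duration_per_region = duration_per_region,
                 base_pitch = as.integer(base_pitch), tempo = tempo,
                 harmonic_count = as.integer(harmonic_count),
                 intensity_high = intensity_high,
                 intensity_low = intensity_low,
                 area_large_frac = area_large_frac,
                 area_small_frac = area_small_frac,
                 complexity_high = complexity_high,
                 small_complex_conjunction = small_complex_conjunction,
                 seed = as.integer(seed)),
            class = "sonoseg_sonification_config")
}

#' Musical scale tables
#'
#' Semitone offsets (within one octave, strictly increasing) of the four
#' scales used by the region mapping.
#'
#' @param scale_name one of `"major"`, `"minor"`, `"pentatonic"`, `"blues"`.
#' @param root_pitch root MIDI note.
#' @return an object of class `sonoseg_scale`: list with `scale_name`,
#'   `root_pitch`, `pitch_classes`.
#' @export
scale_mapping <- function(scale_name = c("major", "minor", "pentatonic",
                                         "blues"),
                          root_pitch = 60L) {
  scale_name <- match.arg(scale_name)
  pcs <- switch(scale_name,
                major = c(0L, 2L, 4L, 5L, 7L, 9L, 11L),
                minor = c(0L, 2L, 3L, 5L, 7L, 8L, 10L),
                pentatonic = c(0L, 2L, 4L, 7L, 9L),
                blues = c(0L, 3L, 5L, 6L, 7L, 10L))
  structure(list(scale_name = scale_name, root_pitch = as.integer(root_pitch),
                 pitch_classes = pcs),
            class = "sonoseg_scale")
}

#' Map a region to a musical scale
#'
#' The decision ladder encodes the perceptual mapping: small-and-complex
#' regions select the blues scale, large areas the pentatonic scale,
#' high mean intensity the major and low mean intensity the minor scale
#' (mid-intensity regions default to major).  Morphology takes precedence
#' over size, and size over intensity, because shape anomalies are the
#' rarest and most diagnostic cue.
#'
#' @param region a one-row region record (list or tibble row) with `area`,
#'   `mean_intensity`, `complexity`.
#' @param config a [sonification_config()].
#' @param image_pixels total pixel count of the source image (converts the
#'   area fractions in `config` to pixels).
#' @return a [scale_mapping()] object.
#' @export
region_to_musical_scale <- function(region, config = sonification_config(),
                                    image_pixels) {
  a <- region$area / image_pixels
  small <- a < config$area_small_frac
  complexx <- region$complexity >= config$complexity_high
  blues <- if (config$small_complex_conjunction) small && complexx
  else small || complexx
  name <- if (blues) "blues"
  else if (a >= config$area_large_frac) "pentatonic"
  else if (region$mean_intensity >= config$intensity_high) "major"
  else if (region$mean_intensity <= config$intensity_low) "minor"
  else "major"
  scale_mapping(name, config$base_pitch)
}

#' Dissonance intervals for an anomaly severity
#'
#' High-severity anomalies map to a tritone dyad (root plus 6 semitones),
#' moderate ones to a minor seventh (root plus 10), and `none` to the bare
#' root.
#'
#' @param severity `"none"`, `"moderate"`, or `"high"`.
#' @param base_pitch root MIDI note.
#' @return integer vector of MIDI pitches.
#' @export
anomaly_to_dissonance <- function(severity, base_pitch = 60L) {
  iv <- switch(severity,
               high = c(0L, 6L),
               moderate = c(0L, 10L),
               none = 0L,
               abort_sonoseg(sprintf("unknown severity '%s'", severity),
                             class = "sonoseg_sensory_error"))
  as.integer(base_pitch) + iv
}

# deterministic melodic contour: an intensity-anchored expanding walk over
# scale degrees (start degree from mean intensity, then +1, -1, +2, -2, ...)
phrase_pitches <- function(region, scale) {
  pcs <- scale$pitch_classes
  len <- length(pcs)
  n_notes <- min(8L, max(3L, round(sqrt(region$area) / 2)))
  start <- 1L + floor(min(max(region$mean_intensity, 0), 0.999) * len)
  steps <- c(0L, as.vector(rbind(seq_len(n_notes), -seq_len(n_notes))))
  idx <- start + steps[seq_len(n_notes)]
  deg <- ((idx - 1L) %% len) + 1L
  oct <- (idx - 1L) %/% len
  scale$root_pitch + pcs[deg] + 12L * oct
}

# region area -> note duration in beats, quantized to {1/4, 1/2, 1, 2}
area_to_duration_beats <- function(area_frac, config) {
  cuts <- config$area_large_frac * c(0.25, 0.5, 1)
  if (area_frac < cuts[1]) 0.25
  else if (area_frac < cuts[2]) 0.5
  else if (area_frac < cuts[3]) 1
  else 2
}

intensity_to_velocity <- function(mean_intensity) {
  as.integer(round(40 + min(max(mean_intensity, 0), 1) * 87))
}

#' Generate a MIDI sequence from an anomaly report
#'
#' One phrase per region, in descending-area order: melodic pitches are an
#' intensity-anchored walk over the region's scale (see
#' [region_to_musical_scale()]), note durations are the region's
#' area-quantized beat value, velocity is an affine map of mean intensity
#' into `[40, 127]`, and a severity dyad ([anomaly_to_dissonance()]) is
#' appended as a simultaneous chord at the end of the phrase.
#'
#' @param report a [anomaly_report()] result.
#' @param config a [sonification_config()].
#' @return an object of class `sonoseg_midi`: list with `events` (tibble:
#'   `onset_beats`, `duration_beats`, `pitch`, `velocity`, `channel`),
#'   `tempo`, `program`, `ticks_per_beat`.
#' @export
create_advanced_midi_from_brain <- function(report,
                                            config = sonification_config()) {
  stopifnot(inherits(report, "sonoseg_anomaly_report"))
  npx <- prod(report$image_size)
  regions <- report$regions
  evs <- list()
  onset <- 0
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    sc <- region_to_musical_scale(reg, config, npx)
    pitches <- phrase_pitches(reg, sc)
    dur <- area_to_duration_beats(reg$area / npx, config)
    vel <- intensity_to_velocity(reg$mean_intensity)
    for (p in pitches) {
      evs[[length(evs) + 1L]] <- tibble::tibble(
        onset_beats = onset, duration_beats = dur,
        pitch = clamp_pitch(p), velocity = vel, channel = 0L,
        region = reg$region_id, role = "melody")
      onset <- onset + dur
    }
    dyad <- anomaly_to_dissonance(reg$severity %||% "none", sc$root_pitch)
    for (p in dyad) {
      evs[[length(evs) + 1L]] <- tibble::tibble(
        onset_beats = onset, duration_beats = 1,
        pitch = clamp_pitch(p), velocity = 100L, channel = 0L,
        region = reg$region_id, role = "dissonance")
    }
    onset <- onset + 1.5      # phrase separation
  }
  events <- if (length(evs)) dplyr::bind_rows(evs)
  else tibble::tibble(onset_beats = numeric(), duration_beats = numeric(),
                      pitch = integer(), velocity = integer(),
                      channel = integer(), region = integer(),
                      role = character())
  structure(list(events = events, tempo = config$tempo, program = 0L,
                 ticks_per_beat = 480L, seed = config$seed),
            class = "sonoseg_midi")
}

clamp_pitch <- function(p) as.integer(min(max(p, 0L), 127L))

#' @export
print.sonoseg_midi <- function(x, ...) {
  cat(sprintf("<sonoseg_midi> %d note event(s), tempo %g BPM\n",
              nrow(x$events), x$tempo))
  invisible(x)
}

# ---- Standard MIDI File writer --------------------------------------------

varint <- function(x) {
  x <- as.integer(x)
  out <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    out <- c(as.raw(bitwOr(x %% 128L, 0x80L)), out)
    x <- x %/% 128L
  }
  out
}

int_bytes <- function(x, n) {
  as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
}

#' Write a Standard MIDI File (format 0)
#'
#' @param midi a [sonoseg_midi][create_advanced_midi_from_brain()] object.
#' @param path output `.mid` file.
#' @return `path`, invisibly.
#' @export
write_midi <- function(midi, path) {
  tpb <- midi$ticks_per_beat
  ev <- midi$events
  # tempo meta + program change at tick 0
  track <- c(varint(0), as.raw(c(0xFF, 0x51, 0x03)),
             int_bytes(round(6e7 / midi$tempo), 3L),
             varint(0), as.raw(c(0xC0, midi$program)))
  if (nrow(ev)) {
    on_t <- round(ev$onset_beats * tpb)
    off_t <- round((ev$onset_beats + ev$duration_beats) * tpb)
    msgs <- rbind(
      data.frame(tick = on_t, prio = 1L,
                 status = bitwOr(0x90L, ev$channel), d1 = ev$pitch,
                 d2 = ev$velocity),
      data.frame(tick = off_t, prio = 0L,
                 status = bitwOr(0x80L, ev$channel), d1 = ev$pitch,
                 d2 = 64L))
    msgs <- msgs[order(msgs$tick, msgs$prio), ]
    last <- 0
    for (i in seq_len(nrow(msgs))) {
      track <- c(track, varint(msgs$tick[i] - last),
                 as.raw(c(msgs$status[i], msgs$d1[i], msgs$d2[i])))
      last <- msgs$tick[i]
    }
  }
  track <- c(track, varint(0), as.raw(c(0xFF, 0x2F, 0x00)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(c(int_bytes(6L, 4L), int_bytes(0L, 2L), int_bytes(1L, 2L),
             int_bytes(tpb, 2L)), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(int_bytes(length(track), 4L), con)
  writeBin(track, con)
  invisible(path)
}

#' Parse a Standard MIDI File
#'
#' A self-contained reader (independent of [write_midi()]'s encoder) that
#' returns paired note events; supports running status and formats 0/1.
#'
#' @param path `.mid` file.
#' @return list with `events` (tibble: `onset_beats`, `duration_beats`,
#'   `pitch`, `velocity`, `channel`), `tempo`, `ticks_per_beat`,
#'   `n_note_on`.
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u <- function(i) as.integer(raw[i])
  be <- function(i, n) sum(as.integer(raw[i:(i + n - 1)]) * 256^((n - 1):0))
  stopifnot(rawToChar(raw[1:4]) == "MThd")
  ntrk <- be(11, 2)
  tpb <- be(13, 2)
  pos <- 15
  tempo <- 120
  notes <- list()
  for (tr in seq_len(ntrk)) {
    stopifnot(rawToChar(raw[pos:(pos + 3)]) == "MTrk")
    len <- be(pos + 4, 4)
    p <- pos + 8
    end <- p + len
    tick <- 0
    status <- 0L
    open <- list()
    while (p < end) {
      # variable-length delta time
      dt <- 0
      repeat {
        b <- u(p); p <- p + 1
        dt <- dt * 128 + bitwAnd(b, 0x7FL)
        if (b < 128L) break
      }
      tick <- tick + dt
      b <- u(p)
      if (b >= 128L) { status <- b; p <- p + 1 }
      hi <- bitwAnd(status, 0xF0L)
      if (status == 0xFFL) {
        type <- u(p); mlen <- u(p + 1); p <- p + 2
        if (type == 0x51L) tempo <- 6e7 / be(p, 3)
        p <- p + mlen
      } else if (hi %in% c(0x80L, 0x90L)) {
        pitch <- u(p); vel <- u(p + 1); p <- p + 2
        ch <- bitwAnd(status, 0x0FL)
        key <- paste(ch, pitch)
        if (hi == 0x90L && vel > 0L) {
          open[[key]] <- c(open[[key]], list(c(tick, vel)))
        } else if (length(open[[key]])) {
          st <- open[[key]][[1]]
          open[[key]] <- open[[key]][-1]
          notes[[length(notes) + 1L]] <- c(st[1], tick, pitch, st[2], ch)
        }
      } else if (hi %in% c(0xC0L, 0xD0L)) {
        p <- p + 1
      } else {
        p <- p + 2
      }
    }
    pos <- end
  }
  ev <- if (length(notes)) {
    m <- do.call(rbind, notes)
    tibble::tibble(onset_beats = m[, 1] / tpb,
                   duration_beats = (m[, 2] - m[, 1]) / tpb,
                   pitch = as.integer(m[, 3]), velocity = as.integer(m[, 4]),
                   channel = as.integer(m[, 5]))
  } else {
    tibble::tibble(onset_beats = numeric(), duration_beats = numeric(),
                   pitch = integer(), velocity = integer(),
                   channel = integer())
  }
  ev <- ev[order(ev$onset_beats, ev$pitch), ]
  list(events = ev, tempo = tempo, ticks_per_beat = tpb,
       n_note_on = nrow(ev))
}
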