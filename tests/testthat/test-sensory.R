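test_that("colormap rendering hits both endpoints exactly and interpolates", {
  g <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  cm <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)   # black -> white
  out <- render_colormap(g, cm)
  expect_equal(out[1, 1, ], c(0L, 0L, 0L))          # minimum -> first color
  expect_equal(out[2, 2, ], c(255L, 255L, 255L))    # maximum -> last color
  expect_true(all(abs(out[1, 2, ] - 128) <= 1))     # midpoint gray
  # constant grid maps to the first color
  cg <- render_colormap(matrix(3, 2, 2), cm)
  expect_true(all(cg == 0L))
  expect_error(render_colormap(g, matrix(0, 1, 3)),
               class = "sonoseg_color_error")
})

test_that("overlays leave zero-probability pixels untouched and blend linearly", {
  img <- matrix(runif(64), 8, 8)
  cm <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)   # black -> red
  base <- render_overlay(img, matrix(0, 8, 8), cm, alpha = 1)
  for (c in 1:3) expect_equal(base[, , c], round(img * 255) * 1L)

  full <- render_overlay(img, matrix(1, 8, 8), cm, alpha = 1)
  expect_true(all(full[, , 1] == 255L))
  expect_true(all(full[, , 2] == 0L))

  half <- render_overlay(img, matrix(1, 8, 8), cm, alpha = 0.5)
  expect_true(all(abs(half[, , 1] - round((img * 255 + 255) / 2)) <= 1))
})

test_that("the region-to-scale ladder follows the documented precedence", {
  cfg <- sonification_config()
  npx <- 128 * 128
  mk <- function(area, intensity, complexity) {
    list(area = area, mean_intensity = intensity, complexity = complexity)
  }
  expect_equal(region_to_musical_scale(mk(300, 0.9, 1.1), cfg, npx)$scale_name,
               "major")
  expect_equal(region_to_musical_scale(mk(300, 0.2, 1.1), cfg, npx)$scale_name,
               "minor")
  expect_equal(region_to_musical_scale(mk(300, 0.5, 1.1), cfg, npx)$scale_name,
               "major")          # mid intensity defaults to major
  # large area wins over intensity
  expect_equal(region_to_musical_scale(mk(0.03 * npx, 0.2, 1.1), cfg,
                                       npx)$scale_name, "pentatonic")
  # small AND complex wins over everything
  expect_equal(region_to_musical_scale(mk(40, 0.9, 2.5), cfg, npx)$scale_name,
               "blues")
  # small but simple falls through to the intensity rule
  expect_equal(region_to_musical_scale(mk(40, 0.9, 1.0), cfg, npx)$scale_name,
               "major")
  # disjunction flag widens the blues branch
  cfg2 <- sonification_config(small_complex_conjunction = FALSE)
  expect_equal(region_to_musical_scale(mk(300, 0.9, 2.5), cfg2, npx)$scale_name,
               "blues")
})

test_that("scale tables hold the canonical semitone offsets", {
  expect_equal(scale_mapping("major")$pitch_classes, c(0, 2, 4, 5, 7, 9, 11))
  expect_equal(scale_mapping("minor")$pitch_classes, c(0, 2, 3, 5, 7, 8, 10))
  expect_equal(scale_mapping("pentatonic")$pitch_classes, c(0, 2, 4, 7, 9))
  expect_equal(scale_mapping("blues")$pitch_classes, c(0, 3, 5, 6, 7, 10))
})

test_that("dissonance intervals encode severity as tritone / minor seventh", {
  expect_equal(anomaly_to_dissonance("high", 60), c(60L, 66L))
  expect_equal(anomaly_to_dissonance("moderate", 60), c(60L, 70L))
  expect_equal(anomaly_to_dissonance("none", 60), 60L)
  expect_error(anomaly_to_dissonance("weird", 60),
               class = "sonoseg_sensory_error")
})

test_that("melodic pitches stay inside the region's scale across random reports", {
  cfg <- sonification_config()
  for (seed in 1:50) {
    rep_ <- tiny_report(image_size = 48, tumor_radius = 4 + seed %% 8,
                        jitter = (seed %% 4) / 10, seed = seed, min_size = 1)
    if (nrow(rep_$regions) == 0) next
    mid <- create_advanced_midi_from_brain(rep_, cfg)
    npx <- prod(rep_$image_size)
    for (r in seq_len(nrow(rep_$regions))) {
      reg <- rep_$regions[r, ]
      sc <- region_to_musical_scale(reg, cfg, npx)
      ev <- mid$events[mid$events$role == "melody" &
                         mid$events$region == reg$region_id, ]
      pcs <- (ev$pitch - sc$root_pitch) %% 12
      expect_true(all(pcs %in% sc$pitch_classes))
    }
  }
})

test_that("note velocity increases with region mean intensity", {
  vel <- function(x) sonoseg:::intensity_to_velocity(x)
  xs <- seq(0, 1, by = 0.05)
  vs <- vapply(xs, vel, integer(1))
  expect_true(all(diff(vs) >= 0))
  expect_true(vel(0.9) > vel(0.5))
  expect_gte(min(vs), 40)
  expect_lte(max(vs), 127)
})

test_that("MIDI files round-trip through the independent parser", {
  rep_ <- tiny_report(seed = 6)
  mid <- create_advanced_midi_from_brain(rep_)
  path <- withr::local_tempfile(fileext = ".mid")
  write_midi(mid, path)
  back <- read_midi(path)
  expect_equal(back$n_note_on, nrow(mid$events))
  expect_equal(back$ticks_per_beat, 480)
  expect_equal(back$tempo, mid$tempo, tolerance = 1e-3)
  expect_setequal(back$events$pitch, mid$events$pitch)
  # onsets non-decreasing, pitches in range
  expect_true(all(diff(sort(mid$events$onset_beats)) >= 0))
  expect_true(all(mid$events$pitch >= 0 & mid$events$pitch <= 127))

  # empty report -> valid file with zero notes
  empty <- anomaly_report(matrix(runif(256), 16, 16), matrix(0, 16, 16))
  m0 <- create_advanced_midi_from_brain(empty)
  p0 <- withr::local_tempfile(fileext = ".mid")
  write_midi(m0, p0)
  expect_equal(read_midi(p0)$n_note_on, 0)
})

test_that("high severity emits a simultaneous tritone dyad, moderate a minor seventh", {
  rep_ <- tiny_report(seed = 6)          # hyperintense -> high severity
  expect_equal(rep_$regions$severity[1], "high")
  mid <- create_advanced_midi_from_brain(rep_)
  ev <- mid$events
  simult <- function(events, interval) {
    any(vapply(split(events$pitch, events$onset_beats), function(p) {
      length(p) > 1 && any(diff(sort(p)) == interval)
    }, logical(1)))
  }
  expect_true(simult(ev, 6))

  # force a moderate-only report through the thresholds
  repm <- tiny_report(seed = 6)
  repm$regions$severity <- "moderate"
  midm <- create_advanced_midi_from_brain(repm)
  expect_true(simult(midm$events, 10))
  expect_false(simult(midm$events, 6))
})

test_that("sonification renders silence for empty reports at the configured length", {
  img <- matrix(runif(256), 16, 16)
  rep_ <- anomaly_report(img, matrix(0, 16, 16))
  cfg <- sonification_config(duration_per_region = 0.8)
  au <- create_advanced_brain_sonification(img, matrix(0, 16, 16), rep_, cfg)
  expect_equal(length(au$left), round(0.8 * cfg$sample_rate))
  expect_true(all(au$left == 0) && all(au$right == 0))
})

test_that("stereo panning follows the centroid and swaps under mirroring", {
  ph <- generate_phantom(phantom_params(image_size = 64,
                                        tumor_center = c(32, 8),
                                        tumor_radius = 6, seed = 2))
  rep_ <- anomaly_report(ph$image, ph$mask)
  cfg <- sonification_config(duration_per_region = 0.3)
  au <- create_advanced_brain_sonification(ph$image, ph$mask, rep_, cfg)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(au$left), rms(au$right))   # left-quarter centroid

  mimg <- ph$image[, 64:1]
  mmask <- ph$mask[, 64:1]
  repm <- anomaly_report(mimg, mmask)
  aum <- create_advanced_brain_sonification(mimg, mmask, repm, cfg)
  expect_equal(rms(aum$left), rms(au$right), tolerance = 1e-6)
  expect_equal(rms(aum$right), rms(au$left), tolerance = 1e-6)
})

test_that("audio respects the no-clipping contract and renders deterministically", {
  rep_ <- tiny_report(seed = 13, image_size = 48)
  ph <- generate_phantom(phantom_params(image_size = 48, tumor_radius = 8,
                                        seed = 13))
  cfg <- sonification_config(duration_per_region = 0.3)
  a1 <- create_advanced_brain_sonification(ph$image, ph$mask, rep_, cfg)
  a2 <- create_advanced_brain_sonification(ph$image, ph$mask, rep_, cfg)
  expect_identical(a1, a2)
  expect_lte(max(abs(c(a1$left, a1$right))), 1)
  expect_equal(length(a1$left), length(a1$right))

  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a1, p1)
  write_wav(a2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # 16-bit PCM round trip: samples survive up to quantization exactly
  back <- read_wav(p1)
  expect_equal(back$sample_rate, a1$sample_rate)
  q <- round(pmin(pmax(a1$left, -1), 1) * 32767) / 32767
  expect_equal(back$left, q, tolerance = 1e-12)
})

test_that("spectrograms localize a pure tone and satisfy Parseval", {
  sr <- 8000
  t <- seq_len(sr) / sr
  tone <- sin(2 * pi * 440 * t)
  au <- sonoseg:::new_audio(tone, tone, sr)
  sp <- compute_spectrogram(au, window = 1024, hop = 512)
  peak_bin <- which.max(rowSums(sp$magnitude))
  expect_lt(abs(sp$freq_hz[peak_bin] - 440), sr / 1024 + 1e-9)

  silent <- sonoseg:::new_audio(numeric(4096), numeric(4096), sr)
  expect_true(all(compute_spectrogram(silent)$magnitude == 0))

  # Parseval: full-spectrum energy equals window-length times frame energy
  N <- 1024
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(N) / N)
  frame <- tone[1:N] * win
  spec_energy <- (2 * sum(sp$magnitude[2:(N / 2), 1]^2) +
                    sp$magnitude[1, 1]^2 + sp$magnitude[N / 2 + 1, 1]^2) / N
  expect_equal(spec_energy, sum(frame^2), tolerance = 0.01 * sum(frame^2))
})
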