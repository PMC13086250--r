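test_that("C major progression carries the ii-V-I-vi sevenths (Dm7 G7 Cmaj7 Am7)", {
  s <- compose_chord_progression("C", 1)
  ch <- s$events[s$events$track == "chords", ]
  onsets <- sort(unique(ch$onset))
  first4 <- lapply(onsets[1:4], function(o) sort(ch$pitch[ch$onset == o]))
  expect_equal(first4[[1]], c(50, 53, 57, 60))  # D m7
  expect_equal(first4[[2]], c(55, 59, 62, 65))  # G dom7
  expect_equal(first4[[3]], c(48, 52, 55, 59))  # C maj7
  expect_equal(first4[[4]], c(57, 60, 64, 67))  # A m7
  b <- s$events[s$events$track == "bass", ]
  expect_equal(unique(b$pitch[b$onset < 0.857]), 36 + 2)  # D bass under ii
})

test_that("all 12 keys follow the cyclic root order and resolve on the tonic maj7", {
  for (key in major_keys()) {
    s <- compose_chord_progression(key, 2)
    ch <- s$events[s$events$track == "chords", ]
    onsets <- sort(unique(ch$onset))
    pc_tonic <- match(key, major_keys()) - 1
    expected_roots <- (pc_tonic + c(2, 7, 0, 9)) %% 12
    roots <- vapply(onsets, function(o) min(ch$pitch[ch$onset == o]) %% 12,
                    numeric(1))
    expect_equal(roots, expected_roots[(seq_along(onsets) - 1) %% 4 + 1])
    ## final sounded chord is maj7 on the tonic, sustained to the end
    last <- ch[ch$onset == max(onsets), ]
    expect_equal(sort(last$pitch - min(last$pitch)), c(0, 4, 7, 11))
    expect_equal(min(last$pitch) %% 12, pc_tonic)
    expect_equal(max(last$onset + last$duration), s$length_s)
  }
})

test_that("drum grid matches brute-force enumeration of fitting note values", {
  s <- compose_chord_progression("C", 1)
  beat <- 60 / 140
  ## oracle: enumerate grid onsets whose full note value fits in 15 s
  rides <- sum(sapply(0:100, function(k) k * beat + beat <= 15 + 1e-9))
  kicks <- sum(sapply(0:100, function(k) k * 2 * beat + 2 * beat <= 15 + 1e-9))
  d <- s$events[s$events$track == "drums", ]
  expect_equal(sum(d$pitch == 51), rides)   # 35 ride hits
  expect_equal(sum(d$pitch == 36), kicks)   # 17 kick hits
  expect_equal(rides, 35)
  expect_equal(kicks, 17)
})

test_that("degenerate and invalid inputs are handled", {
  s0 <- compose_chord_progression("C", 1, length_s = 0)
  expect_s3_class(s0, "stimulus_score")
  expect_equal(nrow(s0$events), 0)
  expect_error(compose_chord_progression("H", 1), "key")
  expect_error(compose_chord_progression("C", 5), "melody_id")
})

test_that("shuffling jitters tonal onsets but leaves drums bit-identical", {
  s <- compose_chord_progression("E", 3)
  n <- shuffle_tonal_tracks(s, rng_seed = 42)
  expect_equal(n$condition, "no_chord_progression")
  drum_in <- s$events[s$events$track == "drums", ]
  drum_out <- n$events[n$events$track == "drums", ]
  expect_equal(drum_out[order(drum_out$onset, drum_out$pitch), ],
               drum_in[order(drum_in$onset, drum_in$pitch), ],
               ignore_attr = TRUE)
  for (tr in c("melody", "chords", "bass")) {
    a <- s$events[s$events$track == tr, ]
    b <- n$events[n$events$track == tr, ]
    ## multiset of (pitch, duration) preserved; onsets moved and in range
    expect_equal(sort(paste(b$pitch, round(b$duration, 9))),
                 sort(paste(a$pitch, round(a$duration, 9))))
    expect_true(all(b$onset >= 0 & b$onset < s$length_s))
    expect_false(isTRUE(all.equal(sort(a$onset), sort(b$onset))))
  }
  ## offsets have magnitude >= 0.25 s (mod wrap-around)
  expect_identical(shuffle_tonal_tracks(s, 42), n)  # deterministic
  expect_error(shuffle_tonal_tracks(s, 1, offset_range_s = c(2, 1)), "range")
  expect_error(shuffle_tonal_tracks(n, 1), "chord_progression")
})

test_that("shuffling a drums-only score changes only the condition label", {
  s <- compose_chord_progression("C", 1)
  s$events <- s$events[s$events$track == "drums", ]
  n <- shuffle_tonal_tracks(s, 7)
  expect_equal(n$events, s$events, ignore_attr = TRUE)
  expect_equal(n$condition, "no_chord_progression")
})

test_that("the stimulus set has 12 CP + 12 NCP exemplars, one per key", {
  sets <- build_stimulus_sets(3)
  expect_length(sets$cp, 12)
  expect_length(sets$ncp, 12)
  expect_setequal(vapply(sets$cp, `[[`, "", "key"), major_keys())
  expect_identical(build_stimulus_sets(3), sets)
  ## CP/NCP pair shares the drum track event-for-event
  for (k in c("C", "Gb", "B")) {
    da <- sets$cp[[k]]$events
    db <- sets$ncp[[k]]$events
    expect_equal(da[da$track == "drums", ], db[db$track == "drums", ],
                 ignore_attr = TRUE)
  }
})

test_that("rendering is deterministic, in range, and respects score length", {
  s <- compose_chord_progression("C", 1)
  a <- render_audio(s, rng_seed = 5)
  b <- render_audio(s, rng_seed = 5)
  expect_identical(a$samples, b$samples)
  expect_lt(max(abs(a$samples)), 1)
  expect_gte(length(a$samples) / a$sample_rate, 15)
  expect_error(render_audio(s, sample_rate = 4000), "8000")
  expect_error(render_audio(s, patch = list()), "patch")
})

test_that("a silent score renders to silence and a single note peaks at its pitch", {
  s <- compose_chord_progression("C", 1, length_s = 0)
  clip <- render_audio(s)
  expect_true(all(clip$samples == 0))
  ## single A4 (69) quarter note on the melody track
  s1 <- compose_chord_progression("C", 1, length_s = 0)
  s1$events <- data.frame(onset = 0, duration = 0.5, pitch = 69L,
                          velocity = 0.8, track = "melody")
  s1$length_s <- 0.5
  clip1 <- render_audio(s1, sample_rate = 22050)
  spec <- Mod(stats::fft(clip1$samples * signal::hanning(length(clip1$samples))))
  half <- seq_len(length(spec) %/% 2)
  fpeak <- (which.max(spec[half]) - 1) * 22050 / length(spec)
  expect_lt(abs(fpeak - 440), 5)
})

test_that("CP and NCP renderings share the note-energy budget", {
  sets <- build_stimulus_sets(2)
  ## note-energy budget: the summed energy of individually rendered notes is
  ## preserved by shuffling (catches truncation/dropping of displaced notes)
  note_budget <- function(score) {
    sum(vapply(seq_len(nrow(score$events)), function(i) {
      s1 <- score
      s1$events <- score$events[i, , drop = FALSE]
      sum(render_audio(s1, normalize = FALSE)$samples^2)
    }, numeric(1)))
  }
  expect_equal(note_budget(sets$ncp$C), note_budget(sets$cp$C),
               tolerance = 0.01)
  ## the joint mixes differ only through interference between displaced notes
  for (k in c("C", "A")) {
    ea <- sum(render_audio(sets$cp[[k]], normalize = FALSE)$samples^2)
    eb <- sum(render_audio(sets$ncp[[k]], normalize = FALSE)$samples^2)
    expect_lt(abs(ea - eb) / ea, 0.05)
  }
})

test_that("WAV round trip preserves samples to 16-bit precision", {
  clip <- render_audio(compose_chord_progression("D", 2, length_s = 2))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate, clip$sample_rate)
  expect_equal(back$samples, clip$samples, tolerance = 1e-4)
})

test_that("MIDI and JSON exports are structurally sound", {
  s <- compose_chord_progression("F", 4)
  fm <- withr::local_tempfile(fileext = ".mid")
  write_midi(s, fm)
  bytes <- readBin(fm, "raw", file.size(fm))
  expect_identical(rawToChar(bytes[1:4]), "MThd")
  ## format 1, 5 tracks (tempo + 4 instruments)
  expect_equal(as.integer(bytes[10]), 1)
  expect_equal(as.integer(bytes[12]), 5)
  fj <- withr::local_tempfile(fileext = ".json")
  write_score_json(s, fj)
  back <- read_score_json(fj)
  expect_equal(back$events, s$events, ignore_attr = TRUE)
  expect_equal(back$key, s$key)
})
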