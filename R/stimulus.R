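## Stimulus generation: procedural ii-V-I-vi chord-progression exemplars and
## their note-shuffled (no-chord-progression) controls.

#' The twelve major keys used for the stimulus set
#' @export
major_keys <- function() {
  c("C", "Db", "D", "Eb", "E", "F", "Gb", "G", "Ab", "A", "Bb", "B")
}

## pitch class (0-11) of a key's tonic
key_pitch_class <- function(key) {
  pc <- match(key, major_keys()) - 1L
  if (is.na(pc)) stop("unknown key '", key, "'; expected one of ",
                      paste(major_keys(), collapse = ", "))
  pc
}

## ii-V-I-vi over a major key: root offsets (semitones above tonic) and
## seventh-chord qualities.
progression_degrees <- function() {
  list(root = c(ii = 2L, V = 7L, I = 0L, vi = 9L),
       quality = c(ii = "m7", V = "dom7", I = "maj7", vi = "m7"))
}

chord_intervals <- function(quality) {
  switch(quality,
         m7   = c(0L, 3L, 7L, 10L),
         dom7 = c(0L, 4L, 7L, 10L),
         maj7 = c(0L, 4L, 7L, 11L),
         stop("unknown chord quality '", quality, "'"))
}

## Four fixed half-note melody contours over the major-pentatonic degrees
## {1,2,3,5,6}; recycled over the half-note grid and transposed per key.
melody_templates <- function() {
  list(c(1L, 2L, 3L, 5L, 3L, 2L, 1L, 6L),
       c(3L, 5L, 6L, 5L, 3L, 2L, 1L, 2L),
       c(5L, 3L, 2L, 1L, 2L, 3L, 5L, 6L),
       c(6L, 5L, 3L, 2L, 3L, 1L, 2L, 3L))
}

pentatonic_offsets <- c(0L, 2L, 4L, 7L, 9L)  # degrees 1,2,3,5,6 in semitones

## Reserved percussion note numbers (general-MIDI convention)
DRUM_RIDE <- 51L
DRUM_KICK <- 36L

new_note_event <- function(onset, duration, pitch, velocity, track) {
  data.frame(onset = onset, duration = duration, pitch = as.integer(pitch),
             velocity = velocity, track = track, stringsAsFactors = FALSE)
}

new_stimulus_score <- function(events, key, tempo_bpm, length_s, condition,
                               melody_id) {
  events <- events[order(events$onset, events$track, events$pitch), ,
                   drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, key = key, tempo_bpm = tempo_bpm,
                 length_s = length_s, condition = condition,
                 melody_id = as.integer(melody_id)),
            class = "stimulus_score")
}

#' @export
print.stimulus_score <- function(x, ...) {
  cat(sprintf("<stimulus_score> key %s major, %s, %g BPM, %g s, melody %d\n",
              x$key, x$condition, x$tempo_bpm, x$length_s, x$melody_id))
  tab <- table(x$events$track)
  if (length(tab)) {
    cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else cat("  events: none\n")
  invisible(x)
}

#' Compose a chord-progression stimulus
#'
#' Builds the four-track score of one consonant-music exemplar: a piano melody
#' in half notes from the key's major pentatonic scale, piano seventh chords in
#' half notes following ii7-V7-Imaj7-vi7 root motion, a bass playing quarter
#' notes on the chord roots, and a drum pattern (ride cymbal on quarter notes,
#' kick on half notes). The progression cycles and resolves on the tonic major
#' seventh in the final cycle, sustained to the end of the stimulus. All events
#' sit on the tempo grid; drum hits are only placed where the full note value
#' fits inside the stimulus.
#'
#' @param key one of the 12 major keys, see [major_keys()]
#' @param melody_id integer 1-4 selecting the fixed pentatonic melody template
#' @param tempo_bpm tempo in beats per minute (default 140)
#' @param length_s stimulus length in seconds (default 15)
#' @return a `stimulus_score` object (events, key, tempo, length, condition)
#' @examples
#' s <- compose_chord_progression("C", 1)
#' s
#' @export
compose_chord_progression <- function(key = "C", melody_id = 1,
                                      tempo_bpm = 140, length_s = 15) {
  pc <- key_pitch_class(key)
  if (!is.numeric(melody_id) || length(melody_id) != 1 ||
      melody_id < 1 || melody_id > 4 || melody_id != round(melody_id)) {
    stop("melody_id must be an integer in 1..4, got ", melody_id)
  }
  stopifnot(tempo_bpm > 0, length_s >= 0)
  beat <- 60 / tempo_bpm
  half <- 2 * beat
  prog <- progression_degrees()
  ev <- list()

  ## --- chord track: half-note seventh chords, cycles of ii-V-I-vi; in the
  ## final (4th by default) cycle the tonic is sustained to the end.
  chords <- data.frame(onset = numeric(0), duration = numeric(0),
                       root_off = integer(0), quality = character(0))
  slot <- 0L
  repeat {
    onset <- slot * half
    if (onset >= length_s - 1e-9) break
    cycle <- slot %/% 4L + 1L
    pos <- slot %% 4L + 1L
    root_off <- prog$root[[pos]]
    quality <- prog$quality[[pos]]
    dur <- min(half, length_s - onset)
    if (cycle >= 4L && pos == 3L) {           # final resolution on Imaj7
      dur <- length_s - onset
      chords <- rbind(chords, data.frame(onset = onset, duration = dur,
                                         root_off = root_off,
                                         quality = quality))
      break
    }
    chords <- rbind(chords, data.frame(onset = onset, duration = dur,
                                       root_off = root_off,
                                       quality = quality))
    slot <- slot + 1L
  }
  if (nrow(chords)) {
    for (i in seq_len(nrow(chords))) {
      root <- 48L + ((pc + chords$root_off[i]) %% 12L)  # close voicing, oct 3
      pitches <- root + chord_intervals(chords$quality[i])
      ev[[length(ev) + 1L]] <- new_note_event(chords$onset[i],
                                              chords$duration[i], pitches,
                                              0.6, "chords")
    }
    ## --- bass track: quarter notes on the sounding chord's root, one octave
    ## below the chord voicing.
    b <- 0L
    repeat {
      onset <- b * beat
      if (onset >= length_s - 1e-9) break
      idx <- max(which(chords$onset <= onset + 1e-9))
      root <- 36L + ((pc + chords$root_off[idx]) %% 12L)
      ev[[length(ev) + 1L]] <- new_note_event(onset,
                                              min(beat, length_s - onset),
                                              root, 0.7, "bass")
      b <- b + 1L
    }
  }

  ## --- melody track: half notes over the pentatonic template, octave 5.
  template <- melody_templates()[[melody_id]]
  m <- 0L
  repeat {
    onset <- m * half
    if (onset >= length_s - 1e-9) break
    deg <- template[(m %% length(template)) + 1L]
    pitch <- 72L + pc + pentatonic_offsets[match(deg, c(1L, 2L, 3L, 5L, 6L))]
    ev[[length(ev) + 1L]] <- new_note_event(onset, min(half, length_s - onset),
                                            pitch, 0.8, "melody")
    m <- m + 1L
  }

  ## --- drums: ride on every beat, kick on every half note; a hit is placed
  ## only if its full note value fits within the stimulus.
  r <- 0L
  repeat {
    onset <- r * beat
    if (onset + beat > length_s + 1e-9) break
    ev[[length(ev) + 1L]] <- new_note_event(onset, beat, DRUM_RIDE, 0.5,
                                            "drums")
    r <- r + 1L
  }
  k <- 0L
  repeat {
    onset <- k * half
    if (onset + half > length_s + 1e-9) break
    ev[[length(ev) + 1L]] <- new_note_event(onset, half, DRUM_KICK, 0.9,
                                            "drums")
    k <- k + 1L
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    new_note_event(numeric(0), numeric(0), integer(0), numeric(0),
                   character(0))
  new_stimulus_score(events, key, tempo_bpm, length_s, "chord_progression",
                     melody_id)
}

#' Shuffle the tonal tracks of a score
#'
#' Derives the no-chord-progression control from a chord-progression exemplar
#' by displacing every melody, chord and bass note in time while leaving the
#' drum track untouched, destroying the harmonic and rhythmic context of the
#' tonal instruments but preserving the drum grid and tempo.
#'
#' @param score a `stimulus_score` with `condition == "chord_progression"`
#' @param rng_seed integer seed; shuffling is deterministic given the seed
#' @param offset_range_s magnitude range (seconds) of the temporal offset,
#'   default `c(0.25, 2)`; each note gets an independent uniform magnitude and
#'   random sign, and onsets wrap around the stimulus length
#' @param method `"jitter"` (per-note offset, default) or `"permute"`
#'   (permute onsets among the notes of each tonal track)
#' @return a `stimulus_score` with `condition == "no_chord_progression"`
#' @export
shuffle_tonal_tracks <- function(score, rng_seed = 1,
                                 offset_range_s = c(0.25, 2),
                                 method = c("jitter", "permute")) {
  stopifnot(inherits(score, "stimulus_score"))
  method <- match.arg(method)
  if (score$condition != "chord_progression") {
    stop("shuffle_tonal_tracks expects a chord_progression score")
  }
  if (length(offset_range_s) != 2 || !all(is.finite(offset_range_s)) ||
      offset_range_s[2] < offset_range_s[1] || offset_range_s[1] < 0) {
    stop("offset_range_s must be a nondecreasing nonnegative pair")
  }
  events <- score$events
  tonal <- events$track %in% c("melody", "chords", "bass")
  out <- events
  if (any(tonal) && score$length_s > 0) {
    with_seed(rng_seed, {
      if (method == "jitter") {
        n <- sum(tonal)
        mag <- stats::runif(n, offset_range_s[1], offset_range_s[2])
        sgn <- sample(c(-1, 1), n, replace = TRUE)
        out$onset[tonal] <- (events$onset[tonal] + sgn * mag) %% score$length_s
      } else {
        for (tr in c("melody", "chords", "bass")) {
          idx <- which(events$track == tr)
          if (length(idx) > 1) out$onset[idx] <- events$onset[sample(idx)]
        }
      }
    })
  }
  new_stimulus_score(out, score$key, score$tempo_bpm, score$length_s,
                     "no_chord_progression", score$melody_id)
}

#' Build the full 12 + 12 stimulus set
#'
#' One chord-progression exemplar per major key, with one of the four
#' pentatonic melodies randomly assigned to each key, plus the matched
#' note-shuffled control for each exemplar (identical drum track).
#'
#' @param rng_seed integer root seed for melody assignment and shuffling
#' @param tempo_bpm,length_s passed to [compose_chord_progression()]
#' @return list with elements `cp` and `ncp`, each a list of 12 scores named
#'   by key
#' @export
build_stimulus_sets <- function(rng_seed = 1, tempo_bpm = 140, length_s = 15) {
  keys <- major_keys()
  melody_ids <- with_seed(derive_seed(rng_seed, "melody_assignment"),
                          sample(1:4, length(keys), replace = TRUE))
  cp <- ncp <- vector("list", length(keys))
  names(cp) <- names(ncp) <- keys
  for (i in seq_along(keys)) {
    cp[[i]] <- compose_chord_progression(keys[i], melody_ids[i], tempo_bpm,
                                         length_s)
    ncp[[i]] <- shuffle_tonal_tracks(cp[[i]],
                                     derive_seed(rng_seed,
                                                 paste0("shuffle_", keys[i])))
  }
  list(cp = cp, ncp = ncp)
}
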