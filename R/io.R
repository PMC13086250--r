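## Plain-file interchange: 16-bit PCM WAV, standard MIDI files, and a JSON
## event-list dialect for scores. Writers are self-contained (binary formats
## are assembled with writeBin).

#' Write an audio clip as 16-bit PCM mono WAV
#'
#' @param clip an `audio_clip`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(clip$sample_rate)
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal reader for files produced by [write_wav()] (and any canonical
#' 16-bit mono PCM WAV).
#'
#' @param path file path
#' @return an `audio_clip`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (!identical(bits, 16L) || !identical(channels, 1L)) {
    stop("read_wav supports 16-bit mono PCM only")
  }
  new_audio_clip(samples / 32767, sr, basename(path))
}

## --- standard MIDI file export ---------------------------------------------

midi_varlen <- function(value) {
  bytes <- value %% 128L
  value <- value %/% 128L
  while (value > 0) {
    bytes <- c(value %% 128L + 128L, bytes)
    value <- value %/% 128L
  }
  ## continuation bit on all but the last byte
  if (length(bytes) > 1) bytes[-length(bytes)] <- bytes[-length(bytes)]
  as.raw(bytes)
}

int_be <- function(value, size) {
  as.raw(rev((value %/% 256^(0:(size - 1))) %% 256))
}

#' Write a stimulus score as a standard MIDI file
#'
#' Format-1 file with one tempo track plus one track per instrument (melody,
#' chords, bass on channels 1-3; drums on the percussion channel 10), at 480
#' ticks per quarter note.
#'
#' @param score a `stimulus_score`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_midi <- function(score, path) {
  stopifnot(inherits(score, "stimulus_score"))
  division <- 480L
  beat <- 60 / score$tempo_bpm
  tracks <- c("melody", "chords", "bass", "drums")
  channel <- c(melody = 0L, chords = 1L, bass = 2L, drums = 9L)

  track_chunk <- function(body) {
    c(charToRaw("MTrk"), int_be(length(body), 4), body)
  }
  end_of_track <- c(as.raw(0x00), as.raw(c(0xFF, 0x2F, 0x00)))

  ## tempo track
  usec_per_quarter <- as.integer(round(60e6 / score$tempo_bpm))
  tempo_body <- c(as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)),
                  int_be(usec_per_quarter, 3), end_of_track)
  chunks <- list(track_chunk(tempo_body))

  for (tr in tracks) {
    ev <- score$events[score$events$track == tr, , drop = FALSE]
    msgs <- data.frame(tick = integer(0), on = logical(0), pitch = integer(0),
                       vel = integer(0))
    for (i in seq_len(nrow(ev))) {
      t_on <- as.integer(round(ev$onset[i] / beat * division))
      t_off <- as.integer(round((ev$onset[i] + ev$duration[i]) / beat *
                                  division))
      if (t_off <= t_on) t_off <- t_on + 1L
      vel <- as.integer(round(ev$velocity[i] * 127))
      msgs <- rbind(msgs, data.frame(tick = c(t_on, t_off), on = c(TRUE, FALSE),
                                     pitch = ev$pitch[i], vel = c(vel, 0L)))
    }
    msgs <- msgs[order(msgs$tick, msgs$on), , drop = FALSE]  # offs before ons
    body <- raw(0)
    last <- 0L
    ch <- channel[[tr]]
    for (i in seq_len(nrow(msgs))) {
      delta <- msgs$tick[i] - last
      last <- msgs$tick[i]
      status <- if (msgs$on[i]) 0x90L + ch else 0x80L + ch
      body <- c(body, midi_varlen(delta),
                as.raw(c(status, msgs$pitch[i], msgs$vel[i])))
    }
    body <- c(body, end_of_track)
    chunks[[length(chunks) + 1L]] <- track_chunk(body)
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(charToRaw("MThd"), int_be(6, 4), int_be(1, 2),
             int_be(length(chunks), 2), int_be(division, 2)), con)
  for (ch in chunks) writeBin(ch, con)
  invisible(path)
}

#' Write a stimulus score as JSON
#'
#' Schema: top-level fields `key`, `tempo_bpm`, `length_s`, `condition`,
#' `melody_id` and `events`, the latter an array of objects with `onset`,
#' `duration`, `pitch`, `velocity`, `track`.
#'
#' @param score a `stimulus_score`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_score_json <- function(score, path) {
  stopifnot(inherits(score, "stimulus_score"))
  jsonlite::write_json(
    list(key = score$key, tempo_bpm = score$tempo_bpm,
         length_s = score$length_s, condition = score$condition,
         melody_id = score$melody_id, events = score$events),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a score back from its JSON export
#' @param path file path
#' @return a `stimulus_score`
#' @export
read_score_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_stimulus_score(as.data.frame(x$events), x$key, x$tempo_bpm, x$length_s,
                     x$condition, x$melody_id)
}
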