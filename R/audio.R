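# MIDI and WAV export of stimulus timelines.
#
# Standard MIDI File format 1 (one track per player) and 16-bit PCM RIFF
# WAV writers/readers, implemented directly against the format
# specifications. Player 1 and 2 use distinct synthetic percussive bursts;
# the stereo mix pans the players at a 4:1 amplitude ratio (left favours
# player 1, right favours player 2).

#' Rendering specification
#'
#' @param sample_rate WAV sample rate (Hz), >= 8000.
#' @param pan_ratio amplitude ratio of the dominant to the non-dominant
#'   player within a channel (default 4, i.e. 4:1).
#' @param midi_notes General-MIDI note numbers per player (default both 38,
#'   acoustic snare).
#' @param velocity note-on velocity (default 100).
#' @param ppq MIDI pulses per quarter note (default 960; one quarter note =
#'   one 500 ms interbeat at the encoded tempo).
#' @param beat_s duration encoded as one quarter note (s, default 0.5).
#' @param gain master amplitude applied to the unit-peak player samples
#'   (default 0.9). The channel pan weights are normalized to sum to 1, so a
#'   single hit never clips; overlapping hits that would exceed full scale
#'   raise an error rather than clip.
#' @param note_dur_s MIDI note length (s, default 0.1).
#' @param player_samples optional list of two mono waveforms (numeric, peak
#'   <= 1) to use instead of the built-in bursts.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(sample_rate = 44100, pan_ratio = 4,
                        midi_notes = c(38L, 38L), velocity = 100L,
                        ppq = 960L, beat_s = 0.5, gain = 0.9,
                        note_dur_s = 0.1, player_samples = NULL) {
  stopifnot(sample_rate >= 8000, pan_ratio > 0, gain > 0, gain <= 1,
            ppq >= 24, beat_s > 0, length(midi_notes) == 2)
  structure(list(sample_rate = as.integer(sample_rate), pan_ratio = pan_ratio,
                 midi_notes = as.integer(midi_notes),
                 velocity = as.integer(velocity), ppq = as.integer(ppq),
                 beat_s = beat_s, gain = gain, note_dur_s = note_dur_s,
                 player_samples = player_samples),
            class = "render_spec")
}

# ---- synthetic percussive bursts ------------------------------------------

# Deterministic pseudo-noise (Park-Miller LCG in exact double arithmetic),
# independent of R's RNG so that rendering never perturbs simulation
# reproducibility.
.pseudo_noise <- function(n, state = 88172645) {
  out <- numeric(n)
  x <- state
  for (i in seq_len(n)) {
    x <- (16807 * x) %% 2147483647
    out[i] <- x / 2147483647 * 2 - 1
  }
  out
}

# Two spectrally distinct snare-like bursts (exponentially decaying tone
# stack + band-limited pseudo-noise), unit peak, ~80 ms.
.player_sample <- function(player, sample_rate) {
  t <- seq(0, 0.08, by = 1 / sample_rate)
  if (player == 1) {
    tone <- 0.6 * sin(2 * pi * 185 * t) + 0.4 * sin(2 * pi * 330 * t)
    noise_amt <- 0.8
    decay <- 25
  } else {
    tone <- 0.5 * sin(2 * pi * 240 * t) + 0.5 * sin(2 * pi * 452 * t)
    noise_amt <- 0.5
    decay <- 35
  }
  noise <- .pseudo_noise(length(t), state = if (player == 1) 88172645 else 362436069)
  # one-pole smoothing gives the noise a darker spectrum for player 2
  if (player == 2) noise <- stats::filter(noise, 0.6, method = "recursive")
  w <- (tone + noise_amt * as.numeric(noise)) * exp(-decay * t)
  w / max(abs(w))
}

.get_samples <- function(spec) {
  if (!is.null(spec$player_samples)) {
    stopifnot(length(spec$player_samples) == 2)
    lapply(spec$player_samples, function(s) {
      if (max(abs(s)) > 1) stop("player samples must have peak <= 1")
      as.numeric(s)
    })
  } else {
    list(.player_sample(1, spec$sample_rate), .player_sample(2, spec$sample_rate))
  }
}

# ---- MIDI ------------------------------------------------------------------

.vlq <- function(x) { # variable-length quantity encoding
  stopifnot(x >= 0)
  bytes <- x %% 128
  x <- x %/% 128
  while (x > 0) {
    bytes <- c(x %% 128 + 128, bytes)
    x <- x %/% 128
  }
  as.raw(bytes)
}

.be <- function(x, width) { # big-endian unsigned integer
  as.raw((x %/% 256^((width - 1):0)) %% 256)
}

.midi_track <- function(events_raw) {
  c(charToRaw("MTrk"), .be(length(events_raw), 4), events_raw)
}

#' Write a pair timeline as a standard MIDI file
#'
#' Format-1 file with a tempo track (tempo meta event encoding `beat_s` per
#' quarter note) and one track per player on MIDI channel 10 (percussion).
#' Each tap becomes a note-on at tick `round(time / beat_s * ppq)` followed
#' by a note-off.
#'
#' @param timeline a [pair_timeline()].
#' @param spec a [render_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_midi <- function(timeline, spec = render_spec(), path) {
  stopifnot(inherits(timeline, "pair_timeline"), inherits(spec, "render_spec"))
  tempo_us <- round(spec$beat_s * 1e6)
  tempo_track <- .midi_track(c(
    as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)), .be(tempo_us, 3),
    as.raw(0x00), as.raw(c(0xFF, 0x2F, 0x00))))
  note_ticks <- max(1L, round(spec$note_dur_s / spec$beat_s * spec$ppq))
  player_track <- function(taps, note) {
    on_t <- round(taps / spec$beat_s * spec$ppq)
    nt <- note_ticks
    if (length(on_t) > 1) # keep note-offs ahead of the next onset
      nt <- max(1L, min(nt, min(diff(on_t)) - 1L))
    ev <- raw(0)
    cur <- 0
    for (tick in on_t) {
      ev <- c(ev, .vlq(tick - cur), as.raw(c(0x99, note, spec$velocity)),
              .vlq(nt), as.raw(c(0x89, note, 0)))
      cur <- tick + nt
    }
    .midi_track(c(ev, as.raw(0x00), as.raw(c(0xFF, 0x2F, 0x00))))
  }
  header <- c(charToRaw("MThd"), .be(6, 4), .be(1, 2), .be(3, 2),
              .be(spec$ppq, 2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, tempo_track,
             player_track(timeline$taps_p1, spec$midi_notes[1]),
             player_track(timeline$taps_p2, spec$midi_notes[2])), con)
  invisible(path)
}

#' Read note-on times back from a MIDI file
#'
#' Minimal standard-MIDI parser sufficient to round-trip files written by
#' [write_midi()]: returns the note-on times (seconds) of each non-tempo
#' track, using the file's first tempo meta event and PPQ.
#'
#' @param path a MIDI file.
#' @return List of numeric vectors of onset times in seconds, one per
#'   player track.
#' @export
read_midi_onsets <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  be <- function(idx) sum(as.integer(raw[idx]) * 256^((length(idx) - 1):0))
  stopifnot(rawToChar(raw[1:4]) == "MThd")
  ntrk <- be(11:12)
  ppq <- be(13:14)
  pos <- 15
  tempo_us <- 500000
  tracks <- list()
  for (k in seq_len(ntrk)) {
    stopifnot(rawToChar(raw[pos:(pos + 3)]) == "MTrk")
    len <- be((pos + 4):(pos + 7))
    p <- pos + 8
    end <- p + len
    tick <- 0
    onsets <- numeric(0)
    status <- 0L
    while (p < end) {
      # variable-length delta time
      delta <- 0
      repeat {
        b <- as.integer(raw[p]); p <- p + 1
        delta <- delta * 128 + b %% 128
        if (b < 128) break
      }
      tick <- tick + delta
      b <- as.integer(raw[p])
      if (b >= 128) { status <- b; p <- p + 1 }
      if (status == 255) { # meta event
        type <- as.integer(raw[p]); p <- p + 1
        mlen <- 0
        repeat {
          b2 <- as.integer(raw[p]); p <- p + 1
          mlen <- mlen * 128 + b2 %% 128
          if (b2 < 128) break
        }
        if (type == 0x51) tempo_us <- be(p:(p + 2))
        p <- p + mlen
      } else {
        hi <- status %/% 16
        nbytes <- if (hi %in% c(12, 13)) 1 else 2
        if (hi == 9 && as.integer(raw[p + 1]) > 0)
          onsets <- c(onsets, tick)
        p <- p + nbytes
      }
    }
    if (length(onsets)) tracks[[length(tracks) + 1]] <- onsets * tempo_us / 1e6 / ppq
    pos <- end
  }
  tracks
}

# ---- WAV -------------------------------------------------------------------

#' Render a pair timeline as stereo 16-bit PCM WAV
#'
#' Places each player's percussive sample at the nearest audio sample to each
#' tap time and mixes the two players with normalized pan weights
#' `c(pan_ratio, 1) / (pan_ratio + 1)`: the left channel carries players
#' 1 and 2 at ratio `pan_ratio`:1, the right channel the opposite. Swapping the
#' players and swapping the channels yields identical audio.
#'
#' @param timeline a [pair_timeline()].
#' @param spec a [render_spec()].
#' @param path output file path.
#' @param tail_s silence appended after the last onset beyond the sample
#'   length (s, default 0.2).
#' @return `path`, invisibly.
#' @export
render_wav <- function(timeline, spec = render_spec(), path, tail_s = 0.2) {
  stopifnot(inherits(timeline, "pair_timeline"), inherits(spec, "render_spec"))
  sr <- spec$sample_rate
  smp <- .get_samples(spec)
  taps <- list(timeline$taps_p1, timeline$taps_p2)
  dur <- max(unlist(taps), 0) + max(lengths(smp)) / sr + tail_s
  n <- ceiling(dur * sr)
  tracks <- lapply(1:2, function(p) {
    x <- numeric(n)
    L <- length(smp[[p]])
    for (t0 in taps[[p]]) {
      i0 <- round(t0 * sr) + 1
      idx <- i0:(i0 + L - 1)
      x[idx] <- x[idx] + smp[[p]]
    }
    x * spec$gain
  })
  wfar <- 1 / (spec$pan_ratio + 1)
  wnear <- spec$pan_ratio * wfar
  left <- wnear * tracks[[1]] + wfar * tracks[[2]]
  right <- wfar * tracks[[1]] + wnear * tracks[[2]]
  peak <- max(abs(left), abs(right))
  if (peak > 1)
    stop(sprintf("mix clips: peak %.3f > 1.0; lower gain or thin overlaps", peak))
  .write_wav_pcm16(left, right, sr, path)
  invisible(path)
}

.write_wav_pcm16 <- function(left, right, sr, path) {
  n <- length(left)
  pcm <- integer(2 * n)
  pcm[seq(1, 2 * n, 2)] <- as.integer(round(pmax(pmin(left, 1), -1) * 32767))
  pcm[seq(2, 2 * n, 2)] <- as.integer(round(pmax(pmin(right, 1), -1) * 32767))
  data_bytes <- 2L * length(pcm)
  le <- function(x, width) writeBin(as.integer(x), con, size = width,
                                    endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL); le(36 + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); le(16, 4)
  le(1, 2); le(2, 2)            # PCM, stereo
  le(sr, 4); le(sr * 4, 4)      # sample rate, byte rate
  le(4, 2); le(16, 2)           # block align, bits per sample
  writeChar("data", con, eos = NULL); le(data_bytes, 4)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Minimal RIFF reader for files written by [render_wav()].
#'
#' @param path a WAV file.
#' @return List with `left`, `right` (numeric in `[-1, 1]`; `right` is `NULL`
#'   for mono files) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4); stopifnot(hdr == "RIFF")
  readBin(con, "integer", 1, 4, endian = "little")
  stopifnot(readChar(con, 4) == "WAVE")
  sr <- NULL; nchan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      nchan <- fmt[2]
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      ba <- readBin(con, "integer", 2, 2, endian = "little")
      bits <- ba[2]
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      stopifnot(bits == 16)
      pcm <- readBin(con, "integer", sz / 2, 2, endian = "little") / 32767
      break
    } else readBin(con, "raw", sz)
  }
  if (nchan == 2) {
    list(left = pcm[seq(1, length(pcm), 2)],
         right = pcm[seq(2, length(pcm), 2)], sample_rate = sr)
  } else list(left = pcm, right = NULL, sample_rate = sr)
}
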