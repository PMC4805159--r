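# Standard MIDI File (format 0) persistence for note sequences.
#
# Layout written: MThd with the tick resolution, one MTrk containing a tempo
# meta event, a text meta event recording ticks_per_window (so a sequence
# round-trips including its timing), note on/off pairs, and an end-of-track
# meta placed at the sequence's total tick so trailing rests survive.

encode_varlen <- function(x) {
  x <- as.integer(x)
  if (x < 0L) abort("negative delta time")
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  # continuation bit on all but the last byte
  if (length(bytes) > 1L) bytes[-length(bytes)] <- bitwOr(bytes[-length(bytes)], 128L)
  as.raw(bytes)
}

uint_bytes <- function(x, n) {
  as.raw((x %/% 256^((n - 1L):0)) %% 256)
}

#' Write a note sequence as a standard MIDI file
#'
#' Writes a single-track (format 0) MIDI file declaring the sequence's
#' resolution and tempo. Rests become gaps between note-on/note-off pairs;
#' the end-of-track event is placed at the total tick count so trailing
#' rests are preserved. A text meta event records `ticks_per_window`, making
#' [read_midi()] an exact inverse on sequences produced by [quantize()].
#'
#' @param seq A [note_sequence()].
#' @param path Output file path.
#' @param channel MIDI channel 0-15.
#' @return `path`, invisibly.
#' @export
write_midi <- function(seq, path, channel = 0L) {
  stopifnot(inherits(seq, "note_sequence"))
  channel <- as.integer(channel)
  if (channel < 0L || channel > 15L) abort("channel must be in 0..15")
  tempo <- round(60e6 / seq$timing$bpm) # microseconds per quarter note

  ev <- seq$events[seq$events$kind == "note", , drop = FALSE]
  # (tick, order, bytes): note-offs sort before note-ons at the same tick
  msgs <- list(
    list(tick = 0L, ord = 0L,
         bytes = c(as.raw(c(0xFF, 0x51, 0x03)), uint_bytes(tempo, 3L)))
  )
  txt <- charToRaw(sprintf("ticks_per_window=%d", seq$timing$ticks_per_window))
  msgs[[2]] <- list(tick = 0L, ord = 0L,
                    bytes = c(as.raw(c(0xFF, 0x01)), encode_varlen(length(txt)), txt))
  for (i in seq_len(nrow(ev))) {
    on_tick <- ev$start_tick[i]
    off_tick <- ev$start_tick[i] + ev$duration_ticks[i]
    msgs[[length(msgs) + 1L]] <- list(
      tick = on_tick, ord = 2L,
      bytes = as.raw(c(0x90 + channel, ev$pitch[i], ev$velocity[i])))
    msgs[[length(msgs) + 1L]] <- list(
      tick = off_tick, ord = 1L,
      bytes = as.raw(c(0x80 + channel, ev$pitch[i], 0x00)))
  }
  msgs[[length(msgs) + 1L]] <- list(tick = total_ticks(seq), ord = 3L,
                                    bytes = as.raw(c(0xFF, 0x2F, 0x00)))

  ticks <- vapply(msgs, `[[`, 0L, "tick")
  ords <- vapply(msgs, `[[`, 0L, "ord")
  msgs <- msgs[order(ticks, ords)]

  track <- raw(0)
  now <- 0L
  for (m in msgs) {
    track <- c(track, encode_varlen(m$tick - now), m$bytes)
    now <- m$tick
  }

  out <- c(
    charToRaw("MThd"), uint_bytes(6L, 4L),
    uint_bytes(0L, 2L), uint_bytes(1L, 2L),
    uint_bytes(seq$timing$resolution, 2L),
    charToRaw("MTrk"), uint_bytes(length(track), 4L),
    track
  )
  writeBin(out, path)
  invisible(path)
}

#' Read a note sequence from a standard MIDI file
#'
#' Parses a single-track MIDI file written by [write_midi()] (or any format
#' 0/1 file whose first track with notes is monophonic and non-overlapping).
#' Gaps between notes, and before the end-of-track event, are reconstructed
#' as rest events. Malformed input raises an error naming the byte offset.
#'
#' @param path MIDI file path.
#' @return A [note_sequence()].
#' @export
read_midi <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  pos <- 1L
  fail <- function(msg, at = pos) {
    abort(sprintf("malformed MIDI file '%s' at byte offset %d: %s", path, at - 1L, msg))
  }
  take <- function(n) {
    if (pos + n - 1L > length(b)) fail("unexpected end of file")
    out <- b[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  uint <- function(n) sum(as.integer(take(n)) * 256^((n - 1L):0))
  varlen <- function() {
    v <- 0
    repeat {
      byte <- as.integer(take(1L))
      v <- v * 128 + byte %% 128L
      if (byte < 128L) return(v)
    }
  }

  if (!identical(rawToChar(take(4L)), "MThd")) fail("missing MThd header", 1L)
  if (uint(4L) != 6) fail("bad MThd length")
  fmt <- uint(2L)
  n_trk <- uint(2L)
  division <- uint(2L)
  if (division >= 32768) fail("SMPTE time division is not supported")
  if (fmt > 1L) fail(sprintf("unsupported MIDI format %d", fmt))

  tempo <- 500000
  tpw <- NA_integer_
  notes <- list()
  open <- list() # pitch -> list(tick, velocity)
  end_tick <- NA_real_

  for (trk in seq_len(n_trk)) {
    if (!identical(rawToChar(take(4L)), "MTrk")) fail("missing MTrk header")
    trk_len <- uint(4L)
    trk_end <- pos + trk_len
    tick <- 0
    status <- NA_integer_
    while (pos < trk_end) {
      tick <- tick + varlen()
      byte <- as.integer(take(1L))
      if (byte >= 128L) {
        status <- byte
      } else {
        if (is.na(status)) fail("data byte without running status")
        pos <- pos - 1L # running status: re-read as data
      }
      hi <- status %/% 16L
      if (status == 0xFF) {
        type <- as.integer(take(1L))
        len <- varlen()
        dat <- if (len > 0) take(len) else raw(0)
        if (type == 0x51) tempo <- sum(as.integer(dat) * 256^((len - 1L):0))
        if (type == 0x01) {
          m <- regmatches(rawToChar(dat), regexec("ticks_per_window=(\\d+)", rawToChar(dat)))[[1]]
          if (length(m) == 2L) tpw <- as.integer(m[2])
        }
        if (type == 0x2F) end_tick <- max(end_tick, tick, na.rm = TRUE)
        status <- NA_integer_
      } else if (status %in% c(0xF0, 0xF7)) {
        len <- varlen()
        if (len > 0) take(len)
        status <- NA_integer_
      } else if (hi %in% c(0x8, 0x9, 0xA, 0xB, 0xE)) {
        d1 <- as.integer(take(1L))
        d2 <- as.integer(take(1L))
        key <- as.character(d1)
        if (hi == 0x9 && d2 > 0L) {
          open[[key]] <- list(tick = tick, velocity = d2)
        } else if (hi == 0x8 || (hi == 0x9 && d2 == 0L)) {
          if (!is.null(open[[key]])) {
            notes[[length(notes) + 1L]] <- list(
              pitch = d1, start = open[[key]]$tick,
              dur = tick - open[[key]]$tick, vel = open[[key]]$velocity)
            open[[key]] <- NULL
          }
        }
      } else if (hi %in% c(0xC, 0xD)) {
        take(1L)
      } else {
        fail(sprintf("unknown status byte 0x%X", status))
      }
    }
    if (pos != trk_end) fail("track length does not match contents")
  }

  timing <- timing_params(resolution = division, bpm = 60e6 / tempo,
                          ticks_per_window = if (is.na(tpw)) 1L else tpw)
  if (length(notes) == 0L) {
    ev <- empty_events()
    if (is.finite(end_tick) && end_tick > 0) {
      ev <- tibble::tibble(kind = "rest", pitch = NA_integer_, start_tick = 0L,
                           duration_ticks = as.integer(end_tick), velocity = NA_integer_)
    }
    return(note_sequence(ev, timing))
  }

  nt <- dplyr::arrange(dplyr::bind_rows(lapply(notes, tibble::as_tibble)), .data$start)
  if (!is.finite(end_tick)) end_tick <- max(nt$start + nt$dur)
  rows <- list()
  now <- 0
  for (i in seq_len(nrow(nt))) {
    if (nt$start[i] > now) {
      rows[[length(rows) + 1L]] <- list(kind = "rest", pitch = NA_integer_,
                                        start_tick = now, duration_ticks = nt$start[i] - now,
                                        velocity = NA_integer_)
    } else if (nt$start[i] < now) {
      fail("overlapping notes are not supported", pos)
    }
    rows[[length(rows) + 1L]] <- list(kind = "note", pitch = nt$pitch[i],
                                      start_tick = nt$start[i], duration_ticks = nt$dur[i],
                                      velocity = nt$vel[i])
    now <- nt$start[i] + nt$dur[i]
  }
  if (end_tick > now) {
    rows[[length(rows) + 1L]] <- list(kind = "rest", pitch = NA_integer_,
                                      start_tick = now, duration_ticks = end_tick - now,
                                      velocity = NA_integer_)
  }
  ev <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  ev$start_tick <- as.integer(ev$start_tick)
  ev$duration_ticks <- as.integer(ev$duration_ticks)
  ev$pitch <- as.integer(ev$pitch)
  ev$velocity <- as.integer(ev$velocity)
  note_sequence(ev, timing)
}
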