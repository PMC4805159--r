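#' MIDI timing parameters
#'
#' `resolution` is the number of ticks per quarter note (MIDI "division");
#' together with the tempo it fixes the wall-clock duration of one tick, see
#' [tick_duration_us()]. `ticks_per_window` is the number of ticks assigned
#' to one genomic bin; the defaults (resolution 600, 300 ticks per window,
#' 120 BPM) make each 300 bp bin a quaver (1/8 note).
#'
#' @param resolution Ticks per quarter note (positive integer).
#' @param bpm Tempo in beats (quarter notes) per minute.
#' @param ticks_per_window Ticks per genomic bin (positive integer).
#'
#' @return A `timing_params` object.
#' @export
timing_params <- function(resolution = 600, bpm = 120, ticks_per_window = 300) {
  resolution <- as.integer(resolution)
  ticks_per_window <- as.integer(ticks_per_window)
  if (resolution < 1L || ticks_per_window < 1L || !is.finite(bpm) || bpm <= 0) {
    abort("timing_params: resolution, ticks_per_window and bpm must be positive")
  }
  structure(list(resolution = resolution, bpm = as.double(bpm),
                 ticks_per_window = ticks_per_window),
            class = "timing_params")
}

#' Duration of one MIDI tick in microseconds
#'
#' One quarter note lasts `60e6 / bpm` microseconds and is divided into
#' `resolution` ticks, so `T = 60e6 / (resolution * bpm)`.
#'
#' @param timing A [timing_params()].
#' @return Tick duration in microseconds.
#' @examples
#' tick_duration_us(timing_params(resolution = 1, bpm = 60)) # 1e6
#' @export
tick_duration_us <- function(timing) {
  stopifnot(inherits(timing, "timing_params"))
  60e6 / (timing$resolution * timing$bpm)
}

#' Quantization grid over a signal's intensity range
#'
#' Divides `[lo, hi]` into `n_levels` equal-width bands (`n_levels + 1`
#' edges). Values in the lowest band quantize to level 0, which encodes a
#' rest; bands 1 and above map to scale pitches. The top band is closed on
#' the right so the maximum value is kept; all other bands are right-open.
#'
#' @param binned A [binned_signal()] supplying the range (per-track min/max),
#'   or `NULL` when `lo`/`hi` are given explicitly.
#' @param n_levels Number of bands (default 52, the default semitone count).
#' @param lo,hi Explicit range; required when the signal is constant.
#'
#' @return A `quantization_grid` with fields `n_levels`, `lo`, `hi`,
#'   `boundaries`.
#' @export
make_grid <- function(binned = NULL, n_levels = 52, lo = NULL, hi = NULL) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) abort("make_grid: need at least 2 levels (rest + 1 pitch)")
  if (is.null(lo) || is.null(hi)) {
    if (is.null(binned)) abort("make_grid: supply a binned signal or an explicit lo/hi range")
    stopifnot(inherits(binned, "binned_signal"))
    lo <- min(binned$values)
    hi <- max(binned$values)
    if (lo == hi) {
      abort("make_grid: signal range is degenerate (all values identical); supply lo/hi explicitly")
    }
  }
  if (!(lo < hi)) abort("make_grid: need lo < hi")
  structure(
    list(n_levels = n_levels, lo = as.double(lo), hi = as.double(hi),
         boundaries = seq(lo, hi, length.out = n_levels + 1L)),
    class = "quantization_grid"
  )
}

#' Quantization level of values on a grid
#'
#' @param x Numeric values.
#' @param grid A [make_grid()] grid.
#' @return Integer levels in `0..n_levels - 1`; level 0 is the rest band.
#'   Values outside `[lo, hi]` clamp to the end levels.
#' @export
grid_level <- function(x, grid) {
  stopifnot(inherits(grid, "quantization_grid"))
  w <- (grid$hi - grid$lo) / grid$n_levels
  lev <- floor((x - grid$lo) / w)
  as.integer(pmin(pmax(lev, 0), grid$n_levels - 1L))
}

#' Quantize a binned signal into a note sequence
#'
#' Each genomic bin is assigned a quantization level on `grid`; level 0
#' becomes a rest and level `l >= 1` becomes a note with pitch
#' `scale$pitches[l]`, so louder bins map to higher in-scale pitches.
#' Maximal runs of `k` consecutive bins with equal level collapse into a
#' single event of duration `k * ticks_per_window` (consecutive equal notes
#' are merged, doubling duration pairwise); total tick duration is conserved.
#'
#' @param binned A [binned_signal()].
#' @param grid A [make_grid()] grid; needs `n_levels - 1 <=
#'   length(scale$pitches)`.
#' @param scale A [build_scale()] scale.
#' @param timing A [timing_params()].
#' @param velocity MIDI velocity for all notes (1-127).
#'
#' @return A `note_sequence`: a tibble of events (`kind`, `pitch`,
#'   `start_tick`, `duration_ticks`, `velocity`) plus the timing parameters.
#' @export
quantize <- function(binned, grid, scale, timing = timing_params(), velocity = 100L) {
  stopifnot(inherits(binned, "binned_signal"), inherits(grid, "quantization_grid"),
            inherits(scale, "scale_definition"), inherits(timing, "timing_params"))
  velocity <- as.integer(velocity)
  if (velocity < 1L || velocity > 127L) abort("velocity must be in 1..127")
  if (grid$n_levels - 1L > length(scale$pitches)) {
    abort(sprintf("grid has %d pitch levels but scale only %d pitches",
                  grid$n_levels - 1L, length(scale$pitches)))
  }
  lev <- grid_level(binned$values, grid)
  if (length(lev) == 0L) {
    return(note_sequence(empty_events(), timing))
  }
  r <- rle(lev)
  dur <- r$lengths * timing$ticks_per_window
  start <- c(0L, head(cumsum(dur), -1L))
  is_note <- r$values >= 1L
  events <- tibble::tibble(
    kind = ifelse(is_note, "note", "rest"),
    pitch = ifelse(is_note, scale$pitches[pmax(r$values, 1L)], NA_integer_),
    start_tick = as.integer(start),
    duration_ticks = as.integer(dur),
    velocity = ifelse(is_note, velocity, NA_integer_)
  )
  note_sequence(events, timing)
}

empty_events <- function() {
  tibble::tibble(kind = character(), pitch = integer(), start_tick = integer(),
                 duration_ticks = integer(), velocity = integer())
}

#' Note sequence
#'
#' An ordered, contiguous, non-overlapping stream of note and rest events
#' with tick timing. Usually produced by [quantize()] or [read_midi()].
#'
#' @param events Tibble with columns `kind` (`"note"`/`"rest"`), `pitch`
#'   (MIDI number, `NA` for rests), `start_tick`, `duration_ticks`,
#'   `velocity` (`NA` for rests).
#' @param timing A [timing_params()].
#' @return A `note_sequence` object.
#' @export
note_sequence <- function(events, timing = timing_params()) {
  stopifnot(inherits(timing, "timing_params"))
  events <- tibble::as_tibble(events)
  need <- c("kind", "pitch", "start_tick", "duration_ticks", "velocity")
  if (!all(need %in% names(events))) {
    abort(sprintf("note_sequence events need columns: %s", paste(need, collapse = ", ")))
  }
  events <- events[need]
  if (nrow(events) > 0L) {
    if (any(events$duration_ticks < 1L)) abort("event durations must be >= 1 tick")
    expect_start <- c(0L, head(cumsum(events$duration_ticks), -1L))
    if (any(events$start_tick != expect_start)) {
      abort("events must be contiguous: each start = previous start + previous duration")
    }
    bad <- events$kind == "note" & (is.na(events$pitch) | is.na(events$velocity))
    if (any(bad)) abort("note events need pitch and velocity")
  }
  structure(list(events = events, timing = timing), class = "note_sequence")
}

#' Total duration of a note sequence in ticks
#' @param seq A [note_sequence()].
#' @return Integer tick count.
#' @export
total_ticks <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  if (nrow(seq$events) == 0L) return(0L)
  as.integer(sum(seq$events$duration_ticks))
}

#' @export
print.note_sequence <- function(x, ...) {
  n_note <- sum(x$events$kind == "note")
  cat(sprintf("<note_sequence> %d events (%d notes, %d rests), %d ticks @ R=%d, %.4g BPM\n",
              nrow(x$events), n_note, nrow(x$events) - n_note, total_ticks(x),
              x$timing$resolution, x$timing$bpm))
  if (nrow(x$events) > 0L) print(head(x$events, 8))
  invisible(x)
}

#' @describeIn note_sequence Events as a tibble, with note names attached.
#' @param x A `note_sequence`.
#' @param ... Unused.
#' @export
tidy.note_sequence <- function(x, ...) {
  dplyr::mutate(x$events,
                note = ifelse(.data$kind == "note", pitch_name(.data$pitch), NA_character_))
}

#' Sonify a raw coverage signal in one call
#'
#' Convenience wrapper: bin + log-transform, build the scale and grid, and
#' quantize. The number of quantization levels defaults to
#' `length(scale$pitches) + 1` (every scale pitch usable plus the rest band),
#' capped at `n_levels` when given.
#'
#' @param raw A [raw_signal()].
#' @param bin_size Genomic bin size in bp.
#' @param key,mode,base_octave,n_octaves Scale parameters, see [build_scale()].
#' @param timing A [timing_params()].
#' @param n_levels Number of quantization levels; `NULL` for the default.
#' @param lo,hi Optional explicit intensity range for the grid.
#'
#' @return A [note_sequence()].
#' @export
sonify <- function(raw, bin_size = 300, key = "C", mode = "chromatic",
                   base_octave = 4, n_octaves = 4, timing = timing_params(),
                   n_levels = NULL, lo = NULL, hi = NULL) {
  binned <- bin_signal(raw, bin_size)
  scale <- build_scale(key, mode, base_octave, n_octaves)
  if (is.null(n_levels)) n_levels <- length(scale$pitches) + 1L
  n_levels <- min(n_levels, length(scale$pitches) + 1L)
  grid <- make_grid(binned, n_levels = n_levels, lo = lo, hi = hi)
  quantize(binned, grid, scale, timing)
}
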