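PITCH_CLASSES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

SCALE_INTERVALS <- list(
  chromatic  = 0:11,
  major      = c(0L, 2L, 4L, 5L, 7L, 9L, 11L),
  minor      = c(0L, 2L, 3L, 5L, 7L, 8L, 10L), # natural minor
  pentatonic = c(0L, 2L, 4L, 7L, 9L)           # major pentatonic
)

#' Build a musical scale as an ordered set of MIDI pitches
#'
#' Returns the in-scale pitches spanning `n_octaves` upward from the root at
#' `(key, base_octave)`, plus the closing root one octave above the last span.
#' Octave numbering follows the MIDI convention with C4 = middle C = note 60,
#' so e.g. B3 is note 59.
#'
#' @param key Pitch class of the root: one of `"C", "C#", ..., "B"`.
#' @param mode `"chromatic"`, `"major"`, `"minor"` (natural) or
#'   `"pentatonic"` (major pentatonic intervals).
#' @param base_octave Octave of the root note.
#' @param n_octaves Number of octaves to span (>= 1).
#'
#' @return A `scale_definition` object with fields `key`, `mode`,
#'   `base_octave`, `n_octaves` and `pitches` (strictly increasing MIDI note
#'   numbers; 12 per octave for chromatic, 7 for major/minor, 5 for
#'   pentatonic, plus the closing root).
#' @examples
#' length(build_scale("B", "minor", 3, 4)$pitches) # 29
#' @export
build_scale <- function(key = "C", mode = "chromatic", base_octave = 4, n_octaves = 4) {
  key <- match.arg(toupper(key), PITCH_CLASSES)
  if (!mode %in% names(SCALE_INTERVALS)) {
    abort(sprintf("unknown scale mode '%s' (use %s)", mode,
                  paste(names(SCALE_INTERVALS), collapse = ", ")))
  }
  n_octaves <- as.integer(n_octaves)
  if (n_octaves < 1L) abort("n_octaves must be >= 1")
  root <- 12L * (as.integer(base_octave) + 1L) + (match(key, PITCH_CLASSES) - 1L)
  steps <- SCALE_INTERVALS[[mode]]
  pitches <- c(outer(steps, 12L * (seq_len(n_octaves) - 1L), `+`)) + root
  pitches <- sort(c(pitches, root + 12L * n_octaves))
  if (any(pitches < 0L | pitches > 127L)) {
    abort("scale exceeds the MIDI pitch range 0..127; lower base_octave or n_octaves")
  }
  structure(
    list(key = key, mode = mode, base_octave = as.integer(base_octave),
         n_octaves = n_octaves, pitches = as.integer(pitches)),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale> %s %s, octaves %d..%d, %d pitches (MIDI %d..%d)\n",
              x$key, x$mode, x$base_octave, x$base_octave + x$n_octaves,
              length(x$pitches), min(x$pitches), max(x$pitches)))
  invisible(x)
}

#' Note name of a MIDI pitch
#' @param pitch MIDI note number(s).
#' @return Character note names such as `"B3"`.
#' @export
pitch_name <- function(pitch) {
  paste0(PITCH_CLASSES[pitch %% 12L + 1L], pitch %/% 12L - 1L)
}
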