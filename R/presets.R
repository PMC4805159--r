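#' Per-antibody sonification presets
#'
#' The parameter set used to convert each ChIP-seq mark to music: scale mode,
#' base octave, key, tick size (ticks per genomic bin) and bin size (bp).
#' Every mark maps to B natural minor; broad marks get larger bins with
#' proportionally more ticks so tempo is preserved.
#'
#' @return A tibble with columns `antibody`, `scale`, `octave`, `key`,
#'   `tick_size`, `bin_size`.
#' @examples
#' chip_presets()
#' @export
chip_presets <- function() {
  tibble::tribble(
    ~antibody,  ~scale,  ~octave, ~key, ~tick_size, ~bin_size,
    "H3K27me3", "minor", 4L,      "B",  600L,       400L,
    "H3K27ac",  "minor", 3L,      "B",  900L,       600L,
    "H3K9ac",   "minor", 3L,      "B",  1200L,      800L,
    "H3K36me3", "minor", 4L,      "B",  300L,       200L,
    "H3K4me1",  "minor", 3L,      "B",  1200L,      800L,
    "H3K4me2",  "minor", 3L,      "B",  300L,       200L,
    "H3K4me3",  "minor", 3L,      "B",  300L,       200L,
    "H3K9me3",  "minor", 4L,      "B",  300L,       200L,
    "Pol2",     "minor", 4L,      "B",  600L,       400L
  )
}

#' Read a preset table from a TSV file
#'
#' The package ships its default presets as a plain-text table in
#' `inst/extdata/presets.tsv`; this reads that file (or a user-supplied one
#' with the same columns).
#'
#' @param path Path to a preset TSV; defaults to the shipped table.
#' @return A tibble like [chip_presets()].
#' @export
read_presets <- function(path = system.file("extdata", "presets.tsv",
                                            package = "chromatune")) {
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("antibody", "scale", "octave", "key", "tick_size", "bin_size")
  if (!all(need %in% names(df))) {
    abort(sprintf("preset table must have columns: %s", paste(need, collapse = ", ")))
  }
  df$octave <- as.integer(df$octave)
  df$tick_size <- as.integer(df$tick_size)
  df$bin_size <- as.integer(df$bin_size)
  df[need]
}

#' Look up one antibody's preset
#' @param antibody Antibody name, e.g. `"H3K4me3"`.
#' @param presets Preset table (default [chip_presets()]).
#' @return A one-row tibble.
#' @export
get_preset <- function(antibody, presets = chip_presets()) {
  row <- presets[presets$antibody == antibody, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("no preset for antibody '%s' (have: %s)", antibody,
                  paste(presets$antibody, collapse = ", ")))
  }
  row
}
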