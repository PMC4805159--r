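# End-to-end helpers wiring signal -> score -> audio -> MFCC -> GMM.

#' Default pipeline parameters
#'
#' Bundles the sonification and summarization settings used by the
#' track-comparison pipeline: 300 bp bins, B natural minor over four octaves
#' starting at octave 3 (29 pitches, so 30 quantization levels including the
#' rest band), default MIDI timing (one bin = one quaver), synthesis at
#' 22.05 kHz, 25 ms / 10 ms MFCC frames with 30 coefficients, and a
#' 10-component GMM.
#'
#' @param bin_size Genomic bin size (bp).
#' @param key,mode,base_octave,n_octaves Scale parameters ([build_scale()]).
#' @param timing [timing_params()].
#' @param sample_rate Synthesis rate (Hz).
#' @param n_mfcc MFCC coefficients per frame.
#' @param n_gmm GMM components per track.
#' @param seed Seed for GMM initialization.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(bin_size = 300, key = "B", mode = "minor",
                            base_octave = 3, n_octaves = 4,
                            timing = timing_params(), sample_rate = 22050,
                            n_mfcc = 30, n_gmm = 10, seed = 1) {
  list(bin_size = bin_size, key = key, mode = mode, base_octave = base_octave,
       n_octaves = n_octaves, timing = timing, sample_rate = sample_rate,
       n_mfcc = n_mfcc, n_gmm = n_gmm, seed = seed)
}

#' Summarize one coverage track as a fitted GMM
#'
#' Runs the full per-track pipeline: bin + log-transform, quantize onto the
#' scale, synthesize audio, extract MFCC frames and fit the mixture model.
#'
#' @param raw A [raw_signal()].
#' @param params A [pipeline_params()] list.
#' @return A [gmm_model()].
#' @export
track_to_gmm <- function(raw, params = pipeline_params()) {
  seq <- sonify(raw, bin_size = params$bin_size, key = params$key,
                mode = params$mode, base_octave = params$base_octave,
                n_octaves = params$n_octaves, timing = params$timing)
  w <- synthesize(seq, sample_rate = params$sample_rate)
  m <- extract_mfcc(w, n_coeff = params$n_mfcc)
  fit_gmm(m, n_components = params$n_gmm, seed = params$seed)
}

#' Score a 2 x 2 quartet of coverage tracks
#'
#' @param quartet Named list of four [raw_signal()]s: `a1`, `a2` (condition A
#'   replicates) and `b1`, `b2` (condition B replicates).
#' @param params A [pipeline_params()] list.
#' @return A [quartet_distances()] object.
#' @export
score_quartet <- function(quartet, params = pipeline_params()) {
  need <- c("a1", "a2", "b1", "b2")
  if (!all(need %in% names(quartet))) {
    abort("quartet must be a named list with elements a1, a2, b1, b2")
  }
  models <- lapply(quartet[need], track_to_gmm, params = params)
  compare_quartet(models$a1, models$a2, models$b1, models$b2)
}

#' Score every locus of a simulated DE scenario
#'
#' Applies [score_quartet()] to each locus of a
#' [simulate_de_experiment()] scenario and returns the per-locus D statistic
#' next to the true label.
#'
#' @param scenario A `de_scenario` from [simulate_de_experiment()].
#' @param params A [pipeline_params()] list.
#' @return A tibble with columns `locus`, `label`, `w_bar`, `b_bar`, `D`.
#' @export
score_de_scenario <- function(scenario, params = pipeline_params()) {
  stopifnot(inherits(scenario, "de_scenario"))
  purrr::imap_dfr(scenario$loci, function(quartet, i) {
    q <- score_quartet(quartet, params)
    tibble::tibble(locus = i, label = scenario$labels[i],
                   w_bar = q$w_bar, b_bar = q$b_bar, D = q$D)
  })
}

#' Grid search over MFCC and GMM sizes
#'
#' For every `(n_mfcc, n_gmm)` cell, re-runs the summarization (MFCC frames,
#' mixture fit, Hausdorff quartet distances, D statistic) on each locus and
#' measures the AUC of D against the labels. Waveforms are synthesized once
#' per track and reused across cells. Ties in AUC resolve to the smaller
#' `n_mfcc`, then the smaller `n_gmm`.
#'
#' @param tracks List (one element per locus) of named lists `a1`, `a2`,
#'   `b1`, `b2` of [raw_signal()]s — e.g. `scenario$loci`.
#' @param labels Binary label per locus.
#' @param mfcc_counts,gmm_counts Integer vectors defining the grid.
#' @param params Baseline [pipeline_params()]; `n_mfcc`/`n_gmm` are overridden
#'   per cell.
#' @return A `grid_search_result`: list with `best` (row of the best cell)
#'   and `table` (tibble of `n_mfcc`, `n_gmm`, `auc`, `p_value`).
#' @export
grid_search <- function(tracks, labels, mfcc_counts = c(10, 30),
                        gmm_counts = c(2, 10), params = pipeline_params()) {
  if (length(tracks) < 2L) abort("grid_search: need at least two loci")
  if (length(labels) != length(tracks)) abort("one label per locus required")
  mfcc_counts <- sort(unique(as.integer(mfcc_counts)))
  gmm_counts <- sort(unique(as.integer(gmm_counts)))
  if (length(mfcc_counts) < 1L || length(gmm_counts) < 1L) abort("empty grid")

  waves <- purrr::map(tracks, function(quartet) {
    purrr::map(quartet[c("a1", "a2", "b1", "b2")], function(raw) {
      seq <- sonify(raw, bin_size = params$bin_size, key = params$key,
                    mode = params$mode, base_octave = params$base_octave,
                    n_octaves = params$n_octaves, timing = params$timing)
      synthesize(seq, sample_rate = params$sample_rate)
    })
  })

  rows <- list()
  for (nm in mfcc_counts) {
    mfccs <- purrr::map(waves, function(q) purrr::map(q, extract_mfcc, n_coeff = nm))
    for (ng in gmm_counts) {
      D <- vapply(mfccs, function(q) {
        models <- purrr::map(q, fit_gmm, n_components = ng, seed = params$seed)
        compare_quartet(models$a1, models$a2, models$b1, models$b2)$D
      }, 0)
      roc <- auc_roc(D, labels)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_mfcc = nm, n_gmm = ng, auc = roc$auc, p_value = roc$p_value)
    }
  }
  table <- dplyr::bind_rows(rows)
  best <- table[which.max(table$auc), , drop = FALSE] # first max: smallest n_mfcc, then n_gmm
  structure(list(best = best, table = table), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> best: n_mfcc = %d, n_gmm = %d, AUC = %.4f\n",
              x$best$n_mfcc, x$best$n_gmm, x$best$auc))
  print(x$table)
  invisible(x)
}

#' @describeIn grid_search AUC table of the grid.
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @export
tidy.grid_search_result <- function(x, ...) x$table
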