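# Negative-binomial coverage simulator: background reads with localized
# rectangular enrichment peaks, and two-condition / two-replicate designs
# with a controllable fraction of differential loci.

#' Simulation configuration
#'
#' @param background_mean Background coverage in reads per base.
#' @param dispersion Negative-binomial size parameter; variance is
#'   `mu + mu^2 / dispersion`, and `Inf` gives Poisson sampling.
#' @param seed Integer seed; all draws are deterministic given the seed.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(background_mean = 5, dispersion = 10, seed = 1) {
  if (background_mean <= 0) abort("background_mean must be > 0")
  if (!(dispersion > 0)) abort("dispersion must be > 0 (use Inf for Poisson)")
  structure(list(background_mean = as.double(background_mean),
                 dispersion = as.double(dispersion), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Enrichment peak specification
#'
#' @param center Peak center as a bp offset from the region start.
#' @param width Peak width in bp (> 0).
#' @param fold Mean enrichment over background inside the peak (>= 1).
#' @return A `peak_spec` object.
#' @export
peak_spec <- function(center, width, fold) {
  if (width <= 0) abort("peak width must be > 0")
  if (fold < 1) abort("peak fold must be >= 1")
  structure(list(center = as.double(center), width = as.double(width),
                 fold = as.double(fold)), class = "peak_spec")
}

# Per-base expected fold over background for a peak list.
peak_fold_profile <- function(n, peaks) {
  fold <- rep(1, n)
  for (p in peaks) {
    a <- max(1L, as.integer(ceiling(p$center - p$width / 2)) + 1L)
    b <- min(n, as.integer(floor(p$center + p$width / 2)))
    if (a <= b) fold[a:b] <- pmax(fold[a:b], p$fold)
  }
  fold
}

#' Simulate a coverage track
#'
#' Per-base counts are drawn from a negative binomial with mean
#' `background_mean * fold(x)` (fold 1 outside peaks) and size `dispersion`;
#' `dispersion = Inf` draws Poisson counts. Deterministic given the config
#' seed.
#'
#' @param region A [genomic_region()].
#' @param cfg A [simulation_config()].
#' @param peaks List of [peak_spec()]s; offsets must fall inside the region.
#' @return A [raw_signal()].
#' @export
simulate_coverage <- function(region, cfg = simulation_config(), peaks = list()) {
  stopifnot(inherits(region, "genomic_region"), inherits(cfg, "simulation_config"))
  n <- region_length(region)
  for (p in peaks) {
    if (p$center < 0 || p$center > n) abort("peak center outside region")
  }
  mu <- cfg$background_mean * peak_fold_profile(n, peaks)
  vals <- with_seed(cfg$seed, draw_counts(mu, cfg$dispersion))
  raw_signal(region, vals)
}

draw_counts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) rpois(length(mu), mu) else {
    rnbinom(length(mu), mu = mu, size = dispersion)
  }
}

#' Simulate a two-condition, two-replicate differential experiment
#'
#' Each locus gets a random layout of 2-4 rectangular peaks (width 300-800
#' bp, fold 4-16 over background). Non-differential loci use the same layout
#' in both conditions, so their four tracks differ only by sampling noise;
#' differential loci have all peak folds multiplied by `effect_fold` in
#' condition B. Exactly `round(frac_de * n_loci)` loci are differential.
#'
#' @param cfg A [simulation_config()]; its seed drives every draw.
#' @param n_loci Number of loci (>= 2).
#' @param frac_de Fraction of differential loci in `[0, 1]`.
#' @param effect_fold Multiplier applied to peak folds in condition B of
#'   differential loci (1 = null experiment).
#' @param locus_length Length of each locus in bp.
#'
#' @return A `de_scenario`: list with `loci` (per locus, a named list of
#'   four [raw_signal()]s `a1`, `a2`, `b1`, `b2`), `labels` (1 =
#'   differential), `peaks` (per-locus layouts) and `cfg`.
#' @export
simulate_de_experiment <- function(cfg = simulation_config(), n_loci = 60,
                                   frac_de = 0.5, effect_fold = 8,
                                   locus_length = 6000) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_loci <- as.integer(n_loci)
  if (n_loci < 2L) abort("n_loci must be >= 2")
  if (frac_de < 0 || frac_de > 1) abort("frac_de must be in [0, 1]")
  if (effect_fold < 1) abort("effect_fold must be >= 1")

  with_seed(cfg$seed, {
    n_de <- round(frac_de * n_loci)
    labels <- integer(n_loci)
    if (n_de > 0L) labels[sample.int(n_loci, n_de)] <- 1L

    peaks_per_locus <- lapply(seq_len(n_loci), function(i) {
      k <- sample(2:4, 1L)
      lapply(seq_len(k), function(j) {
        width <- runif(1, 300, 800)
        center <- runif(1, width / 2, locus_length - width / 2)
        peak_spec(center, width, runif(1, 4, 16))
      })
    })

    loci <- lapply(seq_len(n_loci), function(i) {
      region <- genomic_region("chrS", (i - 1L) * locus_length, i * locus_length)
      peaks_a <- peaks_per_locus[[i]]
      peaks_b <- if (labels[i] == 1L) {
        lapply(peaks_a, function(p) peak_spec(p$center, p$width, p$fold * effect_fold))
      } else {
        peaks_a
      }
      mu_a <- cfg$background_mean * peak_fold_profile(locus_length, peaks_a)
      mu_b <- cfg$background_mean * peak_fold_profile(locus_length, peaks_b)
      list(
        a1 = raw_signal(region, draw_counts(mu_a, cfg$dispersion)),
        a2 = raw_signal(region, draw_counts(mu_a, cfg$dispersion)),
        b1 = raw_signal(region, draw_counts(mu_b, cfg$dispersion)),
        b2 = raw_signal(region, draw_counts(mu_b, cfg$dispersion))
      )
    })

    structure(list(loci = loci, labels = labels, peaks = peaks_per_locus,
                   cfg = cfg, effect_fold = effect_fold, frac_de = frac_de),
              class = "de_scenario")
  })
}

#' @export
print.de_scenario <- function(x, ...) {
  cat(sprintf("<de_scenario> %d loci (%d differential), effect_fold = %g, seed = %d\n",
              length(x$loci), sum(x$labels), x$effect_fold, x$cfg$seed))
  invisible(x)
}

#' Write a DE scenario as bedGraph tracks plus a label table
#'
#' Writes four bedGraph files (`a1.bedgraph`, ..., `b2.bedgraph`, all loci
#' concatenated on the simulated chromosome) and `labels.tsv` into `dir`, so
#' simulated designs flow through the same readers as real data.
#'
#' @param scenario A `de_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_de_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "de_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (track in c("a1", "a2", "b1", "b2")) {
    path <- file.path(dir, paste0(track, ".bedgraph"))
    if (file.exists(path)) file.remove(path)
    for (locus in scenario$loci) write_bedgraph(locus[[track]], path, append = TRUE)
  }
  labs <- purrr::imap_dfr(scenario$loci, function(quartet, i) {
    region <- quartet$a1$region
    tibble::tibble(locus = i, chrom = region$chrom, start = region$start,
                   end = region$end, label = scenario$labels[i])
  })
  write.table(labs, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
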