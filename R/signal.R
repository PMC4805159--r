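#' Per-base raw signal over a region
#'
#' @param region A [genomic_region()].
#' @param values Numeric vector of non-negative per-base coverage, one value
#'   per base of the region.
#'
#' @return A `raw_signal` object.
#' @export
raw_signal <- function(region, values) {
  stopifnot(inherits(region, "genomic_region"))
  values <- as.double(values)
  if (length(values) != region_length(region)) {
    abort(sprintf("raw_signal: expected %d values (one per base), got %d",
                  region_length(region), length(values)))
  }
  if (anyNA(values) || any(values < 0)) {
    abort("raw_signal: values must be finite and non-negative")
  }
  structure(list(region = region, values = values), class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s:%d-%d, %d bases, mean coverage %.3f\n",
              x$region$chrom, x$region$start, x$region$end,
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Binned log-intensity signal
#'
#' Usually produced by [bin_signal()]; the constructor is exported so
#' synthetic bin-level signals can be built directly.
#'
#' @param region A [genomic_region()].
#' @param bin_size Bin width in bp.
#' @param values Mean log-intensity per bin; length must be
#'   `ceiling(region_length(region) / bin_size)`.
#'
#' @return A `binned_signal` object.
#' @export
binned_signal <- function(region, bin_size, values) {
  stopifnot(inherits(region, "genomic_region"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) abort("bin_size must be >= 1")
  values <- as.double(values)
  n_expect <- ceiling(region_length(region) / bin_size)
  if (length(values) != n_expect) {
    abort(sprintf("binned_signal: expected %d bins, got %d", n_expect, length(values)))
  }
  if (anyNA(values) || any(!is.finite(values))) abort("binned_signal: values must be finite")
  structure(list(region = region, bin_size = bin_size, values = values),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("<binned_signal> %s:%d-%d, %d bins of %d bp, range [%.3f, %.3f]\n",
              x$region$chrom, x$region$start, x$region$end,
              length(x$values), x$bin_size, min(x$values), max(x$values)))
  invisible(x)
}

#' Bin a raw signal and log-transform bin means
#'
#' Splits the per-base signal into consecutive fixed-size windows (the last
#' window may be partial and is averaged over its actual width) and records
#' the natural log of 1 + mean coverage per window. The pseudocount keeps
#' zero-coverage bins finite at exactly 0.
#'
#' @param raw A [raw_signal()].
#' @param bin_size Window size in bp (default 300, the size mapped to one
#'   quaver at default timing).
#'
#' @return A [binned_signal()] with `log1p(mean coverage)` per bin.
#' @examples
#' r <- genomic_region("chr1", 0, 900)
#' bin_signal(raw_signal(r, rep(exp(1) - 1, 900)), 300)$values # 1 1 1
#' @export
bin_signal <- function(raw, bin_size = 300) {
  stopifnot(inherits(raw, "raw_signal"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) abort("bin_size must be >= 1")
  n <- length(raw$values)
  if (n == 0L) abort("bin_signal: empty raw signal")
  nb <- ceiling(n / bin_size)
  idx <- rep(seq_len(nb), each = bin_size, length.out = n)
  sums <- vapply(split(raw$values, factor(idx, levels = seq_len(nb))), sum, 0)
  widths <- tabulate(idx, nbins = nb)
  binned_signal(raw$region, bin_size, log1p(unname(sums / widths)))
}

#' Shuffle a signal at base level
#'
#' Uniformly permutes the per-base values; the multiset of values is exactly
#' preserved. Base-level shuffling destroys the spatial concentration of
#' reads, so subsequent binning yields near-constant bin means (the
#' "repeated note" control for sonified tracks).
#'
#' @param raw A [raw_signal()].
#' @param seed Integer seed; same seed, same permutation.
#' @return A [raw_signal()] with permuted values.
#' @export
randomize_base_level <- function(raw, seed) {
  stopifnot(inherits(raw, "raw_signal"))
  v <- raw$values
  raw_signal(raw$region, v[with_seed(seed, sample.int(length(v)))])
}

#' Shuffle a signal at bin level
#'
#' Uniformly permutes bin values, which is equivalent to shuffling the notes
#' of the resulting score while keeping their durations' building blocks.
#'
#' @param binned A [binned_signal()].
#' @param seed Integer seed; same seed, same permutation.
#' @return A [binned_signal()] with permuted values.
#' @export
randomize_bin_level <- function(binned, seed) {
  stopifnot(inherits(binned, "binned_signal"))
  v <- binned$values
  binned_signal(binned$region, binned$bin_size, v[with_seed(seed, sample.int(length(v)))])
}

#' Read per-base coverage for a region from a bedGraph or bigWig track
#'
#' Bases not covered by any track interval get coverage 0. The requested
#' region is clamped to the chromosome bounds declared by the file when that
#' information is available (bigWig); requesting a chromosome absent from the
#' file is an error.
#'
#' @param path Path to a 4-column bedGraph (`chrom start end value`,
#'   0-based half-open) or a bigWig file.
#' @param region A [genomic_region()] to extract.
#' @param format `"auto"` (by file extension), `"bedGraph"` or `"bigWig"`.
#'
#' @return A [raw_signal()] over the (possibly clamped) region.
#' @export
read_coverage <- function(path, region, format = c("auto", "bedGraph", "bigWig")) {
  stopifnot(inherits(region, "genomic_region"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "bigWig" else "bedGraph"
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_coverage requires the rtracklayer package")
  }
  if (format == "bigWig") {
    si <- rtracklayer::seqinfo(rtracklayer::BigWigFile(path))
    if (!region$chrom %in% GenomicRanges::seqnames(si)) {
      abort(sprintf("chromosome '%s' not present in %s", region$chrom, path))
    }
    chrom_len <- GenomicRanges::seqlengths(si)[[region$chrom]]
    region <- clamp_region(region, chrom_len)
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start + 1L, region$end))
    gr <- rtracklayer::import(path, format = "BigWig", which = which)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!region$chrom %in% as.character(unique(GenomicRanges::seqnames(gr)))) {
      abort(sprintf("chromosome '%s' not present in %s", region$chrom, path))
    }
  }
  gr_to_raw_signal(gr, region)
}

clamp_region <- function(region, chrom_len) {
  e <- min(region$end, chrom_len)
  s <- min(region$start, e - 1)
  genomic_region(region$chrom, max(0, s), e)
}

# Project scored intervals (GRanges, 1-based) onto per-base values.
gr_to_raw_signal <- function(gr, region) {
  vals <- numeric(region_length(region))
  keep <- as.character(GenomicRanges::seqnames(gr)) == region$chrom
  gr <- gr[keep]
  if (length(gr) > 0L) {
    s0 <- GenomicRanges::start(gr) - 1L # back to 0-based
    e0 <- GenomicRanges::end(gr)        # exclusive
    sc <- S4Vectors::mcols(gr)$score
    for (i in seq_along(gr)) {
      a <- max(s0[i], region$start)
      b <- min(e0[i], region$end)
      if (a < b) vals[(a - region$start + 1L):(b - region$start)] <- sc[i]
    }
  }
  raw_signal(region, vals)
}

#' Write a raw signal as bedGraph
#'
#' Adjacent equal-valued runs are collapsed into single intervals so
#' simulated fixtures round-trip through the same reader as real tracks.
#'
#' @param raw A [raw_signal()].
#' @param path Output path.
#' @param append Append to an existing file (for multi-region tracks).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(raw, path, append = FALSE) {
  stopifnot(inherits(raw, "raw_signal"))
  r <- rle(raw$values)
  ends <- raw$region$start + cumsum(r$lengths)
  starts <- c(raw$region$start, head(ends, -1))
  df <- data.frame(chrom = raw$region$chrom, start = starts, end = ends,
                   value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = append)
  invisible(path)
}

#' @describeIn bin_signal Tidy per-bin view of a binned signal.
#' @param x A `binned_signal`.
#' @param ... Unused.
#' @export
tidy.binned_signal <- function(x, ...) {
  n <- length(x$values)
  tibble::tibble(
    bin = seq_len(n),
    start = x$region$start + (seq_len(n) - 1L) * x$bin_size,
    end = pmin(x$region$start + seq_len(n) * x$bin_size, x$region$end),
    value = x$values
  )
}
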