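#' Genomic region
#'
#' A half-open genomic interval in BED convention: `start` is 0-based
#' inclusive, `end` is exclusive, so the region covers `end - start` bases.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end Exclusive end (bp); must satisfy `0 <= start < end`.
#'
#' @return A `genomic_region` object.
#' @examples
#' genomic_region("chr1", 9000, 17000)
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, !is.na(chrom))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    abort("invalid genomic region: need 0 <= start < end")
  }
  structure(
    list(chrom = chrom, start = start, end = end),
    class = "genomic_region"
  )
}

#' Length of a genomic region in base pairs
#' @param region A [genomic_region()].
#' @return Integer length `end - start`.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  region$end - region$start
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%d-%d (%d bp)\n",
              x$chrom, x$start, x$end, region_length(x)))
  invisible(x)
}

#' Gene record with strand-aware TSS/TES
#'
#' `tss` and `tes` are genome coordinates of the transcription start and end
#' sites. On the minus strand the TSS has the larger coordinate (`tss > tes`).
#'
#' @param id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes Transcription start / end site (bp, genome coordinates).
#'
#' @return A `gene_record` object.
#' @export
gene_record <- function(id, chrom, strand, tss, tes) {
  strand <- match.arg(strand, c("+", "-"))
  tss <- as.integer(tss)
  tes <- as.integer(tes)
  if (tss == tes) abort("gene_record: tss and tes must differ")
  if (strand == "+" && tss > tes) abort("gene_record: on strand + tss must precede tes")
  if (strand == "-" && tss < tes) abort("gene_record: on strand - tss must follow tes")
  structure(
    list(id = as.character(id), chrom = as.character(chrom),
         strand = strand, tss = tss, tes = tes),
    class = "gene_record"
  )
}

#' Sonification region around a gene
#'
#' Expands a gene body into the interval used for sonification: from
#' `upstream` bp upstream of the TSS to `downstream` bp downstream of the TES,
#' with flanks placed according to strand (on the minus strand "upstream"
#' extends toward higher genome coordinates). The default flanks are 1 kb
#' upstream and 2 kb downstream. The result is clipped at coordinate 0.
#'
#' @param gene A [gene_record()].
#' @param upstream,downstream Non-negative flank sizes in bp.
#'
#' @return A [genomic_region()].
#' @examples
#' g <- gene_record("g1", "chr1", "+", tss = 10000, tes = 15000)
#' region_from_gene(g) # chr1:9000-17000
#' @export
region_from_gene <- function(gene, upstream = 1000, downstream = 2000) {
  stopifnot(inherits(gene, "gene_record"))
  if (upstream < 0 || downstream < 0) abort("flanks must be non-negative")
  if (gene$strand == "+") {
    s <- gene$tss - upstream
    e <- gene$tes + downstream
  } else {
    s <- gene$tes - downstream
    e <- gene$tss + upstream
  }
  s <- max(0, s)
  if (e <= s) abort(sprintf("region for gene '%s' is empty after clipping", gene$id))
  genomic_region(gene$chrom, s, e)
}

#' Read a gene table
#'
#' Reads a tab-separated table with columns `id`, `chrom`, `strand`, `tss`,
#' `tes` and returns one [gene_record()] per row.
#'
#' @param path Path to a TSV file with a header row.
#' @return A list of `gene_record` objects, named by gene id.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df))) {
    abort(sprintf("gene table must have columns: %s", paste(need, collapse = ", ")))
  }
  genes <- purrr::pmap(df[need], function(id, chrom, strand, tss, tes) {
    gene_record(id, chrom, strand, tss, tes)
  })
  setNames(genes, df$id)
}

#' Read regions from a BED file
#'
#' Reads BED (3-6 columns) via rtracklayer and returns a list of
#' [genomic_region()] objects named by the BED name column when present.
#'
#' @param path Path to a BED file.
#' @return A list of `genomic_region` objects.
#' @export
read_bed_regions <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_bed_regions requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  regions <- lapply(seq_along(gr), function(i) {
    genomic_region(as.character(GenomicRanges::seqnames(gr)[i]),
                   GenomicRanges::start(gr)[i] - 1L,
                   GenomicRanges::end(gr)[i])
  })
  nm <- gr$name
  if (!is.null(nm)) names(regions) <- nm
  regions
}
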