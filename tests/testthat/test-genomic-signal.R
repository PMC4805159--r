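test_that("region_from_gene places flanks by strand and clips at zero", {
  plus <- gene_record("g+", "chr1", "+", tss = 10000, tes = 15000)
  r <- region_from_gene(plus, 1000, 2000)
  expect_equal(c(r$start, r$end), c(9000L, 17000L))

  r0 <- region_from_gene(plus, 0, 0)
  expect_equal(c(r0$start, r0$end), c(10000L, 15000L))

  minus <- gene_record("g-", "chr1", "-", tss = 15000, tes = 10000)
  rm_ <- region_from_gene(minus, 1000, 2000)
  expect_equal(c(rm_$start, rm_$end), c(8000L, 16000L))

  near0 <- gene_record("g0", "chr1", "+", tss = 500, tes = 900)
  expect_equal(region_from_gene(near0, 1000, 0)$start, 0L)

  # unclipped regions have length gene span + flanks
  withr::with_seed(42, {
    for (i in 1:20) {
      tss <- sample(5000:50000, 1)
      span <- sample(100:5000, 1)
      up <- sample(0:2000, 1)
      down <- sample(0:3000, 1)
      g <- gene_record("g", "chr2", "+", tss, tss + span)
      expect_equal(region_length(region_from_gene(g, up, down)), span + up + down)
    }
  })
})

test_that("degenerate gene records and empty regions are rejected", {
  expect_error(gene_record("g", "chr1", "+", 100, 100), "differ")
  expect_error(gene_record("g", "chr1", "-", 100, 200), "strand")
  expect_error(genomic_region("chr1", 200, 200))
  expect_error(genomic_region("chr1", -5, 200))
})

test_that("bin_signal averages within bins and log1p-transforms", {
  r <- genomic_region("chr1", 0, 900)
  expect_equal(bin_signal(raw_signal(r, rep(0, 900)), 300)$values, c(0, 0, 0))

  r2 <- genomic_region("chr1", 0, 600)
  expect_equal(bin_signal(raw_signal(r2, rep(exp(1) - 1, 600)), 300)$values, c(1, 1))

  stepped <- raw_signal(r2, c(rep(0, 300), rep(10, 300)))
  expect_equal(bin_signal(stepped, 300)$values, c(0, log(11)))

  # partial final bin is averaged over its own width
  r3 <- genomic_region("chr1", 0, 450)
  part <- bin_signal(raw_signal(r3, c(rep(0, 300), rep(3, 150))), 300)
  expect_equal(part$values, c(0, log1p(3)))

  # bin larger than region collapses to a single bin
  one <- bin_signal(raw_signal(r3, rep(1, 450)), 10000)
  expect_length(one$values, 1)

  # monotone: raising coverage in a bin never lowers its value
  base <- raw_signal(r2, rep(2, 600))
  up <- raw_signal(r2, c(rep(2, 300), rep(5, 300)))
  expect_gte(bin_signal(up, 300)$values[2], bin_signal(base, 300)$values[2])
})

test_that("randomization preserves the value multiset and is seed-deterministic", {
  r <- genomic_region("chr1", 0, 3000)
  raw <- simulate_coverage(r, simulation_config(seed = 5),
                           list(peak_spec(1500, 400, 10)))
  shuf <- randomize_base_level(raw, 7)
  expect_equal(sort(shuf$values), sort(raw$values))
  expect_identical(randomize_base_level(raw, 7)$values, shuf$values)

  const <- raw_signal(r, rep(2, 3000))
  expect_identical(randomize_base_level(const, 3)$values, const$values)

  b <- bin_signal(raw, 300)
  bs <- randomize_bin_level(b, 11)
  expect_equal(sort(bs$values), sort(b$values))
  expect_identical(randomize_bin_level(b, 11)$values, bs$values)
  single <- binned_signal(genomic_region("chr1", 0, 100), 100L, 1.5)
  expect_identical(randomize_bin_level(single, 1)$values, 1.5)
})

test_that("base-level shuffling concentrates bin means for peaked signals", {
  r <- genomic_region("chr1", 0, 3000)
  for (seed in 1:20) {
    raw <- simulate_coverage(r, simulation_config(5, Inf, seed),
                             list(peak_spec(1500, 300, 10)))
    v_orig <- var(bin_signal(raw, 300)$values)
    v_shuf <- var(bin_signal(randomize_base_level(raw, seed + 100), 300)$values)
    expect_lt(v_shuf, v_orig)
  }
})

test_that("bedGraph tracks round-trip through the coverage reader", {
  r <- genomic_region("chr9", 1000, 4000)
  raw <- simulate_coverage(r, simulation_config(seed = 2),
                           list(peak_spec(1500, 300, 6)))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(raw, path)
  back <- read_coverage(path, r)
  expect_equal(back$values, raw$values)

  # sub-region extraction
  sub <- genomic_region("chr9", 1500, 2500)
  expect_equal(read_coverage(path, sub)$values, raw$values[501:1500])

  expect_error(read_coverage(path, genomic_region("chrX", 0, 100)), "chrX")
})

test_that("gene tables read into gene records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tstrand\ttss\ttes",
               "geneA\tchr1\t+\t1000\t5000",
               "geneB\tchr2\t-\t9000\t6000"), path)
  genes <- read_gene_table(path)
  expect_named(genes, c("geneA", "geneB"))
  expect_equal(genes$geneB$strand, "-")
  expect_equal(region_from_gene(genes$geneA)$start, 0L)
})
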