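test_that("build_scale yields the mode's pitch classes and counts", {
  cmaj <- build_scale("C", "major", 4, 1)
  expect_equal(cmaj$pitches %% 12, c(0, 2, 4, 5, 7, 9, 11, 12) %% 12)
  expect_equal(length(cmaj$pitches), 8)

  bmin <- build_scale("B", "minor", 3, 4)
  expect_length(bmin$pitches, 29)
  b_minor_classes <- sort((59 + c(0, 2, 3, 5, 7, 8, 10)) %% 12)
  expect_true(all(sort(unique(bmin$pitches %% 12)) == b_minor_classes))
  expect_equal(bmin$pitches[1], 59) # root B3

  chrom <- build_scale("C", "chromatic", 4, 4)
  expect_length(chrom$pitches, 49)
  expect_equal(diff(chrom$pitches), rep(1L, 48))

  pent <- build_scale("G", "pentatonic", 4, 2)
  expect_length(pent$pitches, 11)

  expect_error(build_scale("C", "dorian", 4, 1), "unknown scale mode")
  expect_true(all(diff(build_scale("A#", "minor", 2, 3)$pitches) > 0))
})

test_that("make_grid builds equal-width edges and rejects degenerate ranges", {
  g <- make_grid(n_levels = 10, lo = 0, hi = 10)
  expect_equal(g$boundaries, 0:10)

  b <- random_binned(20, lo = 0, hi = 1)
  b$values[1] <- 0; b$values[2] <- 1
  g52 <- make_grid(b, n_levels = 52)
  expect_equal(diff(g52$boundaries), rep(1 / 52, 52), tolerance = 1e-12)

  const <- binned_signal(genomic_region("c", 0, 600), 300L, c(2, 2))
  expect_error(make_grid(const), "degenerate")
  expect_silent(make_grid(const, lo = 0, hi = 4))

  # value exactly at hi lands in the top level (right-closed top bin)
  expect_equal(grid_level(10, g), 9L)
  expect_equal(grid_level(0, g), 0L)
  expect_equal(grid_level(9.9999, g), 9L)
})

test_that("quantize maps levels to pitches, merges runs, conserves duration", {
  timing <- timing_params()
  scale <- build_scale("C", "chromatic", 4, 4)
  region <- genomic_region("c", 0, 3000)

  # all values at the grid minimum: one whole-track rest
  b <- binned_signal(region, 300L, rep(0, 10))
  g <- make_grid(n_levels = 30, lo = 0, hi = 3)
  s <- quantize(b, g, scale, timing)
  expect_equal(nrow(s$events), 1)
  expect_equal(s$events$kind, "rest")
  expect_equal(s$events$duration_ticks, 10L * timing$ticks_per_window)

  # two consecutive bins at one level merge into a double-duration note
  b2 <- binned_signal(region, 300L, c(0, 1.55, 1.55, 0, rep(2.9, 6)))
  s2 <- quantize(b2, make_grid(n_levels = 30, lo = 0, hi = 3), scale, timing)
  merged <- s2$events[s2$events$kind == "note", ]
  expect_equal(merged$duration_ticks[1], 2L * timing$ticks_per_window)
  expect_equal(merged$duration_ticks[2], 6L * timing$ticks_per_window)

  # strictly increasing values hitting each level once: ascending, unmerged
  g10 <- make_grid(n_levels = 10, lo = 0, hi = 10)
  vals <- seq(0.5, 9.5, by = 1) # one value per level 0..9
  b3 <- binned_signal(region, 300L, vals)
  s3 <- quantize(b3, g10, scale, timing)
  expect_equal(nrow(s3$events), 10)
  notes <- s3$events[s3$events$kind == "note", ]
  expect_equal(notes$pitch, scale$pitches[1:9])
  # brute-force per-bin mapper agrees before merging
  lev <- grid_level(vals, g10)
  expect_equal(lev, 0:9)

  # empty signal gives an empty sequence (constructed directly: a region
  # always spans at least one bin, so this is a defensive branch)
  b0 <- structure(list(region = region, bin_size = 300L, values = numeric(0)),
                  class = "binned_signal")
  expect_equal(nrow(quantize(b0, g10, scale, timing)$events), 0)

  # grid with more pitch levels than the scale has pitches is rejected
  small <- build_scale("C", "pentatonic", 4, 1)
  expect_error(quantize(b3, make_grid(n_levels = 10, lo = 0, hi = 1), small, timing),
               "pitch levels")
})

test_that("quantized sequences satisfy the sonification invariants", {
  timing <- timing_params()
  modes <- c("chromatic", "major", "minor", "pentatonic")
  withr::with_seed(7, {
    for (i in 1:200) {
      mode <- modes[(i %% 4) + 1]
      scale <- build_scale(sample(c("C", "B", "F#"), 1), mode,
                           base_octave = sample(2:4, 1), n_octaves = 4)
      n_bins <- sample(2:60, 1)
      b <- random_binned(n_bins)
      g <- make_grid(b, n_levels = min(20, length(scale$pitches) + 1))
      s <- quantize(b, g, scale, timing)
      ev <- s$events

      expect_true(all(ev$pitch[ev$kind == "note"] %in% scale$pitches))
      expect_equal(sum(ev$duration_ticks), n_bins * timing$ticks_per_window)
      if (nrow(ev) > 1) {
        same_kind <- ev$kind[-1] == ev$kind[-nrow(ev)]
        same_pitch <- ev$pitch[-1] == ev$pitch[-nrow(ev)]
        expect_false(any(same_kind & (ev$kind[-1] == "rest" | same_pitch), na.rm = TRUE))
      }
      lev <- grid_level(b$values, g)
      o <- order(b$values)
      expect_true(all(diff(lev[o]) >= 0))
    }
  })
})

test_that("tick duration follows MIDI tempo semantics", {
  expect_equal(tick_duration_us(timing_params(1, 60, 1)), 1e6)
  expect_equal(tick_duration_us(timing_params(300, 120, 1)), 60e6 / (300 * 120))
  t1 <- tick_duration_us(timing_params(600, 60))
  t2 <- tick_duration_us(timing_params(600, 120))
  expect_equal(t1 / t2, 2)
  expect_error(timing_params(0, 120, 300))
  expect_error(timing_params(600, -1, 300))
})
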