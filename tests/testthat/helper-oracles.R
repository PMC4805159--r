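# Independent oracles and random-object generators shared across tests.

# Bhattacharyya distance by numerical integration of the Bhattacharyya
# coefficient: B = -log integral sqrt(p(x) q(x)) dx. Supports 1-D (adaptive
# quadrature) and 2-D (trapezoid grid over a box covering both components).
bhattacharyya_numeric <- function(g0, g1, n_grid = 401L) {
  d <- length(g0$mean)
  if (d == 1L) {
    s0 <- sqrt(g0$cov[1, 1])
    s1 <- sqrt(g1$cov[1, 1])
    lo <- min(g0$mean - 10 * s0, g1$mean - 10 * s1)
    hi <- max(g0$mean + 10 * s0, g1$mean + 10 * s1)
    f <- function(x) {
      sqrt(dnorm(x, g0$mean, s0) * dnorm(x, g1$mean, s1))
    }
    -log(integrate(f, lo, hi, rel.tol = 1e-10)$value)
  } else if (d == 2L) {
    s0 <- sqrt(diag(g0$cov))
    s1 <- sqrt(diag(g1$cov))
    lo <- pmin(g0$mean - 9 * s0, g1$mean - 9 * s1)
    hi <- pmax(g0$mean + 9 * s0, g1$mean + 9 * s1)
    xs <- seq(lo[1], hi[1], length.out = n_grid)
    ys <- seq(lo[2], hi[2], length.out = n_grid)
    ldens <- function(g, X) {
      U <- chol(g$cov)
      V <- forwardsolve(t(U), t(X) - g$mean)
      -0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(V^2))
    }
    X <- as.matrix(expand.grid(x = xs, y = ys))
    z <- exp(0.5 * (ldens(g0, X) + ldens(g1, X)))
    zm <- matrix(z, n_grid, n_grid)
    # trapezoid weights in both dimensions
    wx <- rep(1, n_grid); wx[c(1, n_grid)] <- 0.5
    hx <- (hi[1] - lo[1]) / (n_grid - 1)
    hy <- (hi[2] - lo[2]) / (n_grid - 1)
    -log(as.numeric(wx %*% zm %*% wx) * hx * hy)
  } else {
    stop("oracle supports 1-D and 2-D only")
  }
}

# Two-sided Hausdorff of a pairwise distance matrix, written naively.
hausdorff_from_matrix <- function(M) {
  row_min <- numeric(nrow(M))
  col_min <- numeric(ncol(M))
  for (i in seq_len(nrow(M))) row_min[i] <- min(M[i, ])
  for (j in seq_len(ncol(M))) col_min[j] <- min(M[, j])
  max(max(row_min), max(col_min))
}

# Random well-conditioned Gaussian component of dimension d.
random_gaussian <- function(d, mean_scale = 2) {
  mu <- runif(d, -mean_scale, mean_scale)
  A <- matrix(rnorm(d * d), d, d)
  S <- crossprod(A) / d + diag(0.5, d)
  gaussian_component(mu, S)
}

random_gmm <- function(k, d) {
  w <- runif(k)
  gmm_model(replicate(k, random_gaussian(d), simplify = FALSE), w / sum(w))
}

# Random valid note sequence: contiguous events, no two adjacent rests (a
# rest gap is indistinguishable from two adjacent rests in a MIDI file).
random_note_sequence <- function(timing = timing_params()) {
  n <- sample(0:25, 1)
  kinds <- character(n)
  prev_rest <- FALSE
  for (i in seq_len(n)) {
    kinds[i] <- if (prev_rest) "note" else sample(c("note", "rest"), 1, prob = c(0.7, 0.3))
    prev_rest <- kinds[i] == "rest"
  }
  dur <- sample(1:1200, n, replace = TRUE)
  start <- c(0L, head(cumsum(dur), -1L))
  is_note <- kinds == "note"
  ev <- tibble::tibble(
    kind = kinds,
    pitch = as.integer(ifelse(is_note, sample(24:108, n, replace = TRUE), NA_integer_)),
    start_tick = as.integer(start),
    duration_ticks = as.integer(dur),
    velocity = as.integer(ifelse(is_note, sample(1:127, n, replace = TRUE), NA_integer_))
  )
  note_sequence(ev, timing)
}

# Random binned signal over a fresh region.
random_binned <- function(n_bins, lo = 0, hi = 4, bin_size = 300L) {
  region <- genomic_region("chrT", 0, n_bins * bin_size)
  binned_signal(region, bin_size, runif(n_bins, lo, hi))
}

# Dominant frequency of a waveform by FFT argmax.
dominant_frequency <- function(w) {
  n <- length(w$samples)
  spec <- Mod(fft(w$samples))[seq_len(n %/% 2)]
  (which.max(spec) - 1) * w$sample_rate / n
}
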