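test_that("Bhattacharyya closed form matches hand-computed cases", {
  a <- gaussian_component(0, matrix(1))
  b <- gaussian_component(2, matrix(1))
  expect_equal(bhattacharyya(a, b), 0.5)
  expect_equal(bhattacharyya(a, a), 0)

  wide <- gaussian_component(0, matrix(4))
  expect_equal(bhattacharyya(a, wide), 0.5 * log(2.5 / 2))

  # symmetry and non-negativity on random pairs
  withr::with_seed(21, {
    for (i in 1:25) {
      g0 <- random_gaussian(3)
      g1 <- random_gaussian(3)
      b01 <- bhattacharyya(g0, g1)
      expect_equal(b01, bhattacharyya(g1, g0))
      expect_gte(b01, 0)
    }
  })

  expect_error(bhattacharyya(a, gaussian_component(c(0, 0), diag(2))), "dimension")
})

test_that("Bhattacharyya agrees with the numeric-integration oracle", {
  withr::with_seed(33, {
    for (i in 1:10) {
      d <- sample(1:2, 1)
      g0 <- random_gaussian(d)
      g1 <- random_gaussian(d)
      expect_equal(bhattacharyya(g0, g1), bhattacharyya_numeric(g0, g1),
                   tolerance = 1e-5)
    }
  })
})

test_that("Hausdorff-of-matrix logic matches the worked max-min example", {
  M <- rbind(c(0.5, 1.0), c(0.2, 0.7))
  # row minima 0.5, 0.2 -> max 0.5; column minima 0.2, 0.7 -> max 0.7
  expect_equal(hausdorff_from_matrix(M), 0.7)
})

test_that("hausdorff_gmm is symmetric, zero on self, and singleton-exact", {
  withr::with_seed(17, {
    A <- random_gmm(3, 2)
    B <- random_gmm(4, 2)
    expect_equal(hausdorff_gmm(A, A), 0)
    expect_equal(hausdorff_gmm(A, B), hausdorff_gmm(B, A))
    expect_gte(hausdorff_gmm(A, B), 0)

    a <- random_gaussian(2)
    b <- random_gaussian(2)
    sA <- gmm_model(list(a), 1)
    sB <- gmm_model(list(b), 1)
    expect_equal(hausdorff_gmm(sA, sB), bhattacharyya(a, b))
  })
})

test_that("hausdorff_gmm equals brute force over component pairs", {
  withr::with_seed(29, {
    for (i in 1:40) {
      A <- random_gmm(sample(1:4, 1), 2)
      B <- random_gmm(sample(1:4, 1), 2)
      M <- matrix(0, length(A$components), length(B$components))
      for (r in seq_len(nrow(M))) {
        for (s in seq_len(ncol(M))) {
          M[r, s] <- bhattacharyya(A$components[[r]], B$components[[s]])
        }
      }
      expect_equal(hausdorff_gmm(A, B), hausdorff_from_matrix(M))
    }
  })
})

test_that("the D statistic contrasts between- vs within-condition distances", {
  q0 <- quartet_distances(within = c(0.3, 0.3), between = rep(0.3, 4))
  expect_equal(d_statistic(q0), 0)

  q1 <- quartet_distances(within = c(0, 0), between = rep(exp(1) - 1, 4))
  expect_equal(d_statistic(q1), 1)

  q2 <- quartet_distances(within = c(0.1, 0.3), between = c(0.4, 0.6, 0.5, 0.5))
  expect_equal(q2$w_bar, 0.2)
  expect_equal(q2$b_bar, 0.5)
  expect_equal(d_statistic(q2), log(1.5) - log(1.2))

  # monotone: increasing b_bar raises D, increasing w_bar lowers it
  expect_gt(quartet_distances(c(0.1, 0.3), c(0.5, 0.7, 0.6, 0.6))$D, q2$D)
  expect_lt(quartet_distances(c(0.2, 0.4), c(0.4, 0.6, 0.5, 0.5))$D, q2$D)

  expect_error(quartet_distances(c(0.1, -0.2), rep(0.5, 4)), "non-negative")
  expect_error(quartet_distances(0.1, rep(0.5, 4)), "2 within")
})

test_that("AUC follows the rank-based definition with tie handling", {
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(auc_roc(c(0.9, 0.6, 0.8, 0.7), c(1, 1, 0, 0))$auc, 0.5)
  expect_equal(auc_roc(c(1, 1, 2, 2), c(0, 1, 0, 1))$auc, 0.5) # all ties half

  withr::with_seed(41, {
    scores <- rnorm(1000)
    labels <- rbinom(1000, 1, 0.5)
  })
  null_auc <- auc_roc(scores, labels)$auc
  expect_gt(null_auc, 0.45)
  expect_lt(null_auc, 0.55)

  expect_error(auc_roc(c(1, 2), c(1, 1)), "one positive and one negative")
})

test_that("AUC and p-value agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    scores <- c(rnorm(40, 1), rnorm(60, 0))
    labels <- c(rep(1, 40), rep(0, 60))
  })
  ours <- auc_roc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours$auc, ref)
  expect_lt(ours$p_value, 0.05)
})
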