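test_that("the distance matrix is symmetric, zero-diagonal and oracle-exact", {
  withr::with_seed(13, models <- replicate(5, random_gmm(2, 2), simplify = FALSE))
  names(models) <- paste0("locus", 1:5)
  d <- distance_matrix(models)
  expect_equal(d$values, t(d$values))
  expect_equal(diag(d$values), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(d$values[i, j], hausdorff_gmm(models[[i]], models[[j]]))
    }
  }

  # duplicate locus models give a zero off-diagonal entry
  models2 <- c(models, list(locus1b = models[[1]]))
  d2 <- distance_matrix(models2)
  expect_equal(d2$values["locus1", "locus1b"], 0)

  # invariant under relabelling/reordering of loci
  perm <- c(3, 1, 5, 2, 4)
  dp <- distance_matrix(models[perm])
  expect_equal(dp$values, d$values[perm, perm])
})

test_that("Ward clustering handles the trivial cuts and recovers planted blocks", {
  withr::with_seed(19, models <- replicate(6, random_gmm(2, 2), simplify = FALSE))
  d <- distance_matrix(models)
  expect_equal(unique(ward_clusters(d, 1)$cluster), 1L)
  expect_equal(sort(ward_clusters(d, 6)$cluster), 1:6)
  expect_error(ward_clusters(d, 0))
  expect_error(ward_clusters(d, 7))

  for (seed in 1:10) {
    n <- 12
    truth <- rep(1:2, each = n / 2)
    vals <- withr::with_seed(seed, {
      m <- matrix(5, n, n)
      m[truth == 1, truth == 1] <- 0.1
      m[truth == 2, truth == 2] <- 0.1
      m <- m + matrix(runif(n * n, 0, 0.01), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    })
    d2 <- structure(list(labels = paste0("l", 1:n), values = vals),
                    class = "distance_matrix")
    cl <- ward_clusters(d2, 2)
    expect_equal(length(unique(cl$cluster[truth == 1])), 1)
    expect_equal(length(unique(cl$cluster[truth == 2])), 1)
    expect_false(cl$cluster[1] == cl$cluster[n])
  }
})

test_that("cluster expression tests reproduce exact Mann-Whitney p-values", {
  cl <- tibble::tibble(label = paste0("g", 1:6), cluster = rep(1:2, each = 3))
  class(cl) <- c("cluster_assignment", class(cl))

  # complete separation of 3 vs 3: exact two-sided p = 2/20
  sep <- cluster_expression_tests(c(1, 2, 3, 10, 11, 12), cl)
  expect_equal(sep$p_value, 0.1)

  # identical values in both clusters: no evidence, p = 1
  same <- cluster_expression_tests(rep(c(5, 6, 7), 2), cl)
  expect_equal(same$p_value, 1)

  # pair order does not matter
  cl_rev <- cl
  cl_rev$cluster <- 3L - cl$cluster
  sep_rev <- cluster_expression_tests(c(1, 2, 3, 10, 11, 12), cl_rev)
  expect_equal(sep$p_value, sep_rev$p_value)

  expect_error(cluster_expression_tests(1:5, cl), "one expression value")
})

test_that("the pairwise p-value table covers all cluster pairs symmetrically", {
  withr::with_seed(23, {
    expr <- c(rnorm(10, 0), rnorm(10, 3), rnorm(10, 6))
  })
  cl <- tibble::tibble(label = paste0("g", 1:30), cluster = rep(1:3, each = 10))
  class(cl) <- c("cluster_assignment", class(cl))
  tests <- cluster_expression_tests(expr, cl)
  expect_equal(nrow(tests), 3)
  m <- pvalue_matrix(tests)
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  expect_lt(tests$p_value[tests$cluster_a == 1 & tests$cluster_b == 3], 0.001)
})

test_that("distance matrices survive the TSV round trip", {
  withr::with_seed(3, models <- replicate(4, random_gmm(2, 2), simplify = FALSE))
  d <- distance_matrix(models)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  back <- read_distance_matrix(path)
  expect_equal(back$values, d$values, tolerance = 1e-6, ignore_attr = TRUE)
})
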