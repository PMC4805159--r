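#' All-pairs Hausdorff distance matrix across loci
#'
#' Computes `hausdorff_gmm` once per unordered pair of per-locus models; the
#' result is symmetric with a zero diagonal by construction.
#'
#' @param models List of [gmm_model()]s, one per locus; names become locus
#'   labels.
#' @return A `distance_matrix` with fields `labels` and `values` (n x n).
#' @export
distance_matrix <- function(models) {
  n <- length(models)
  if (n < 2L) abort("distance_matrix: need at least two loci")
  labels <- names(models)
  if (is.null(labels)) labels <- paste0("locus_", seq_len(n))
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      values[i, j] <- values[j, i] <- hausdorff_gmm(models[[i]], models[[j]])
    }
  }
  structure(list(labels = labels, values = values), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d loci, distances in [%.4g, %.4g]\n",
              length(x$labels), min(x$values[upper.tri(x$values)]),
              max(x$values)))
  invisible(x)
}

#' @describeIn distance_matrix Long tidy view (one row per unordered pair).
#' @param x A `distance_matrix`.
#' @param ... Unused.
#' @export
tidy.distance_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    locus_a = x$labels[idx[, 1]],
    locus_b = x$labels[idx[, 2]],
    distance = x$values[idx]
  )
}

#' Write / read a distance matrix as TSV
#' @param d A `distance_matrix`.
#' @param path File path.
#' @return `path` (writer) or a `distance_matrix` (reader).
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(inherits(d, "distance_matrix"))
  write.table(d$values, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) abort("distance matrix file must be square")
  storage.mode(m) <- "double"
  m <- (m + t(m)) / 2
  structure(list(labels = rownames(m), values = m), class = "distance_matrix")
}

#' Ward clustering of a distance matrix
#'
#' Agglomerative hierarchical clustering with Ward linkage
#' (`stats::hclust(method = "ward.D2")`) applied directly to the precomputed
#' distance matrix, with the tree cut at `k` clusters. Deterministic.
#'
#' @param d A [distance_matrix()].
#' @param k Number of clusters, `1 <= k <= n` (default 8).
#' @return A `cluster_assignment`: tibble columns `label`, `cluster`
#'   (integers `1..k`, each non-empty), plus the `hclust` tree as attribute
#'   `"tree"`.
#' @export
ward_clusters <- function(d, k = 8) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- length(d$labels)
  k <- as.integer(k)
  if (k < 1L || k > n) abort(sprintf("k must be in 1..%d", n))
  tree <- hclust(as.dist(d$values), method = "ward.D2")
  cl <- cutree(tree, k = k)
  out <- tibble::tibble(label = d$labels, cluster = as.integer(cl))
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "tree") <- tree
  out
}

#' Mann-Whitney tests of expression between clusters
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the expression values
#' of every unordered cluster pair. The exact distribution is used when both
#' groups have at most 8 values and no ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param expr Numeric expression values (e.g. log RPKM), one per locus,
#'   aligned with `assignment` (or named by locus label).
#' @param assignment A [ward_clusters()] assignment.
#' @return A tibble `cluster_a`, `cluster_b`, `p_value` (upper-triangular
#'   pairs, `cluster_a < cluster_b`); `as_matrix = TRUE` attribute-free
#'   symmetric matrix available via [pvalue_matrix()].
#' @export
cluster_expression_tests <- function(expr, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!is.null(names(expr))) expr <- expr[assignment$label]
  if (length(expr) != nrow(assignment)) {
    abort("need one expression value per clustered locus")
  }
  ks <- sort(unique(assignment$cluster))
  if (length(ks) < 2L) abort("need at least two clusters")
  groups <- split(as.double(expr), assignment$cluster)
  if (any(vapply(groups, length, 0L) == 0L)) abort("empty cluster")
  pairs <- utils::combn(ks, 2L)
  p <- apply(pairs, 2L, function(ij) {
    x <- groups[[as.character(ij[1])]]
    y <- groups[[as.character(ij[2])]]
    exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
    suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
  })
  tibble::tibble(cluster_a = pairs[1, ], cluster_b = pairs[2, ], p_value = p)
}

#' Symmetric p-value matrix of pairwise cluster tests
#' @param tests Output of [cluster_expression_tests()].
#' @return A symmetric matrix of p-values with `NA` diagonal.
#' @export
pvalue_matrix <- function(tests) {
  ks <- sort(unique(c(tests$cluster_a, tests$cluster_b)))
  m <- matrix(NA_real_, length(ks), length(ks),
              dimnames = list(paste0("cluster_", ks), paste0("cluster_", ks)))
  for (r in seq_len(nrow(tests))) {
    i <- match(tests$cluster_a[r], ks)
    j <- match(tests$cluster_b[r], ks)
    m[i, j] <- m[j, i] <- tests$p_value[r]
  }
  m
}
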