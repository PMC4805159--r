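log_det_chol <- function(S, what = "covariance") {
  U <- tryCatch(chol(S), error = function(e) {
    abort(sprintf("singular %s while computing Bhattacharyya distance", what))
  })
  list(logdet = 2 * sum(log(diag(U))), chol = U)
}

#' Bhattacharyya distance between two Gaussian components
#'
#' Closed form for multivariate normals: with pooled covariance
#' `P = (S0 + S1) / 2`,
#' `B = 1/8 (m0 - m1)' P^-1 (m0 - m1) + 1/2 log(|P| / sqrt(|S0| |S1|))`.
#' Non-negative, symmetric, and zero iff the components coincide.
#'
#' @param g0,g1 [gaussian_component()] objects of equal dimension.
#' @return The distance (a non-negative scalar).
#' @examples
#' a <- gaussian_component(0, matrix(1))
#' b <- gaussian_component(2, matrix(1))
#' bhattacharyya(a, b) # 0.5
#' @export
bhattacharyya <- function(g0, g1) {
  stopifnot(inherits(g0, "gaussian_component"), inherits(g1, "gaussian_component"))
  if (length(g0$mean) != length(g1$mean)) {
    abort("bhattacharyya: components must have equal dimension")
  }
  P <- (g0$cov + g1$cov) / 2
  p <- log_det_chol(P, "pooled covariance P")
  d <- g0$mean - g1$mean
  v <- forwardsolve(t(p$chol), d)
  mean_term <- sum(v^2) / 8
  cov_term <- 0.5 * (p$logdet -
                       0.5 * (log_det_chol(g0$cov, "covariance of first component")$logdet +
                              log_det_chol(g1$cov, "covariance of second component")$logdet))
  mean_term + cov_term
}

#' Hausdorff distance between two Gaussian mixtures
#'
#' Treats each mixture as the set of its components (weights are ignored, as
#' component sets are unordered) and applies the two-sided Hausdorff distance
#' with the Bhattacharyya distance as ground metric: with
#' `M[i, j] = B(A_i, B_j)`,
#' `H = max(max_i min_j M[i, j], max_j min_i M[i, j])`.
#' Symmetric, non-negative, zero on identical component sets.
#'
#' @param A,B [gmm_model()] objects of equal dimension.
#' @return The distance (a non-negative scalar).
#' @export
hausdorff_gmm <- function(A, B) {
  stopifnot(inherits(A, "gmm_model"), inherits(B, "gmm_model"))
  M <- pairwise_bhattacharyya(A, B)
  max(max(apply(M, 1L, min)), max(apply(M, 2L, min)))
}

# Component-pair Bhattacharyya matrix between two mixtures.
pairwise_bhattacharyya <- function(A, B) {
  na <- length(A$components)
  nb <- length(B$components)
  M <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      M[i, j] <- bhattacharyya(A$components[[i]], B$components[[j]])
    }
  }
  M
}

#' Replicate-aware distances for a 2 x 2 (condition x replicate) design
#'
#' Summarizes the six pairwise track distances of a two-condition,
#' two-replicate quartet: `w_bar` is the mean of the two within-condition
#' (replicate) distances, `b_bar` the mean of the four between-condition
#' distances, and `D = log(1 + b_bar) - log(1 + w_bar)` (natural log). Large
#' positive D means the conditions differ more than replicates do.
#'
#' @param within Length-2 numeric: `H(A1, A2)` and `H(B1, B2)`.
#' @param between Length-4 numeric: all cross-condition pairs
#'   `H(A1, B1), H(A1, B2), H(A2, B1), H(A2, B2)`.
#' @return A `quartet_distances` object with fields `within`, `between`,
#'   `w_bar`, `b_bar`, `D`.
#' @export
quartet_distances <- function(within, between) {
  within <- as.double(within)
  between <- as.double(between)
  if (length(within) != 2L || length(between) != 4L) {
    abort("quartet_distances: need 2 within and 4 between distances")
  }
  if (any(c(within, between) < 0)) abort("distances must be non-negative")
  w_bar <- mean(within)
  b_bar <- mean(between)
  structure(
    list(within = within, between = between, w_bar = w_bar, b_bar = b_bar,
         D = log1p(b_bar) - log1p(w_bar)),
    class = "quartet_distances"
  )
}

#' @export
print.quartet_distances <- function(x, ...) {
  cat(sprintf("<quartet_distances> w_bar = %.4g, b_bar = %.4g, D = %.4g\n",
              x$w_bar, x$b_bar, x$D))
  invisible(x)
}

#' @describeIn quartet_distances One-row tidy summary.
#' @param x A `quartet_distances` object.
#' @param ... Unused.
#' @export
tidy.quartet_distances <- function(x, ...) {
  tibble::tibble(
    within_1 = x$within[1], within_2 = x$within[2],
    between_11 = x$between[1], between_12 = x$between[2],
    between_21 = x$between[3], between_22 = x$between[4],
    w_bar = x$w_bar, b_bar = x$b_bar, D = x$D
  )
}

#' D statistic of a quartet
#'
#' `D = log(1 + b_bar) - log(1 + w_bar)`; positive iff the mean
#' between-condition distance exceeds the mean within-condition distance.
#'
#' @param q A [quartet_distances()] object.
#' @return The D statistic.
#' @export
d_statistic <- function(q) {
  stopifnot(inherits(q, "quartet_distances"))
  q$D
}

#' Compare a quartet of fitted track models
#'
#' @param a1,a2 [gmm_model()]s of the two replicates of condition A.
#' @param b1,b2 [gmm_model()]s of the two replicates of condition B.
#' @return A [quartet_distances()] object.
#' @export
compare_quartet <- function(a1, a2, b1, b2) {
  quartet_distances(
    within = c(hausdorff_gmm(a1, a2), hausdorff_gmm(b1, b2)),
    between = c(hausdorff_gmm(a1, b1), hausdorff_gmm(a1, b2),
                hausdorff_gmm(a2, b1), hausdorff_gmm(a2, b2))
  )
}

#' ROC AUC of scores against binary labels
#'
#' Rank-based AUC: the probability that a randomly chosen positive outranks a
#' randomly chosen negative, with ties counted one half (the Mann-Whitney U
#' form). The p-value tests AUC = 0.5 via the rank-sum normal approximation
#' (two-sided, with tie correction).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, or logical).
#' @return A `roc_result` with fields `auc`, `p_value`, `n_pos`, `n_neg`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) abort("scores and labels must have equal length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("auc_roc: need at least one positive and one negative")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  p <- suppressWarnings(
    wilcox.test(scores[labels == 1L], scores[labels == 0L], exact = FALSE)$p.value
  )
  structure(list(auc = auc, p_value = p, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (p = %.4g; %d positives, %d negatives)\n",
              x$auc, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn auc_roc One-row tidy summary.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_value = x$p_value, n_pos = x$n_pos, n_neg = x$n_neg)
}
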