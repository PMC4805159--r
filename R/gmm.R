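#' Multivariate Gaussian component
#'
#' @param mean Numeric mean vector.
#' @param cov Symmetric positive-definite covariance matrix.
#' @return A `gaussian_component` object.
#' @export
gaussian_component <- function(mean, cov) {
  mean <- as.double(mean)
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || nrow(cov) != length(mean)) {
    abort("gaussian_component: cov must be square with dim matching mean")
  }
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov)))) {
    abort("gaussian_component: cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  if (inherits(try(chol(cov), silent = TRUE), "try-error")) {
    abort("gaussian_component: cov must be positive definite")
  }
  structure(list(mean = mean, cov = cov), class = "gaussian_component")
}

#' Gaussian mixture model
#'
#' @param components List of [gaussian_component()] objects (equal dimension).
#' @param weights Mixing weights; must sum to 1.
#' @param loglik,n_iter,converged Optional fit metadata.
#' @return A `gmm_model` object.
#' @export
gmm_model <- function(components, weights, loglik = NA_real_, n_iter = NA_integer_,
                      converged = NA) {
  if (length(components) < 1L) abort("gmm_model: need at least one component")
  dims <- vapply(components, function(g) length(g$mean), 0L)
  if (length(unique(dims)) != 1L) abort("gmm_model: components must share a dimension")
  weights <- as.double(weights)
  if (length(weights) != length(components) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("gmm_model: weights must be non-negative and sum to 1")
  }
  structure(list(components = components, weights = weights, loglik = loglik,
                 n_iter = n_iter, converged = converged),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> %d components in %d dimensions (loglik %.4g)\n",
              length(x$components), length(x$components[[1]]$mean), x$loglik))
  invisible(x)
}

# Per-row log density of X under N(mu, Sigma) given U = chol(Sigma).
mvn_logdens <- function(X, mu, U) {
  d <- ncol(X)
  V <- forwardsolve(t(U), t(X) - mu)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(V^2))
}

#' Fit a Gaussian mixture to MFCC frames by EM
#'
#' Full-covariance expectation-maximization with k-means initialization and a
#' fixed diagonal regularization of `reg` added to every covariance update.
#' The fit is deterministic for a given seed.
#'
#' @param m An `mfcc_matrix` from [extract_mfcc()], or a plain numeric matrix
#'   of observations (rows) by variables (columns).
#' @param n_components Number of mixture components (10 at this package's
#'   default operating point).
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param reg Diagonal covariance regularization.
#'
#' @return A [gmm_model()].
#' @export
fit_gmm <- function(m, n_components = 10, seed = 1, max_iter = 200,
                    tol = 1e-6, reg = 1e-6) {
  X <- if (inherits(m, "mfcc_matrix")) m$frames else as.matrix(m)
  storage.mode(X) <- "double"
  n <- nrow(X)
  d <- ncol(X)
  k <- as.integer(n_components)
  if (k < 1L) abort("n_components must be >= 1")
  if (n < k) abort(sprintf("cannot fit %d components to %d frames", k, n))

  assign0 <- with_seed(seed, {
    n_distinct <- nrow(unique(X))
    if (n_distinct >= k && k > 1L) {
      tryCatch(kmeans(X, centers = k, nstart = 5L, iter.max = 50L)$cluster,
               error = function(e) sample(rep_len(seq_len(k), n)))
    } else if (k == 1L) {
      rep(1L, n)
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), assign0)] <- 1

  loglik <- -Inf
  comps <- vector("list", k)
  w <- rep(1 / k, k)
  it <- 0L
  converged <- FALSE
  repeat {
    # M-step
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / sum(nk)
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2L, mu)
      S <- crossprod(sqrt(resp[, j]) * Xc) / nk[j] + diag(reg, d)
      U <- chol((S + t(S)) / 2)
      comps[[j]] <- structure(list(mean = mu, cov = (S + t(S)) / 2),
                              class = "gaussian_component")
      logd[, j] <- mvn_logdens(X, mu, U) + log(w[j])
    }
    # E-step
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    it <- it + 1L
    if (is.finite(loglik) && abs(ll - loglik) <= tol * (abs(ll) + 1e-3)) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
    if (it >= max_iter) break
  }
  gmm_model(comps, w, loglik = loglik, n_iter = it, converged = converged)
}

#' @describeIn fit_gmm Tidy per-component summary (weight, mean vector).
#' @param x A `gmm_model`.
#' @param ... Unused.
#' @export
tidy.gmm_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$components),
    weight = x$weights,
    mean = purrr::map(x$components, "mean"),
    cov = purrr::map(x$components, "cov")
  )
}

#' @describeIn fit_gmm One-row fit summary.
#' @export
glance.gmm_model <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$components),
    dim = length(x$components[[1]]$mean),
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
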