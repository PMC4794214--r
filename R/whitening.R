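#' Fit a PCA whitening transform
#'
#' Principal-component whitening of a patch matrix: after centring by the
#' data mean, the `forward` matrix projects a patch onto the top `k`
#' principal axes scaled to unit variance, so the whitened sample
#' covariance is the identity.  `inverse` maps whitened coordinates back to
#' patch space (up to the discarded low-variance subspace).
#'
#' @param x A `patch_matrix` (any stage) or plain numeric matrix, rows =
#'   observations.
#' @param k Number of whitened dimensions to retain, `1 <= k <= rank`.
#' @return An object of class `whitening_transform` with fields
#'   `mean_vector`, `forward` (`k x M`), `inverse` (`M x k`) and
#'   `eigenvalues` (descending).
#' @export
fit_whitening <- function(x, k) {
  X <- if (inherits(x, "patch_matrix")) x$data else as.matrix(x)
  n <- nrow(X)
  if (n <= k) stop("need more observations than retained dimensions")
  if (k < 1) stop("k must be >= 1")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  rank <- sum(ev > max(ev) * 1e-10)
  if (k > rank)
    stop(sprintf("k = %d exceeds the data rank (%d of %d dims)",
                 k, rank, ncol(X)))
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  ev <- ev[seq_len(k)]
  structure(list(mean_vector = mu,
                 forward = t(V) / sqrt(ev),
                 inverse = t(t(V) * sqrt(ev)),
                 eigenvalues = ev),
            class = "whitening_transform")
}

#' @export
print.whitening_transform <- function(x, ...) {
  cat(sprintf("whitening_transform: %d -> %d dims, eigenvalues [%.3g .. %.3g]\n",
              ncol(x$forward), nrow(x$forward),
              x$eigenvalues[1], x$eigenvalues[length(x$eigenvalues)]))
  invisible(x)
}

#' Project a patch matrix into whitened space
#'
#' @param transform A `whitening_transform`.
#' @param x A `patch_matrix` or numeric matrix (rows = patches).
#' @return A `patch_matrix` with stage `"whitened"` and `k` columns.
#' @export
apply_whitening <- function(transform, x) {
  stopifnot(inherits(transform, "whitening_transform"))
  X <- if (inherits(x, "patch_matrix")) x$data else as.matrix(x)
  if (ncol(X) != ncol(transform$forward)) stop("dimension mismatch")
  Z <- sweep(X, 2, transform$mean_vector) %*% t(transform$forward)
  pp <- if (inherits(x, "patch_matrix")) x$patch_px else
    as.integer(sqrt(ncol(X) / 2))
  patch_matrix(Z, pp, stage = "whitened")
}

#' Map whitened-space filters to pixel-space analysis filters
#'
#' For each whitened-space row `w` of `W`, returns the patch-space filter
#' `f = w %*% forward`, so that `f %*% x` equals `w %*% (forward %*% x)`
#' exactly for any patch vector `x`.  (Responses of learned components to a
#' stimulus additionally subtract the filter's response to the training
#' data mean; see [subspace_models()].)
#'
#' @param transform A `whitening_transform`.
#' @param W Matrix of filters in whitened space, one per row (or a vector).
#' @return A matrix of pixel-space filters, one per row.
#' @export
filters_to_pixel_space <- function(transform, W) {
  stopifnot(inherits(transform, "whitening_transform"))
  if (is.vector(W)) W <- matrix(W, nrow = 1)
  if (ncol(W) != nrow(transform$forward))
    stop("filter dimension does not match whitened dimension")
  W %*% transform$forward
}

#' Identity whitening transform
#'
#' A trivial transform (zero mean, identity forward/inverse) useful for
#' building complex-cell models directly from pixel-space filters.
#'
#' @param m Ambient dimension.
#' @return A `whitening_transform`.
#' @export
identity_whitening <- function(m) {
  structure(list(mean_vector = rep(0, m),
                 forward = diag(m), inverse = diag(m),
                 eigenvalues = rep(1, m)),
            class = "whitening_transform")
}
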