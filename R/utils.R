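# Internal numerical helpers shared across modules.

# Wrap angles to [-pi, pi).
wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

# DFT frequencies in cycles per sample for length n (fftfreq convention).
fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# Symmetric orthonormalization of the rows of W: W <- (W W^T)^(-1/2) W.
# Keeps W as close as possible (in Frobenius norm) to the input while
# restoring exact row-orthonormality.
sym_orth <- function(W) {
  E <- W %*% t(W)
  eg <- eigen(E, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("rank-deficient basis; cannot orthonormalize")
  inv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  inv_sqrt %*% W
}

# Deterministic per-stage seed derived from a master seed and a stage name.
# Kept strictly below 2^31 so it is a valid R integer seed.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 10007 + h * 131) %% 2147483629 + 1)
}

# Row-major (reading-order) vectorization of a matrix patch; the on-disk
# contract for patch vectors is row-major within eye, left eye first.
vec_rowmajor <- function(m) as.vector(t(m))

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(TRUE)
}

# Two-sample Kolmogorov-Smirnov distance restricted to values below `cut`.
ks_distance_below <- function(a, b, cut) {
  a <- a[is.finite(a) & a < cut]
  b <- b[is.finite(b) & b < cut]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
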