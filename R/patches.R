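#' Construct a binocular patch matrix
#'
#' An `N x M` matrix of vectorised binocular patches, `M = 2 * patch_px^2`:
#' the left-eye pixels in row-major (reading) order followed by the
#' right-eye pixels.  `stage` records how far along the preprocessing
#' pipeline the rows are.
#'
#' @param data Numeric matrix, one patch per row.
#' @param patch_px Patch side length in pixels.
#' @param stage One of `"raw"`, `"preprocessed"`, `"whitened"`.
#' @param dropped Number of degenerate rows removed by preprocessing.
#' @return An object of class `patch_matrix`.
#' @export
patch_matrix <- function(data, patch_px,
                         stage = c("raw", "preprocessed", "whitened"),
                         dropped = 0L) {
  stage <- match.arg(stage)
  data <- as.matrix(data)
  if (stage != "whitened" && ncol(data) != 2 * patch_px^2)
    stop("data must have 2 * patch_px^2 columns")
  structure(list(data = data, patch_px = as.integer(patch_px),
                 stage = stage, dropped = as.integer(dropped)),
            class = "patch_matrix")
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat(sprintf("patch_matrix: %d patches x %d dims (%d px, stage %s, %d dropped)\n",
              nrow(x$data), ncol(x$data), x$patch_px, x$stage, x$dropped))
  invisible(x)
}

#' Sample binocular patches from stereo pairs
#'
#' Cuts `patch_px x patch_px` patches at uniformly random positions; the
#' left and right patches of a row are taken at the same image coordinates
#' (corresponding retinal locations).  Positions are 0-based with top-left
#' origin.
#'
#' @param pairs A `stereo_pair` or list of them.
#' @param n Number of patches to sample.
#' @param patch_px Patch side length in pixels.
#' @param seed Integer seed for the sampled locations.
#' @return A `patch_matrix` with stage `"raw"`.
#' @export
sample_patches <- function(pairs, n, patch_px = 25, seed = 1L) {
  if (inherits(pairs, "stereo_pair")) pairs <- list(pairs)
  if (length(pairs) == 0) stop("no stereo pairs supplied")
  if (n <= 0) stop("n must be positive")
  for (p in pairs) {
    if (nrow(p$left) < patch_px || ncol(p$left) < patch_px)
      stop("patch_px exceeds an image dimension")
    if (!all(dim(p$left) == dim(p$right)))
      stop("left/right shape mismatch in a stereo pair")
  }
  set.seed(as.integer(seed))
  idx <- sample.int(length(pairs), n, replace = TRUE)
  out <- matrix(0, n, 2 * patch_px^2)
  pp <- patch_px - 1L
  for (i in seq_len(n)) {
    pr <- pairs[[idx[i]]]
    x0 <- sample.int(ncol(pr$left) - pp, 1L) # 1-based column of patch start
    y0 <- sample.int(nrow(pr$left) - pp, 1L)
    rows <- y0:(y0 + pp); cols <- x0:(x0 + pp)
    out[i, ] <- c(vec_rowmajor(pr$left[rows, cols]),
                  vec_rowmajor(pr$right[rows, cols]))
  }
  patch_matrix(out, patch_px, stage = "raw")
}

#' Centre and normalise binocular patches per eye
#'
#' For each row, each eye's half is centred by subtracting its own mean
#' luminance and scaled to unit Euclidean norm; the concatenated vector is
#' then normalised to unit length again, so each half ends up with norm
#' `1/sqrt(2)`.  Rows in which an eye's half has (numerically) zero norm
#' after centring carry no local structure and are dropped; the count is
#' recorded in the result's `dropped` field.
#'
#' @param raw A `patch_matrix` with stage `"raw"`.
#' @return A `patch_matrix` with stage `"preprocessed"`.
#' @export
preprocess_patches <- function(raw) {
  stopifnot(inherits(raw, "patch_matrix"))
  if (raw$stage != "raw") stop("input must have stage 'raw'")
  m <- ncol(raw$data)
  half <- m / 2
  L <- raw$data[, 1:half, drop = FALSE]
  R <- raw$data[, (half + 1):m, drop = FALSE]
  L <- L - rowMeans(L)
  R <- R - rowMeans(R)
  nl <- sqrt(rowSums(L^2))
  nr <- sqrt(rowSums(R^2))
  keep <- nl > 1e-12 & nr > 1e-12
  L <- L[keep, , drop = FALSE] / nl[keep]
  R <- R[keep, , drop = FALSE] / nr[keep]
  X <- cbind(L, R)
  X <- X / sqrt(rowSums(X^2))
  patch_matrix(X, raw$patch_px, stage = "preprocessed",
               dropped = sum(!keep))
}

#' Apply the per-eye centring/normalisation to a single binocular stimulus
#'
#' The same transformation as [preprocess_patches()] but for one stimulus
#' given as two monocular patches.  A half whose contrast is numerically
#' zero is mapped to zeros (it contributes no response).
#'
#' @param left,right `patch_px x patch_px` matrices.
#' @return A length `2 * patch_px^2` preprocessed stimulus vector.
#' @export
preprocess_stimulus <- function(left, right) {
  l <- preprocess_half(vec_rowmajor(left))
  r <- preprocess_half(vec_rowmajor(right))
  v <- c(l, r)
  n <- sqrt(sum(v^2))
  if (n > 1e-12) v / n else v
}

preprocess_half <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n > 1e-12) v / n else v * 0
}
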