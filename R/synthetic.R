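#' Specify a horizontal binocular disparity field
#'
#' Describes the horizontal disparity applied when warping the right eye's
#' view of a synthetic stereo pair.  `constant` produces a single global
#' disparity of `amplitude` pixels; `smooth-random` produces a smooth
#' Gaussian random field with standard deviation `amplitude` pixels and
#' spatial correlation length `correlation_length` pixels, concentrated
#' around zero as expected for natural fixating viewing.
#'
#' @param mode `"constant"` or `"smooth-random"`.
#' @param amplitude Disparity scale in pixels (the constant value, or the
#'   standard deviation of the random field).  Must be `>= 0`.
#' @param correlation_length Correlation length of the smooth field in
#'   pixels.  Must be `> 0`.
#' @param seed Integer seed controlling the random field.
#' @return An object of class `disparity_field_spec`.
#' @seealso [generate_stereo_pair()]
#' @export
disparity_field_spec <- function(mode = c("smooth-random", "constant"),
                                 amplitude = 2, correlation_length = 40,
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0")
  if (!is.finite(correlation_length) || correlation_length <= 0)
    stop("correlation_length must be finite and > 0")
  structure(list(mode = mode, amplitude = amplitude,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "disparity_field_spec")
}

# Occluding-ellipse ("dead leaves") base image: piecewise-constant regions
# with power-law size distribution give sparse, oriented edge structure of
# the kind found in natural scenes (and required for ISA to find localized
# components; a Gaussian texture carries no subspace structure at all).
paint_ellipses <- function(nr, nc, n_elements) {
  img <- matrix(0, nr, nc)
  rmin <- 4
  rmax <- max(nr, nc) / 4
  ex <- -1.5 # CDF exponent for p(r) ~ r^-2.5
  radii <- (rmin^ex + stats::runif(n_elements) * (rmax^ex - rmin^ex))^(1 / ex)
  cx <- stats::runif(n_elements, 1, nc)
  cy <- stats::runif(n_elements, 1, nr)
  ar <- stats::runif(n_elements, 0.4, 1)
  th <- stats::runif(n_elements, 0, pi)
  lev <- stats::runif(n_elements, -1, 1)
  for (k in seq_len(n_elements)) {
    r <- radii[k]
    x0 <- max(1L, floor(cx[k] - r)); x1 <- min(nc, ceiling(cx[k] + r))
    y0 <- max(1L, floor(cy[k] - r)); y1 <- min(nr, ceiling(cy[k] + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - cx[k])
    dy <- outer(ys - cy[k], rep(1, length(xs)))
    u1 <- dx * cos(th[k]) + dy * sin(th[k])
    u2 <- -dx * sin(th[k]) + dy * cos(th[k])
    mask <- (u1 / r)^2 + (u2 / (r * ar[k]))^2 <= 1
    sub <- img[ys, xs]
    sub[mask] <- lev[k]
    img[ys, xs] <- sub
  }
  img
}

# Replace the amplitude spectrum by an exact power law f^slope while keeping
# the phase spectrum (where the localized edge structure lives).
impose_spectrum <- function(img, slope) {
  nr <- nrow(img); nc <- ncol(img)
  F <- stats::fft(img)
  f <- sqrt(outer(fft_freq(nr)^2, fft_freq(nc)^2, "+"))
  amp <- ifelse(f > 0, f^slope, 0)
  mod <- Mod(F)
  phase <- F / ifelse(mod > 0, mod, 1)
  out <- Re(stats::fft(amp * phase, inverse = TRUE)) / (nr * nc)
  out / stats::sd(out)
}

# Smooth zero-mean unit-sd Gaussian random field with correlation length ell.
smooth_random_field <- function(nr, nc, ell) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  f2 <- outer(fft_freq(nr)^2, fft_freq(nc)^2, "+")
  g <- exp(-2 * pi^2 * ell^2 * f2)
  s <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / (nr * nc)
  s / stats::sd(s)
}

# Horizontal warp by a per-pixel disparity: out(x, y) = img(x + d(x, y), y),
# cubic spline interpolation row by row.
warp_horizontal <- function(img, disp) {
  out <- img
  xs <- seq_len(ncol(img))
  for (r in seq_len(nrow(img))) {
    d <- disp[r, ]
    if (all(d == 0)) next
    out[r, ] <- stats::spline(xs, img[r, ], xout = xs + d, method = "fmm")$y
  }
  out
}

#' Generate a synthetic binocular stereo image pair
#'
#' Emulates a calibrated luminance stereo pair: the left view is a
#' naturalistic image (occluding-ellipse structure with an exactly enforced
#' `f^spectral_slope` amplitude spectrum), and the right view is the left
#' view warped horizontally by a disparity field, with vertical disparity
#' fixed at zero.  Positive disparity shifts the right view's content
#' leftward (crossed/near convention).  Independent Gaussian sensor noise
#' (standard deviation `noise * sd(image)`) is added to each view, and a
#' margin wide enough to contain the largest warp displacement is cropped
#' from the horizontal borders so no edge artefacts reach the patches.
#'
#' @param width,height Requested output size in pixels (each `>= 64`).
#' @param field A [disparity_field_spec()].
#' @param spectral_slope Log-log slope of the radial amplitude spectrum;
#'   `-1` matches natural-image statistics.
#' @param seed Integer seed for image content and sensor noise.
#' @param n_elements Number of occluding ellipses in the base image.
#' @param noise Sensor noise as a fraction of image RMS contrast.
#' @param pixel_scale Arc minutes of visual angle per pixel (metadata).
#' @return An object of class `stereo_pair` with elements `left`, `right`
#'   (height x width matrices), `disparity` (the applied field, cropped to
#'   match), and `pixel_scale`.
#' @examples
#' sp <- generate_stereo_pair(96, 96, disparity_field_spec("constant", 0),
#'                            seed = 7, noise = 0)
#' identical(sp$left, sp$right)
#' @export
generate_stereo_pair <- function(width, height,
                                 field = disparity_field_spec(),
                                 spectral_slope = -1, seed = 1L,
                                 n_elements = 400, noise = 0.01,
                                 pixel_scale = 1) {
  if (!is.finite(width) || !is.finite(height) || width < 64 || height < 64)
    stop("width and height must be finite and >= 64")
  for (v in c(spectral_slope, noise, pixel_scale))
    if (!is.finite(v)) stop("non-finite generator parameter")
  if (!inherits(field, "disparity_field_spec"))
    stop("field must be a disparity_field_spec")

  # margin covering the largest possible displacement (smooth fields are
  # clamped to +-3 sd below)
  margin <- ceiling(3 * field$amplitude) + 3
  nc <- width + 2 * margin
  nr <- height

  set.seed(as.integer(seed))
  base <- impose_spectrum(paint_ellipses(nr, nc, n_elements), spectral_slope)

  set.seed(field$seed)
  disp <- switch(field$mode,
    "constant" = matrix(field$amplitude, nr, nc),
    "smooth-random" = {
      d <- smooth_random_field(nr, nc, field$correlation_length) *
        field$amplitude
      pmin(pmax(d, -3 * field$amplitude), 3 * field$amplitude)
    })

  right <- warp_horizontal(base, disp)

  keep <- (margin + 1):(margin + width)
  left <- base[, keep, drop = FALSE]
  right <- right[, keep, drop = FALSE]
  disp <- disp[, keep, drop = FALSE]

  if (noise > 0) {
    set.seed(as.integer((as.numeric(seed) * 7 + 13) %% 2147483629))
    sdn <- noise * stats::sd(left)
    left <- left + matrix(stats::rnorm(length(left), sd = sdn), nr, width)
    right <- right + matrix(stats::rnorm(length(right), sd = sdn), nr, width)
  }
  check_finite(left, "left image")
  check_finite(right, "right image")

  structure(list(left = left, right = right, disparity = disp,
                 pixel_scale = pixel_scale,
                 field = field, seed = as.integer(seed)),
            class = "stereo_pair")
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf("stereo_pair: %d x %d px, %.3g arcmin/px, disparity %s (amplitude %.3g px)\n",
              nrow(x$left), ncol(x$left), x$pixel_scale,
              x$field$mode, x$field$amplitude))
  invisible(x)
}

#' Generate patches from a known ISA generative model
#'
#' Draws sources that follow the ISA generative assumption -- isotropic
#' (Gaussian-profile) within each subspace, heavy-tailed (sparse) subspace
#' norms -- and mixes them through a known random orthonormal component
#' matrix.  Used as a recovery benchmark for [fit_isa()].
#'
#' Within each subspace the source vector is a uniform random direction
#' scaled by an exponentially distributed radius, so subspace norms have
#' positive excess kurtosis while the within-subspace profile is isotropic.
#'
#' @param n_patches Number of patch rows to draw.
#' @param patch_px Nominal patch side; the ambient dimension is
#'   `2 * patch_px^2` (two eyes).
#' @param n_subspaces,subunits_per_subspace Subspace layout; their product
#'   must not exceed the ambient dimension.
#' @param seed Integer seed.
#' @return A list with `patches` (a `patch_matrix`), `components` (the true
#'   orthonormal component matrix, rows in patch space), `subspace_of`
#'   (component-to-subspace map), and `sources` (the latent source matrix).
#' @export
generate_isa_ground_truth_patches <- function(n_patches, patch_px,
                                              n_subspaces,
                                              subunits_per_subspace = 2,
                                              seed = 1L) {
  m <- 2 * patch_px^2
  j <- n_subspaces * subunits_per_subspace
  if (m < j)
    stop(sprintf("infeasible dimensions: 2*patch_px^2 = %d < %d components",
                 m, j))
  if (n_patches < 2) stop("n_patches must be >= 2")
  set.seed(as.integer(seed))
  d <- subunits_per_subspace
  S <- matrix(0, n_patches, j)
  for (s in seq_len(n_subspaces)) {
    g <- matrix(stats::rnorm(n_patches * d), n_patches, d)
    g <- g / sqrt(rowSums(g^2))
    r <- stats::rexp(n_patches)
    S[, (s - 1) * d + seq_len(d)] <- g * r
  }
  W <- t(qr.Q(qr(matrix(stats::rnorm(m * j), m, j)))) # j x m, orthonormal rows
  X <- S %*% W
  list(patches = patch_matrix(X, patch_px, stage = "raw"),
       components = W,
       subspace_of = rep(seq_len(n_subspaces), each = d),
       sources = S)
}

#' Write / read a stereo pair as 16-bit TIFF plus sidecar metadata
#'
#' Each eye is stored as a 16-bit grayscale TIFF after affine rescaling to
#' `[0, 1]`; the rescaling constants, pixel scale and generator provenance
#' go into a plain key-value sidecar file so the pair can be restored in its
#' original luminance units (up to 16-bit quantization).
#'
#' @param pair A `stereo_pair`.
#' @param path Base path; files `<path>_L.tif`, `<path>_R.tif` and
#'   `<path>.meta` are written.
#' @return `path`, invisibly (for `write_stereo_pair`); a `stereo_pair`
#'   (for `read_stereo_pair`).
#' @export
write_stereo_pair <- function(pair, path) {
  stopifnot(inherits(pair, "stereo_pair"))
  lo <- min(pair$left, pair$right)
  hi <- max(pair$left, pair$right)
  if (hi <= lo) hi <- lo + 1
  sc <- function(m) (m - lo) / (hi - lo)
  tiff::writeTIFF(sc(pair$left), paste0(path, "_L.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(sc(pair$right), paste0(path, "_R.tif"),
                  bits.per.sample = 16L)
  meta <- c(sprintf("pixel_scale: %.17g", pair$pixel_scale),
            sprintf("lo: %.17g", lo), sprintf("hi: %.17g", hi),
            sprintf("seed: %d", pair$seed %||% NA_integer_),
            sprintf("field_mode: %s", pair$field$mode),
            sprintf("field_amplitude: %.17g", pair$field$amplitude),
            sprintf("field_correlation_length: %.17g",
                    pair$field$correlation_length),
            sprintf("field_seed: %d", pair$field$seed))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_stereo_pair
#' @export
read_stereo_pair <- function(path) {
  meta_lines <- readLines(paste0(path, ".meta"))
  kv <- strsplit(meta_lines, ":\\s*")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  lo <- as.numeric(meta[["lo"]]); hi <- as.numeric(meta[["hi"]])
  un <- function(m) m * (hi - lo) + lo
  left <- un(tiff::readTIFF(paste0(path, "_L.tif")))
  right <- un(tiff::readTIFF(paste0(path, "_R.tif")))
  if (!all(dim(left) == dim(right)))
    stop(sprintf("left/right shape mismatch for '%s'", path))
  field <- disparity_field_spec(meta[["field_mode"]],
                                as.numeric(meta[["field_amplitude"]]),
                                as.numeric(meta[["field_correlation_length"]]),
                                as.integer(meta[["field_seed"]]))
  structure(list(left = left, right = right, disparity = NULL,
                 pixel_scale = as.numeric(meta[["pixel_scale"]]),
                 field = field, seed = as.integer(meta[["seed"]])),
            class = "stereo_pair")
}

#' Read a directory of stereo image pairs
#'
#' Pairs TIFF or PNG files by matching filename stems with `_L` / `_R`
#' suffixes (e.g. `scene01_L.tif` / `scene01_R.tif`).
#'
#' @param dir Directory to scan.
#' @param pixel_scale Arc minutes per pixel to attach to each pair.
#' @return A list of `stereo_pair` objects.
#' @export
read_stereo_dir <- function(dir, pixel_scale = 1) {
  files <- list.files(dir, pattern = "_L\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no *_L image files found in ", dir)
  read_img <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
    } else {
      img <- tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  lapply(files, function(fl) {
    fr <- sub("_L(\\.[^.]+)$", "_R\\1", fl)
    if (!file.exists(file.path(dir, fr)))
      stop("missing right view for ", fl)
    left <- read_img(file.path(dir, fl))
    right <- read_img(file.path(dir, fr))
    if (!all(dim(left) == dim(right)))
      stop(sprintf("left/right shape mismatch for pair '%s' / '%s'", fl, fr))
    structure(list(left = left, right = right, disparity = NULL,
                   pixel_scale = pixel_scale,
                   field = disparity_field_spec("constant", 0),
                   seed = NA_integer_),
              class = "stereo_pair")
  })
}
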