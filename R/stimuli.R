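#' Sine-grating stimulus patch
#'
#' `g(x, y) = amplitude * sin(2 pi f (x cos th + y sin th) + phase)`,
#' sampled at pixel centers on the same centered coordinate grid used for
#' receptive-field filters; `orientation` is the direction along which the
#' grating varies.
#'
#' @param patch_px Patch side length.
#' @param frequency Spatial frequency in cycles/pixel (`> 0`).
#' @param orientation Direction of variation, radians.
#' @param phase Phase in radians.
#' @param amplitude Peak amplitude.
#' @return A `patch_px x patch_px` matrix.
#' @export
make_grating <- function(patch_px, frequency, orientation, phase,
                         amplitude = 1) {
  if (frequency <= 0) stop("frequency must be > 0")
  cx <- seq_len(patch_px) - (patch_px + 1) / 2
  X <- matrix(cx, patch_px, patch_px, byrow = TRUE)
  Y <- matrix(cx, patch_px, patch_px)
  amplitude * sin(2 * pi * frequency *
                    (X * cos(orientation) + Y * sin(orientation)) + phase)
}

#' Bar stimulus patch
#'
#' A bright bar of width `bar_width` on a zero background, spanning the
#' full patch along its orientation ("infinite" height) and displaced by
#' `shift` pixels orthogonal to the bar from the patch center.  Bar edges
#' are area-sampled (each pixel gets the fraction of its extent covered by
#' the bar), so half-pixel shifts are meaningful.
#'
#' @param patch_px Patch side length.
#' @param bar_width Bar width in pixels (`> 0`).
#' @param orientation Direction orthogonal to the bar (the shift axis),
#'   matching the variation direction of [make_grating()].
#' @param shift Displacement of the bar center along that axis, pixels.
#' @param amplitude Bar luminance.
#' @return A `patch_px x patch_px` matrix.
#' @export
make_bar <- function(patch_px, bar_width, orientation, shift,
                     amplitude = 1) {
  if (bar_width <= 0) stop("bar_width must be > 0")
  cx <- seq_len(patch_px) - (patch_px + 1) / 2
  X <- matrix(cx, patch_px, patch_px, byrow = TRUE)
  Y <- matrix(cx, patch_px, patch_px)
  u <- X * cos(orientation) + Y * sin(orientation)
  lo <- shift - bar_width / 2
  hi <- shift + bar_width / 2
  cover <- pmin(u + 0.5, hi) - pmax(u - 0.5, lo)
  amplitude * pmin(pmax(cover, 0), 1)
}

#' Construct a 2D binocular response map
#'
#' @param values `S x S` matrix of responses, rows indexed by the left-eye
#'   stimulus parameter and columns by the right-eye parameter.
#' @param left_axis,right_axis Strictly increasing parameter grids.
#' @param stimulus_kind `"grating"` (axes are phases) or `"bar"` (shifts).
#' @param model_id Identifier of the probed model.
#' @return An object of class `response_map`.
#' @export
response_map <- function(values, left_axis, right_axis,
                         stimulus_kind = c("grating", "bar"),
                         model_id = NA) {
  stimulus_kind <- match.arg(stimulus_kind)
  values <- as.matrix(values)
  if (nrow(values) != length(left_axis) ||
      ncol(values) != length(right_axis))
    stop("axis lengths do not match the value matrix")
  if (any(!is.finite(values)) || any(values < -1e-9))
    stop("response values must be finite and non-negative")
  if (any(diff(left_axis) <= 0) || any(diff(right_axis) <= 0))
    stop("axes must be strictly increasing")
  structure(list(values = values, left_axis = left_axis,
                 right_axis = right_axis, stimulus_kind = stimulus_kind,
                 model_id = model_id),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("response_map (%s): %d x %d, max %.4g (model %s)\n",
              x$stimulus_kind, nrow(x$values), ncol(x$values),
              max(x$values), x$model_id))
  invisible(x)
}

# Shared fast path for binocular maps.  Stimulus preprocessing (per-eye
# centring and normalisation, then joint normalisation) acts on each eye
# independently up to the joint norm, which is sqrt(2) when both halves
# carry contrast and 1 when only one does, so per-subunit responses
# separate into a left part plus a right part and each map is an outer sum.
binocular_map <- function(model, left_stims, right_stims, axis,
                          stimulus_kind, model_id) {
  p <- model$patch_px
  half <- p^2
  prep_half_set <- function(stims) {
    H <- t(vapply(stims, function(m) preprocess_half(vec_rowmajor(m)),
                  numeric(half)))
    list(H = H, ok = rowSums(H^2) > 0.5) # unit norm or exactly zero
  }
  L <- prep_half_set(left_stims)
  R <- prep_half_set(right_stims)
  norm_ij <- sqrt(outer(as.numeric(L$ok), as.numeric(R$ok), "+"))
  norm_ij[norm_ij == 0] <- 1
  FL <- model$filters[, 1:half, drop = FALSE]
  FR <- model$filters[, (half + 1):(2 * half), drop = FALSE]
  PL <- L$H %*% t(FL) # S x J
  PR <- R$H %*% t(FR)
  S <- length(axis)
  acc <- matrix(if (model$rule == "energy") 0 else -Inf, S, S)
  for (k in seq_len(nrow(model$filters))) {
    rk <- outer(PL[, k], PR[, k], "+") / norm_ij - model$bias[k]
    acc <- if (model$rule == "energy") acc + rk^2 else pmax(acc, abs(rk))
  }
  response_map(acc, axis, axis, stimulus_kind, model_id)
}

#' Phase-phase response map to binocular sine gratings
#'
#' Presents a grating of the model's probe frequency and orientation to
#' each eye while varying the two phases independently over `[-pi, pi)`
#' (`n_steps` samples per eye, endpoint excluded since `-pi` and `pi` are
#' the same grating).  Each stimulus passes the standard per-eye
#' centring/normalisation before filtering.  Cells of equal stimulus phase
#' disparity lie on (circular) diagonals; zero disparity is the main
#' diagonal.
#'
#' @param model A `complex_cell`.
#' @param probe_params List with `frequency` and `orientation`; defaults
#'   to the model's own `probe_params`.
#' @param n_steps Samples per phase axis.
#' @return A `response_map` with `stimulus_kind = "grating"`.
#' @export
phase_phase_map <- function(model, probe_params = NULL, n_steps = 100) {
  stopifnot(inherits(model, "complex_cell"))
  pp <- probe_params %||% model$probe_params
  if (is.null(pp)) stop("no probe parameters available for this model")
  phases <- -pi + 2 * pi * (seq_len(n_steps) - 1) / n_steps
  stims <- lapply(phases, function(ph)
    make_grating(model$patch_px, pp$frequency, pp$orientation, ph))
  binocular_map(model, stims, stims, phases, "grating",
                model$subspace_id)
}

#' Shift-shift response map to binocular bar stimuli
#'
#' Presents a bar of width half the model's probe wavelength, oriented
#' along the probe orientation, at a grid of left/right shifts orthogonal
#' to the bar.  Equal-disparity stimuli lie on diagonals of the map.
#'
#' @param model A `complex_cell`.
#' @param probe_params List with `wavelength` and `orientation`; defaults
#'   to the model's own `probe_params`.
#' @param shift_min,shift_max Shift range in pixels.
#' @param n_steps Number of shift samples per eye.
#' @return A `response_map` with `stimulus_kind = "bar"`.
#' @export
bar_shift_map <- function(model, probe_params = NULL, shift_min = -12.5,
                          shift_max = 12.5, n_steps = 51) {
  stopifnot(inherits(model, "complex_cell"))
  pp <- probe_params %||% model$probe_params
  if (is.null(pp)) stop("no probe parameters available for this model")
  shifts <- seq(shift_min, shift_max, length.out = n_steps)
  stims <- lapply(shifts, function(s)
    make_bar(model$patch_px, pp$wavelength / 2, pp$orientation, s))
  binocular_map(model, stims, stims, shifts, "bar", model$subspace_id)
}
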