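#' Construct a complex-cell model
#'
#' A complex-cell model pools two or more linear subunits.  Subunit filters
#' live in pixel (patch) space; a response to a preprocessed binocular
#' stimulus `x` is `r_j = <f_j, x> - bias_j`, pooled either by the energy
#' rule `sum_j r_j^2` or the max-pooling rule `max_j |r_j|`.
#'
#' @param filters `J x M` matrix of subunit filters (rows), `M = 2 *
#'   patch_px^2` (left-eye pixels then right-eye pixels, row-major).
#' @param rule `"energy"` or `"maxpool"`.
#' @param bias Per-subunit response offset (defaults to zero); for learned
#'   components this is the filter's response to the training-data mean.
#' @param patch_px Patch side length.
#' @param subspace_id Identifier of the originating ISA subspace.
#' @param probe_params Optional list `(frequency, orientation, wavelength)`
#'   from [model_probe_params()].
#' @return An object of class `complex_cell`.
#' @export
complex_cell <- function(filters, rule = c("energy", "maxpool"),
                         bias = NULL, patch_px = NULL, subspace_id = NA,
                         probe_params = NULL) {
  rule <- match.arg(rule)
  filters <- as.matrix(filters)
  if (nrow(filters) < 2) stop("a complex cell needs at least 2 subunits")
  if (is.null(patch_px)) patch_px <- as.integer(sqrt(ncol(filters) / 2))
  if (2 * patch_px^2 != ncol(filters))
    stop("filter length must equal 2 * patch_px^2")
  if (is.null(bias)) bias <- rep(0, nrow(filters))
  structure(list(filters = filters, bias = bias, rule = rule,
                 patch_px = as.integer(patch_px),
                 subspace_id = subspace_id, probe_params = probe_params),
            class = "complex_cell")
}

#' @export
print.complex_cell <- function(x, ...) {
  cat(sprintf("complex_cell: %d subunits, %d px, rule %s (subspace %s)\n",
              nrow(x$filters), x$patch_px, x$rule, x$subspace_id))
  invisible(x)
}

#' Complex-cell response to a binocular stimulus
#'
#' @param model A `complex_cell`.
#' @param stimulus Preprocessed binocular patch vector (length `M`), e.g.
#'   from [preprocess_stimulus()].
#' @return A non-negative scalar response.
#' @export
complex_response <- function(model, stimulus) {
  stopifnot(inherits(model, "complex_cell"))
  if (length(stimulus) != ncol(model$filters))
    stop("stimulus length does not match filter length")
  r <- drop(model$filters %*% stimulus) - model$bias
  switch(model$rule,
         energy = sum(r^2),
         maxpool = max(abs(r)))
}

#' Build complex-cell models from the subspaces of an ISA model
#'
#' Each ISA subspace becomes one complex-cell model whose subunit filters
#' are the subspace components mapped to pixel space through the whitening
#' transform ([filters_to_pixel_space()]); the per-subunit bias is the
#' filter's response to the training-data mean, so model responses equal
#' the whitened-space responses exactly.
#'
#' @param isa An `isa_model` carrying its `whitening`.
#' @param rule Pooling rule for the resulting cells.
#' @return A list of `complex_cell` objects, one per subspace.
#' @export
subspace_models <- function(isa, rule = c("energy", "maxpool")) {
  stopifnot(inherits(isa, "isa_model"))
  rule <- match.arg(rule)
  if (is.null(isa$whitening))
    stop("isa model must carry its whitening transform")
  F_all <- filters_to_pixel_space(isa$whitening, isa$W)
  bias_all <- drop(F_all %*% isa$whitening$mean_vector)
  patch_px <- as.integer(sqrt(ncol(F_all) / 2))
  lapply(seq_len(isa$n_subspaces), function(s) {
    rows <- which(isa$subspace_of == s)
    complex_cell(F_all[rows, , drop = FALSE], rule = rule,
                 bias = bias_all[rows], patch_px = patch_px,
                 subspace_id = s)
  })
}

#' Binocular energy model response
#'
#' The classic quadrature-pair binocular energy response
#' `(R_L + R_R)^2 + (I_L + I_R)^2`, where `R_e` / `I_e` are the responses
#' of the even / odd (quadrature) Gabor filter for eye `e`.
#'
#' @param R_L,I_L,R_R,I_R Even and odd monocular filter responses.
#' @return The scalar energy response.
#' @export
binocular_energy <- function(R_L, I_L, R_R, I_R) {
  for (v in c(R_L, I_L, R_R, I_R))
    if (!is.finite(v)) stop("inputs must be finite")
  (R_L + R_R)^2 + (I_L + I_R)^2
}

#' Interocular phase difference from quadrature filter responses
#'
#' Recovers `cos(delta phi)`, the cosine of the local binocular phase
#' difference, from the binocular energy response and the two monocular
#' energies (Fleet-style decomposition):
#' `cos(dphi) = (bem - rhoL^2 - rhoR^2) / (2 rhoL rhoR)` with
#' `rho_e^2 = R_e^2 + I_e^2`.  The value is clipped to `[-1, 1]`.
#'
#' @inheritParams binocular_energy
#' @return `cos(delta phi)` in `[-1, 1]`.
#' @export
phase_difference_from_energies <- function(R_L, I_L, R_R, I_R) {
  eL <- R_L^2 + I_L^2
  eR <- R_R^2 + I_R^2
  if (eL <= 0 || eR <= 0)
    stop("phase difference undefined: zero monocular energy")
  bem <- binocular_energy(R_L, I_L, R_R, I_R)
  min(1, max(-1, (bem - eL - eR) / (2 * sqrt(eL * eR))))
}

# 2D Gabor sampled at pixel centers on a patch_px grid with centered
# coordinates; `orientation` is the direction of carrier variation.
gabor_patch <- function(patch_px, frequency, orientation, phase,
                        sigma = patch_px / 6, center = c(0, 0),
                        sigma_orth = sigma, amplitude = 1) {
  cx <- seq_len(patch_px) - (patch_px + 1) / 2
  X <- matrix(cx, patch_px, patch_px, byrow = TRUE)
  Y <- matrix(cx, patch_px, patch_px)
  xd <- X - center[1]
  yd <- Y - center[2]
  u <- xd * cos(orientation) + yd * sin(orientation)
  v <- -xd * sin(orientation) + yd * cos(orientation)
  amplitude * exp(-(u^2 / (2 * sigma^2) + v^2 / (2 * sigma_orth^2))) *
    cos(2 * pi * frequency * u + phase)
}

#' Construct an ideal quadrature-pair disparity detector
#'
#' A fixture complex cell implementing the textbook binocular energy model:
#' both subunits are binocular Gabor filters of equal frequency and
#' orientation; subunit 2 is the quadrature (pi/2 carrier-shifted) partner
#' of subunit 1, and the right-eye halves carry an extra carrier phase
#' offset of `phase_disparity`, so the cell prefers a stimulus phase
#' disparity (right minus left) of `phase_disparity`.
#'
#' @param patch_px Patch side length.
#' @param frequency Carrier frequency, cycles/pixel (wavelength must be at
#'   least 4 px).
#' @param orientation Carrier orientation in radians.
#' @param phase_disparity Preferred interocular phase difference, radians.
#' @param sigma Gaussian envelope width in pixels.
#' @param rule Pooling rule.
#' @return A `complex_cell` with `probe_params` already set.
#' @export
make_ideal_detector <- function(patch_px = 25, frequency = 0.12,
                                orientation = 0, phase_disparity = 0,
                                sigma = patch_px / 6,
                                rule = c("energy", "maxpool")) {
  rule <- match.arg(rule)
  if (1 / frequency < 4) stop("wavelength must be at least 4 px")
  sub <- function(base_phase) {
    l <- gabor_patch(patch_px, frequency, orientation, base_phase, sigma)
    r <- gabor_patch(patch_px, frequency, orientation,
                     base_phase + phase_disparity, sigma)
    v <- c(vec_rowmajor(l), vec_rowmajor(r))
    v / sqrt(sum(v^2))
  }
  complex_cell(rbind(sub(0), sub(pi / 2)), rule = rule,
               patch_px = patch_px, subspace_id = "ideal",
               probe_params = list(frequency = frequency,
                                   orientation = orientation,
                                   wavelength = 1 / frequency))
}

#' Construct a purely monocular fixture cell
#'
#' Like [make_ideal_detector()] but with the right-eye filter halves set to
#' zero; useful as a negative control (no disparity tuning).
#'
#' @inheritParams make_ideal_detector
#' @return A `complex_cell`.
#' @export
make_monocular_detector <- function(patch_px = 25, frequency = 0.12,
                                    orientation = 0, sigma = patch_px / 6,
                                    rule = c("energy", "maxpool")) {
  rule <- match.arg(rule)
  sub <- function(base_phase) {
    l <- gabor_patch(patch_px, frequency, orientation, base_phase, sigma)
    v <- c(vec_rowmajor(l), rep(0, patch_px^2))
    v / sqrt(sum(v^2))
  }
  complex_cell(rbind(sub(0), sub(pi / 2)), rule = rule,
               patch_px = patch_px, subspace_id = "monocular",
               probe_params = list(frequency = frequency,
                                   orientation = orientation,
                                   wavelength = 1 / frequency))
}
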