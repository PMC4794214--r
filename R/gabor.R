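#' Fit a 2D Gabor function to a receptive-field half
#'
#' Least-squares fit of an oriented Gabor (Gaussian envelope times cosine
#' carrier plus offset) to one eye's half of a subunit filter.  The fit is
#' initialized from the discrete Fourier peak of the field (frequency,
#' orientation, phase) and the centroid of the squared field (center and
#' envelope widths), then refined by bounded Levenberg-Marquardt least
#' squares with a small set of restarts, since the Gabor likelihood surface
#' is multimodal in phase and frequency.
#'
#' @param field A `p x p` numeric matrix (one receptive-field half).
#' @param n_restarts Number of perturbed initializations to try.
#' @return An object of class `gabor_fit` with fields `amplitude`,
#'   `center` (x, y in centered pixel coordinates), `sigma_par`,
#'   `sigma_orth` (envelope widths along/orthogonal to the carrier),
#'   `frequency` (cycles/px), `orientation` (radians in `[0, pi)`),
#'   `phase` (radians in `[-pi, pi)`), `offset`, `sse`, `goodness`
#'   (`1 - SSE / sum(field^2)`, in `[0, 1]`) and `degenerate`.
#' @export
fit_gabor <- function(field, n_restarts = 5) {
  field <- as.matrix(field)
  p <- nrow(field)
  stopifnot(ncol(field) == p)
  total <- sum(field^2)
  if (total < 1e-20)
    return(structure(list(degenerate = TRUE, amplitude = NA_real_,
                          center = c(NA_real_, NA_real_),
                          sigma_par = NA_real_, sigma_orth = NA_real_,
                          frequency = NA_real_, orientation = NA_real_,
                          phase = NA_real_, offset = NA_real_,
                          sse = NA_real_, goodness = NA_real_),
                     class = "gabor_fit"))

  cx <- seq_len(p) - (p + 1) / 2
  X <- matrix(cx, p, p, byrow = TRUE)
  Y <- matrix(cx, p, p)

  # --- initialization from the Fourier peak and energy centroid ---
  F <- stats::fft(field)
  A2 <- Mod(F)
  A2[1, 1] <- 0 # ignore DC
  pk <- arrayInd(which.max(A2), dim(A2))
  fy <- fft_freq(p)[pk[1]]
  fx <- fft_freq(p)[pk[2]]
  f0 <- max(sqrt(fx^2 + fy^2), 1 / (2 * p))
  th0 <- atan2(fy, fx) %% pi
  w <- field^2 / total
  x0 <- sum(w * X); y0 <- sum(w * Y)
  u <- (X - x0) * cos(th0) + (Y - y0) * sin(th0)
  v <- -(X - x0) * sin(th0) + (Y - y0) * cos(th0)
  sp0 <- max(sqrt(sum(w * u^2)), 1)
  so0 <- max(sqrt(sum(w * v^2)), 1)
  arg <- 2 * pi * f0 * u
  ph0 <- atan2(-sum(field * sin(arg)), sum(field * cos(arg)))
  a0 <- max(abs(field))

  gab <- function(par) {
    xd <- X - par[2]; yd <- Y - par[3]
    uu <- xd * cos(par[7]) + yd * sin(par[7])
    vv <- -xd * sin(par[7]) + yd * cos(par[7])
    par[1] * exp(-(uu^2 / (2 * par[4]^2) + vv^2 / (2 * par[5]^2))) *
      cos(2 * pi * par[6] * uu + par[8]) + par[9]
  }
  resid_fn <- function(par) as.vector(field - gab(par))
  lower <- c(0, -p / 2, -p / 2, 0.5, 0.5, 1 / (4 * p), -2 * pi, -2 * pi, -Inf)
  upper <- c(Inf, p / 2, p / 2, 2 * p, 2 * p, 0.6, 2 * pi, 2 * pi, Inf)

  starts <- list(c(a0, x0, y0, sp0, so0, f0, th0, ph0, 0))
  tweaks <- list(c(dph = pi / 2, df = 1), c(dph = pi, df = 1),
                 c(dph = -pi / 2, df = 1), c(dph = 0, df = 0.75),
                 c(dph = 0, df = 1.3))
  for (tw in tweaks)
    starts <- c(starts, list(c(a0, x0, y0, sp0, so0,
                               min(max(f0 * tw["df"], lower[6]), upper[6]),
                               th0, ph0 + tw["dph"], 0)))
  starts <- starts[seq_len(min(n_restarts + 1, length(starts)))]

  best <- NULL
  best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (sse < best_sse) {
      best <- fit$par
      best_sse <- sse
    }
  }
  if (is.null(best))
    stop("Gabor fit failed from every initialization")

  # canonical form: amplitude >= 0, orientation in [0, pi)
  a <- best[1]; th <- best[7]; ph <- best[8]
  if (a < 0) { a <- -a; ph <- ph + pi }
  thw <- th %% pi
  if (round((th - thw) / pi) %% 2 != 0) ph <- -ph # odd pi-shift flips carrier axis
  structure(list(degenerate = FALSE, amplitude = a,
                 center = c(best[2], best[3]),
                 sigma_par = best[4], sigma_orth = best[5],
                 frequency = best[6], orientation = thw,
                 phase = wrap_angle(ph), offset = best[9],
                 sse = best_sse,
                 goodness = max(0, min(1, 1 - best_sse / total))),
            class = "gabor_fit")
}

#' @export
print.gabor_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("gabor_fit: degenerate field\n")
  } else {
    cat(sprintf("gabor_fit: f %.3f cyc/px, theta %.1f deg, phase %.2f rad, goodness %.3f\n",
                x$frequency, x$orientation * 180 / pi, x$phase, x$goodness))
  }
  invisible(x)
}

#' Fit Gabors to every receptive-field half of a complex-cell model
#'
#' Splits each subunit filter into its left- and right-eye halves and fits
#' a Gabor to each ([fit_gabor()]).
#'
#' @param model A `complex_cell`.
#' @param n_restarts Passed to [fit_gabor()].
#' @return A list with one element per subunit, each containing `left`,
#'   `right` (`gabor_fit` objects) and `norm_left`, `norm_right` (Euclidean
#'   norms of the corresponding filter halves).
#' @export
fit_model_gabors <- function(model, n_restarts = 5) {
  stopifnot(inherits(model, "complex_cell"))
  p <- model$patch_px
  half <- p^2
  lapply(seq_len(nrow(model$filters)), function(j) {
    v <- model$filters[j, ]
    lh <- matrix(v[1:half], p, p, byrow = TRUE)
    rh <- matrix(v[(half + 1):(2 * half)], p, p, byrow = TRUE)
    list(left = fit_gabor(lh, n_restarts),
         right = fit_gabor(rh, n_restarts),
         norm_left = sqrt(sum(lh^2)), norm_right = sqrt(sum(rh^2)))
  })
}

#' Derive grating probe parameters for a complex-cell model
#'
#' Aggregates the per-half Gabor fits into the parameters of the probe
#' grating: the arithmetic mean of the fitted carrier frequencies and the
#' circular mean (over doubled angles, since orientation is defined modulo
#' pi) of the fitted orientations.  Halves that are degenerate or whose
#' norm is below `mono_threshold` times the subunit's dominant half are
#' effectively monocular and excluded from the means.
#'
#' @param model A `complex_cell`.
#' @param fits Output of [fit_model_gabors()]; computed if missing.
#' @param mono_threshold Relative-norm cutoff for excluding a half.
#' @return A list `(frequency, orientation, wavelength, n_halves)`, or
#'   `NULL` when every half is degenerate (the model cannot be probed).
#' @export
model_probe_params <- function(model, fits = NULL, mono_threshold = 0.1) {
  if (is.null(fits)) fits <- fit_model_gabors(model)
  freqs <- c(); oris <- c()
  for (sub in fits) {
    dominant <- max(sub$norm_left, sub$norm_right)
    if (dominant <= 0) next
    for (eye in c("left", "right")) {
      nrm <- if (eye == "left") sub$norm_left else sub$norm_right
      fit <- sub[[eye]]
      if (nrm < mono_threshold * dominant || fit$degenerate) next
      freqs <- c(freqs, fit$frequency)
      oris <- c(oris, fit$orientation)
    }
  }
  if (length(freqs) == 0) return(NULL)
  frequency <- mean(freqs)
  orientation <- (atan2(mean(sin(2 * oris)), mean(cos(2 * oris))) / 2) %% pi
  list(frequency = frequency, orientation = orientation,
       wavelength = 1 / frequency, n_halves = length(freqs))
}

#' Probe parameters by response-maximizing grid search
#'
#' Alternative to the Gabor-fit means: scans a coarse frequency by
#' orientation grid and picks the combination whose phase-phase response
#' map attains the largest maximum response.
#'
#' @param model A `complex_cell`.
#' @param frequencies,orientations Candidate grids.
#' @param n_steps Phase resolution used during the scan.
#' @return A list `(frequency, orientation, wavelength)`.
#' @export
probe_params_by_search <- function(model,
                                   frequencies = seq(0.04, 0.3, by = 0.02),
                                   orientations = seq(0, pi - pi / 12,
                                                      by = pi / 12),
                                   n_steps = 24) {
  best <- NULL
  best_val <- -Inf
  for (f in frequencies) {
    for (th in orientations) {
      pp <- list(frequency = f, orientation = th, wavelength = 1 / f)
      mp <- phase_phase_map(model, pp, n_steps = n_steps)
      v <- max(mp$values)
      if (v > best_val) {
        best_val <- v
        best <- pp
      }
    }
  }
  best
}
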