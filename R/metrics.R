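#' Disparity tuning curve from a phase-phase map
#'
#' Collapses a grating response map onto stimulus phase disparity
#' `d = right phase - left phase` (circular): every map cell lies on
#' exactly one constant-disparity diagonal, and the tuning response at `d`
#' is the mean over that diagonal's cells.  Averaging over the common-phase
#' direction implements the requirement that an ideal detector's preferred
#' disparity be constant across stimulus positions: a phase-specific model
#' averages towards a flat curve and scores a low DDI.
#'
#' @param map A `response_map` of kind `"grating"` on a uniform phase grid.
#' @return An object of class `disparity_tuning`: `disparities` (ascending,
#'   in `[-pi, pi)`), `responses` (diagonal means) and `n_samples_per_bin`.
#' @export
disparity_tuning <- function(map) {
  stopifnot(inherits(map, "response_map"))
  if (map$stimulus_kind != "grating")
    stop("disparity tuning is defined for grating maps")
  s <- length(map$left_axis)
  dl <- diff(map$left_axis)
  if (max(abs(dl - dl[1])) > 1e-9 ||
      max(abs(map$left_axis - map$right_axis)) > 1e-9)
    stop("phase grid must be uniform and identical on both axes")
  resp <- numeric(s)
  ss_within <- numeric(s)
  disp <- wrap_angle(2 * pi * (seq_len(s) - 1) / s)
  i <- seq_len(s)
  for (k in seq_len(s)) {
    j <- ((i - 1 + (k - 1)) %% s) + 1 # right index = left index + k - 1 (circular)
    cells <- map$values[cbind(i, j)]
    resp[k] <- mean(cells)
    ss_within[k] <- sum((cells - resp[k])^2)
  }
  ord <- order(disp)
  structure(list(disparities = disp[ord], responses = resp[ord],
                 ss_within = ss_within[ord],
                 n_samples_per_bin = s, model_id = map$model_id),
            class = "disparity_tuning")
}

#' Fit a sinusoid to a disparity tuning curve
#'
#' Closed-form least-squares fit of `r(d) = a sin(d + phase) + offset` via
#' the first circular Fourier harmonic on the uniform disparity grid, with
#' `a >= 0` enforced through the phase convention.  Because the grating
#' stimulus is cyclical in phase, a single-period sinusoid is the natural
#' parametric form for the tuning curve.
#'
#' @param tuning A `disparity_tuning` with at least 8 grid points.
#' @return An object of class `sine_fit`: `amplitude`, `phase` (in
#'   `[-pi, pi)`), `offset`, `sse`, `n` (points), `m` (3 parameters) and
#'   `fitted` (the fitted curve on the grid).
#' @export
fit_sine <- function(tuning) {
  stopifnot(inherits(tuning, "disparity_tuning"))
  d <- tuning$disparities
  r <- tuning$responses
  n <- length(d)
  if (n < 8) stop("need at least 8 disparity samples")
  offset <- mean(r)
  bs <- 2 * mean(r * sin(d)) # sin coefficient
  bc <- 2 * mean(r * cos(d)) # cos coefficient
  amplitude <- sqrt(bs^2 + bc^2)
  phase <- if (amplitude > 0) atan2(bc, bs) else 0
  fitted <- offset + amplitude * sin(d + phase)
  structure(list(amplitude = amplitude, phase = wrap_angle(phase),
                 offset = offset, sse = sum((r - fitted)^2),
                 n = n, m = 3L, fitted = fitted),
            class = "sine_fit")
}

#' Disparity Discrimination Index
#'
#' `DDI = (Rmax - Rmin) / ((Rmax - Rmin) + 2 * RMSerror)` in the manner of
#' Prince et al.: `Rmax`/`Rmin` are the extrema of the fitted sinusoid over
#' the disparity grid and `RMSerror = sqrt(SSE / (N - M))` the residual
#' root-mean-square of the sinusoid against the responses it summarises.
#' When the tuning curve was collapsed from a full response map (it then
#' carries per-diagonal within-bin sums of squares), the residual is taken
#' over every map cell, so response variation at constant disparity --
#' phase-specific rather than disparity-driven modulation -- counts as
#' error; this is what makes the index estimate the proportion of response
#' variation explained by disparity, and a phase-sensitive or monocular
#' model scores near 0 even when its collapsed curve happens to be smooth.
#' The index lies in `[0, 1]`.
#'
#' @param tuning A `disparity_tuning`.
#' @param fit The corresponding [fit_sine()] result; computed if missing.
#' @return The DDI in `[0, 1]`.
#' @export
compute_ddi <- function(tuning, fit = NULL) {
  stopifnot(inherits(tuning, "disparity_tuning"))
  if (is.null(fit)) fit <- fit_sine(tuning)
  if (is.null(tuning$ss_within)) {
    sse <- fit$sse
    n <- fit$n
  } else {
    nb <- tuning$n_samples_per_bin
    sse <- nb * fit$sse + sum(tuning$ss_within)
    n <- nb * fit$n
  }
  if (n <= fit$m) stop("DDI undefined: no residual degrees of freedom")
  rng <- max(fit$fitted) - min(fit$fitted)
  # a fitted range at round-off level relative to the response scale is a
  # flat curve, not disparity tuning
  if (rng <= 1e-8 * max(abs(fit$offset), rng)) return(0)
  rms <- sqrt(sse / (n - fit$m))
  rng / (rng + 2 * rms)
}

#' Classify the symmetry of a disparity response function
#'
#' Uses the response phase `psi`: the disparity at which the fitted
#' sinusoid peaks (the phase of the response function written as a cosine,
#' `r(d) = a cos(d - psi) + c`).  An even-symmetric peak at zero disparity
#' (`|psi| <= pi/4`) is Tuned Excitatory, an even-symmetric trough at zero
#' (`|psi| >= 3 pi/4`) is Tuned Inhibitory, and odd-symmetric functions
#' peaking at positive / negative disparity (right phase leading /
#' lagging) are labelled NEAR / FAR.  Models whose DDI falls below
#' `ddi_threshold` are not disparity tuned and stay `UNCLASSIFIED`.
#'
#' @param fit A `sine_fit`.
#' @param ddi The model's DDI.
#' @param ddi_threshold Minimum DDI for assigning a symmetry class.
#' @return A list with `label` (one of `"TE"`, `"TI"`, `"NEAR"`, `"FAR"`,
#'   `"UNCLASSIFIED"`) and `response_phase` (`psi`, in `[-pi, pi)`).
#' @export
classify_symmetry <- function(fit, ddi, ddi_threshold = 0.6) {
  stopifnot(inherits(fit, "sine_fit"))
  psi <- wrap_angle(pi / 2 - fit$phase) # peak location of a*sin(d + phase)
  label <- if (ddi < ddi_threshold) {
    "UNCLASSIFIED"
  } else if (abs(psi) <= pi / 4) {
    "TE"
  } else if (abs(psi) >= 3 * pi / 4) {
    "TI"
  } else if (psi > 0) {
    "NEAR"
  } else {
    "FAR"
  }
  list(label = label, response_phase = psi)
}

#' Characterize the disparity selectivity of a complex-cell model
#'
#' Convenience wrapper running the full probe-and-measure chain for one
#' model: probe parameters (unless supplied), phase-phase map, disparity
#' tuning, sinusoid fit, DDI and symmetry label.
#'
#' @param model A `complex_cell`.
#' @param probe_params Optional probe parameter list.
#' @param n_steps Phase samples per axis.
#' @param ddi_threshold Passed to [classify_symmetry()].
#' @return A list of class `disparity_characterization` (`model_id`,
#'   `rule`, `probe`, `ddi`, `sine`, `symmetry`, `response_phase`), or
#'   `NULL` when the model has no usable probe parameters.
#' @export
characterize_model <- function(model, probe_params = NULL, n_steps = 100,
                               ddi_threshold = 0.6) {
  pp <- probe_params %||% model$probe_params %||% model_probe_params(model)
  if (is.null(pp)) return(NULL)
  map <- phase_phase_map(model, pp, n_steps = n_steps)
  tuning <- disparity_tuning(map)
  fit <- fit_sine(tuning)
  ddi <- compute_ddi(tuning, fit)
  sym <- classify_symmetry(fit, ddi, ddi_threshold)
  structure(list(model_id = model$subspace_id, rule = model$rule,
                 probe = pp, ddi = ddi, sine = fit,
                 symmetry = sym$label, response_phase = sym$response_phase),
            class = "disparity_characterization")
}

#' Bootstrapped histogram of a population statistic
#'
#' Resamples `values` with replacement `n_boot` times and reports, for each
#' histogram bin, the median and the 2.5/97.5 percentiles of the bootstrap
#' bin proportions.
#'
#' @param values Numeric vector (non-empty).
#' @param bin_edges Strictly increasing bin edges covering the values.
#' @param n_boot Number of bootstrap resamples (`>= 2`).
#' @param seed Integer seed.
#' @return A data frame with `bin_lo`, `bin_hi`, `median`, `ci_lo`,
#'   `ci_hi` (proportions).
#' @export
bootstrap_histogram <- function(values, bin_edges, n_boot = 200,
                                seed = 1L) {
  if (length(values) == 0) stop("values must be non-empty")
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be increasing")
  set.seed(as.integer(seed))
  nb <- length(bin_edges) - 1
  props <- matrix(0, n_boot, nb)
  n <- length(values)
  bin_counts <- function(v) {
    idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  }
  for (b in seq_len(n_boot)) {
    v <- values[sample.int(n, n, replace = TRUE)]
    props[b, ] <- bin_counts(v) / n
  }
  data.frame(bin_lo = bin_edges[-(nb + 1)], bin_hi = bin_edges[-1],
             median = apply(props, 2, stats::median),
             ci_lo = apply(props, 2, stats::quantile, 0.025),
             ci_hi = apply(props, 2, stats::quantile, 0.975))
}

#' Population summary of disparity characterizations
#'
#' Summarises a set of per-model characterizations: DDI percentiles and
#' maximum, the fraction of models above the tuning threshold, and -- among
#' models above the threshold -- the TE/TI/NEAR/FAR proportions with
#' bootstrap confidence intervals.
#'
#' @param chars List of `disparity_characterization` objects (one rule).
#' @param ddi_threshold Tuning threshold.
#' @param n_boot Bootstrap resamples for the label-proportion CIs.
#' @param seed Integer seed.
#' @return A list with `n`, `ddi` (vector), `frac_above_threshold`,
#'   `ddi_p95`, `ddi_max`, `labels` (table over tuned models) and
#'   `label_proportions` (data frame with bootstrap CIs; empty when no
#'   model is tuned).
#' @export
population_summary <- function(chars, ddi_threshold = 0.6, n_boot = 200,
                               seed = 1L) {
  chars <- Filter(Negate(is.null), chars)
  if (length(chars) == 0) stop("no characterizations supplied")
  ddi <- vapply(chars, function(ch) ch$ddi, 0)
  labels <- vapply(chars, function(ch) ch$symmetry, "")
  tuned <- ddi >= ddi_threshold
  classes <- c("TE", "TI", "NEAR", "FAR")
  lab_tab <- table(factor(labels[tuned], levels = classes))
  prop_df <- data.frame(label = classes, proportion = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_)
  if (any(tuned)) {
    lt <- labels[tuned]
    prop_df$proportion <- as.numeric(lab_tab) / sum(tuned)
    set.seed(as.integer(seed))
    boot <- matrix(0, n_boot, length(classes))
    for (b in seq_len(n_boot)) {
      v <- lt[sample.int(length(lt), length(lt), replace = TRUE)]
      boot[b, ] <- as.numeric(table(factor(v, levels = classes))) /
        length(lt)
    }
    prop_df$ci_lo <- apply(boot, 2, stats::quantile, 0.025)
    prop_df$ci_hi <- apply(boot, 2, stats::quantile, 0.975)
  }
  list(n = length(chars), ddi = ddi,
       frac_above_threshold = mean(tuned),
       ddi_p95 = as.numeric(stats::quantile(ddi, 0.95)),
       ddi_max = max(ddi),
       labels = lab_tab, label_proportions = prop_df,
       ddi_threshold = ddi_threshold)
}
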