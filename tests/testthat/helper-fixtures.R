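# Shared fixtures: small, deterministic, built in code at test time.

# Ideal quadrature energy detectors at the four canonical phase disparities.
ideal_detector_set <- function(patch_px = 25) {
  list(TE = make_ideal_detector(patch_px, 0.12, 0.4, 0),
       NEAR = make_ideal_detector(patch_px, 0.12, 0.4, pi / 2),
       TI = make_ideal_detector(patch_px, 0.12, 0.4, pi),
       FAR = make_ideal_detector(patch_px, 0.12, 0.4, -pi / 2))
}

# A constructed disparity tuning curve (no within-bin information).
make_tuning <- function(responses, s = length(responses)) {
  d <- sort(wrap_angle_local(2 * pi * (seq_len(s) - 1) / s))
  structure(list(disparities = d, responses = responses,
                 n_samples_per_bin = 1L, model_id = "constructed"),
            class = "disparity_tuning")
}

wrap_angle_local <- function(x) ((x + pi) %% (2 * pi)) - pi

# Uniform disparity grid matching disparity_tuning's convention.
disparity_grid <- function(s) sort(wrap_angle_local(2 * pi * (seq_len(s) - 1) / s))
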