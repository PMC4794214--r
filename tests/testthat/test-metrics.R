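test_that("disparity tuning peaks at the detector's built-in phase disparity", {
  det0 <- make_ideal_detector(25, 0.12, 0.4, 0)
  t0 <- disparity_tuning(phase_phase_map(det0, n_steps = 100))
  expect_equal(t0$disparities[which.max(t0$responses)], 0,
               tolerance = 1e-9)
  det90 <- make_ideal_detector(25, 0.12, 0.4, pi / 2)
  t90 <- disparity_tuning(phase_phase_map(det90, n_steps = 100))
  step <- 2 * pi / 100
  expect_lt(abs(t90$disparities[which.max(t90$responses)] - pi / 2),
            step + 1e-9)
})

test_that("every map cell contributes exactly once to the tuning curve", {
  det <- make_ideal_detector(15, 0.15, 0.2, 0.5)
  mp <- phase_phase_map(det, n_steps = 24)
  tn <- disparity_tuning(mp)
  expect_equal(length(tn$disparities), 24)
  expect_equal(sum(tn$responses) * 24, sum(mp$values), tolerance = 1e-9)
  expect_equal(mean(tn$responses), mean(mp$values), tolerance = 1e-12)
})

test_that("a monocular model has a flat tuning curve", {
  mono <- make_monocular_detector(15, 0.15, 0.5)
  tn <- disparity_tuning(phase_phase_map(mono, n_steps = 40))
  cv <- stats::sd(tn$responses) / mean(tn$responses)
  expect_lt(cv, 1e-6)
})

test_that("the closed-form sinusoid fit is exact on representable curves", {
  d <- disparity_grid(32)
  fit <- fit_sine(make_tuning(2 * sin(d + 0.3) + 5))
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$phase, 0.3, tolerance = 1e-10)
  expect_equal(fit$offset, 5, tolerance = 1e-10)
  expect_lt(fit$sse, 1e-18)
  # constant curve: zero amplitude, zero residual
  cfit <- fit_sine(make_tuning(rep(3, 32)))
  expect_equal(cfit$amplitude, 0)
  expect_equal(cfit$sse, 0)
  # pure second harmonic is orthogonal to the fitted basis
  h2 <- fit_sine(make_tuning(cos(2 * d)))
  expect_lt(h2$amplitude, 1e-10)
  expect_error(fit_sine(make_tuning(rep(1, 4))), "at least 8")
})

test_that("DDI unit oracles: flat 0, noiseless sinusoid 1, constructed residual 2/3", {
  d <- disparity_grid(16)
  flat <- make_tuning(rep(2, 16))
  expect_equal(compute_ddi(flat, fit_sine(flat)), 0)
  clean <- make_tuning(2 + sin(d))
  expect_equal(compute_ddi(clean, fit_sine(clean)), 1, tolerance = 1e-9)
  # residual constructed orthogonal to {1, sin, cos} with
  # sqrt(SSE / (N - 3)) = 0.5 exactly: DDI = 2 / (2 + 2 * 0.5) = 2/3
  k <- sqrt(0.5 * (16 - 3) / 16)
  tn <- make_tuning(2 + sin(d) + k * cos(2 * d))
  fit <- fit_sine(tn)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal(compute_ddi(tn, fit), 2 / 3, tolerance = 1e-10)
})

test_that("adding noise to a tuning curve does not increase expected DDI", {
  d <- disparity_grid(64)
  base <- 2 + sin(d) + 0.4 * cos(2 * d) # DDI < 1 to leave headroom
  base_ddi <- compute_ddi(make_tuning(base))
  for (sd in c(0.1, 0.5, 1)) {
    set.seed(round(100 * sd))
    ddis <- replicate(20, {
      tn <- make_tuning(pmax(base + rnorm(64, sd = sd), 0))
      compute_ddi(tn)
    })
    expect_lte(mean(ddis), base_ddi + 0.02)
  }
})

test_that("symmetry classes follow the response phase and DDI threshold", {
  fake_fit <- function(phase) structure(
    list(amplitude = 1, phase = phase, offset = 2, sse = 0, n = 100L,
         m = 3L, fitted = NULL), class = "sine_fit")
  # peak at 0 (cosine-phase 0): sine phase pi/2
  expect_equal(classify_symmetry(fake_fit(pi / 2), 0.9)$label, "TE")
  # trough at 0: peak at pi
  expect_equal(classify_symmetry(fake_fit(-pi / 2), 0.9)$label, "TI")
  # odd-symmetric, peak at +pi/2 / -pi/2
  expect_equal(classify_symmetry(fake_fit(0), 0.9)$label, "NEAR")
  expect_equal(classify_symmetry(fake_fit(pi), 0.9)$label, "FAR")
  # below threshold: unclassified regardless of phase
  expect_equal(classify_symmetry(fake_fit(pi / 2), 0.3)$label,
               "UNCLASSIFIED")
  expect_equal(classify_symmetry(fake_fit(pi / 2), 0.9)$response_phase, 0)
})

test_that("bootstrap histograms are deterministic with exact edge cases", {
  one_bin <- bootstrap_histogram(rep(0.5, 40), c(0, 1), n_boot = 100,
                                 seed = 3)
  expect_equal(one_bin$median, 1)
  expect_equal(one_bin$ci_hi - one_bin$ci_lo, 0)
  set.seed(1); v <- runif(200)
  a <- bootstrap_histogram(v, seq(0, 1, 0.25), n_boot = 100, seed = 9)
  b <- bootstrap_histogram(v, seq(0, 1, 0.25), n_boot = 100, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_histogram(numeric(0), c(0, 1)), "non-empty")
  expect_error(bootstrap_histogram(1, c(0, 1), n_boot = 1), "n_boot")
})

test_that("bootstrap bin-proportion spread matches the binomial formula", {
  set.seed(10)
  v <- runif(400)
  edges <- c(0, 0.5, 1)
  n_boot <- 400
  props <- replicate(n_boot, {
    r <- v[sample.int(400, 400, replace = TRUE)]
    mean(r < 0.5)
  })
  # oracle for the package's resampling spread at the empirical p
  p_hat <- mean(v < 0.5)
  expected_sd <- sqrt(p_hat * (1 - p_hat) / 400)
  bh <- bootstrap_histogram(v, edges, n_boot = n_boot, seed = 11)
  observed_spread <- (bh$ci_hi[1] - bh$ci_lo[1]) / (2 * 1.96)
  expect_lt(abs(observed_spread - expected_sd) / expected_sd, 0.35)
})

test_that("population summaries count labels and percentiles correctly", {
  mk <- function(ddi, label) structure(
    list(model_id = 1, rule = "energy", ddi = ddi, symmetry = label,
         response_phase = 0), class = "disparity_characterization")
  chars <- list(mk(0.9, "TE"), mk(0.8, "TE"), mk(0.7, "TI"),
                mk(0.2, "UNCLASSIFIED"))
  s <- population_summary(chars, ddi_threshold = 0.6, n_boot = 50,
                          seed = 2)
  expect_equal(s$frac_above_threshold, 0.75)
  props <- s$label_proportions
  expect_equal(props$proportion[props$label == "TE"], 2 / 3)
  expect_equal(props$proportion[props$label == "TI"], 1 / 3)
  expect_equal(sum(props$proportion), 1)
  flat <- population_summary(list(mk(0.5, "UNCLASSIFIED"),
                                  mk(0.5, "UNCLASSIFIED")),
                             n_boot = 10, seed = 1)
  expect_equal(flat$ddi_p95, 0.5)
  expect_equal(flat$ddi_max, 0.5)
})
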