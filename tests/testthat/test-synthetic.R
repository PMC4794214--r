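test_that("zero disparity and zero noise give identical eyes, deterministically", {
  f0 <- disparity_field_spec("constant", 0)
  sp1 <- generate_stereo_pair(96, 96, f0, seed = 7, noise = 0)
  sp2 <- generate_stereo_pair(96, 96, f0, seed = 7, noise = 0)
  expect_identical(sp1$left, sp1$right)
  expect_identical(sp1$left, sp2$left)
  expect_true(all(is.finite(sp1$left)))
  sp3 <- generate_stereo_pair(96, 96, f0, seed = 8, noise = 0)
  expect_false(identical(sp1$left, sp3$left))
})

test_that("a constant disparity field shifts the right view by that many pixels", {
  amp <- 3
  sp <- generate_stereo_pair(256, 128, disparity_field_spec("constant", amp),
                             seed = 5, noise = 0)
  # oracle: full cross-correlation over integer lags
  lags <- -8:8
  xs <- 20:230
  cc <- vapply(lags, function(l)
    stats::cor(as.vector(sp$left[, xs]), as.vector(sp$right[, xs - l])), 0)
  expect_equal(lags[which.max(cc)], amp)
})

test_that("the radial amplitude spectrum follows the requested power law", {
  sp <- generate_stereo_pair(512, 512, disparity_field_spec("constant", 0),
                             spectral_slope = -1, seed = 3, noise = 0)
  img <- sp$left
  amp <- Mod(stats::fft(img))
  fr <- sqrt(outer(stereoisa:::fft_freq(nrow(img))^2,
                   stereoisa:::fft_freq(ncol(img))^2, "+"))
  sel <- fr > 0.01 & fr < 0.4
  slope <- unname(stats::coef(stats::lm(log(amp[sel]) ~ log(fr[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("warping conserves mean luminance within interpolation error", {
  sp <- generate_stereo_pair(256, 256,
                             disparity_field_spec("smooth-random", 2, 40,
                                                  seed = 2),
                             seed = 9, noise = 0)
  scale <- stats::sd(sp$left)
  expect_lt(abs(mean(sp$left) - mean(sp$right)) / scale, 0.01)
  expect_true(all(dim(sp$left) == dim(sp$right)))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_stereo_pair(32, 96), ">= 64")
  expect_error(generate_stereo_pair(96, 96, spectral_slope = NaN),
               "non-finite")
  expect_error(disparity_field_spec("constant", -1), "amplitude")
  expect_error(disparity_field_spec("smooth-random",
                                    correlation_length = 0),
               "correlation_length")
})

test_that("ground-truth ISA sources are isotropic within subspaces with sparse norms", {
  gt <- generate_isa_ground_truth_patches(10000, 6, 2, 2, seed = 21)
  S <- gt$sources
  # within-subspace isotropy: uncorrelated, equal-variance coordinates
  for (s in 1:2) {
    sub <- S[, (s - 1) * 2 + 1:2]
    expect_lt(abs(stats::cor(sub)[1, 2]), 0.05)
    expect_lt(abs(stats::var(sub[, 1]) / stats::var(sub[, 2]) - 1), 0.1)
    norms <- sqrt(rowSums(sub^2))
    excess_kurtosis <- mean(scale(norms)^4) - 3
    expect_gt(excess_kurtosis, 0)
  }
  # mixing matrix has orthonormal rows and X = S W reproduces the patches
  expect_lt(max(abs(gt$components %*% t(gt$components) - diag(4))), 1e-10)
  expect_equal(gt$patches$data, gt$sources %*% gt$components)
})

test_that("ground-truth generation is bit-identical under a fixed seed and rejects infeasible dims", {
  a <- generate_isa_ground_truth_patches(500, 4, 3, 2, seed = 5)
  b <- generate_isa_ground_truth_patches(500, 4, 3, 2, seed = 5)
  expect_identical(a$patches$data, b$patches$data)
  expect_identical(a$components, b$components)
  expect_error(generate_isa_ground_truth_patches(100, 2, 5, 2),
               "infeasible")
})

test_that("stereo pairs round-trip through 16-bit TIFF plus sidecar", {
  sp <- generate_stereo_pair(96, 96,
                             disparity_field_spec("constant", 1, seed = 4),
                             seed = 11)
  base <- file.path(withr::local_tempdir(), "pair01")
  write_stereo_pair(sp, base)
  rt <- read_stereo_pair(base)
  # 16-bit quantization of the [min, max] range
  tol <- (max(sp$left, sp$right) - min(sp$left, sp$right)) / 65535
  expect_lt(max(abs(rt$left - sp$left)), tol)
  expect_lt(max(abs(rt$right - sp$right)), tol)
  expect_equal(rt$pixel_scale, sp$pixel_scale)
  pairs <- read_stereo_dir(dirname(base))
  expect_length(pairs, 1)
  expect_equal(dim(pairs[[1]]$left), dim(sp$left))
})
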