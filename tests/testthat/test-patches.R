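test_that("sampling returns the expected geometry and is reproducible", {
  sp <- generate_stereo_pair(96, 96, disparity_field_spec("constant", 1),
                             seed = 3)
  pm <- sample_patches(sp, 10, patch_px = 25, seed = 1)
  expect_equal(dim(pm$data), c(10, 1250))
  expect_equal(pm$stage, "raw")
  pm2 <- sample_patches(sp, 10, patch_px = 25, seed = 1)
  expect_identical(pm$data, pm2$data)
  pm3 <- sample_patches(sp, 10, patch_px = 25, seed = 2)
  expect_false(identical(pm$data, pm3$data))
  expect_error(sample_patches(sp, 0, 25), "positive")
  expect_error(sample_patches(sp, 5, 200), "exceeds")
})

test_that("patches from a constant image are constant rows", {
  sp <- generate_stereo_pair(96, 96, disparity_field_spec("constant", 0),
                             seed = 3, noise = 0)
  sp$left[] <- 5
  sp$right[] <- 5
  pm <- sample_patches(sp, 4, patch_px = 8, seed = 1)
  expect_true(all(pm$data == 5))
})

test_that("preprocessing centres each eye and fixes row and half norms", {
  sp <- generate_stereo_pair(128, 128,
                             disparity_field_spec("smooth-random", 2,
                                                  seed = 5),
                             seed = 13)
  pm <- preprocess_patches(sample_patches(sp, 200, 12, seed = 2))
  X <- pm$data
  half <- ncol(X) / 2
  expect_equal(unname(sqrt(rowSums(X^2))), rep(1, nrow(X)), tolerance = 1e-10)
  expect_lt(max(abs(sqrt(rowSums(X[, 1:half]^2)) - 1 / sqrt(2))), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(X[, -(1:half)]^2)) - 1 / sqrt(2))), 1e-10)
  expect_lt(max(abs(rowMeans(X[, 1:half]))), 1e-12)
  expect_lt(max(abs(rowMeans(X[, -(1:half)]))), 1e-12)
})

test_that("preprocessing matches an explicit hand computation", {
  # independent step-by-step evaluation of centre / per-eye normalise /
  # joint normalise for one 2x2-pixel binocular row
  left <- c(1, 2, 3, 4)
  right <- c(4, 6, 8, 10)
  lc <- left - sum(left) / 4
  rc <- right - sum(right) / 4
  ln <- lc / sqrt(sum(lc^2))
  rn <- rc / sqrt(sum(rc^2))
  joint <- c(ln, rn)
  expected <- joint / sqrt(sum(joint^2))

  pm <- patch_matrix(rbind(c(left, right)), patch_px = 2, stage = "raw")
  out <- preprocess_patches(pm)
  expect_equal(as.vector(out$data), expected, tolerance = 1e-12)
})

test_that("rows with a zero-contrast eye are dropped and counted", {
  rows <- rbind(c(1, 2, 3, 4, 4, 6, 8, 10),
                c(7, 7, 7, 7, 1, 2, 3, 4)) # constant left half
  pm <- preprocess_patches(patch_matrix(rows, 2, stage = "raw"))
  expect_equal(nrow(pm$data), 1)
  expect_equal(pm$dropped, 1L)
})

test_that("per-row normalisation is idempotent", {
  sp <- generate_stereo_pair(96, 96, disparity_field_spec("constant", 1),
                             seed = 4)
  X <- preprocess_patches(sample_patches(sp, 50, 10, seed = 3))$data
  again <- X / sqrt(rowSums(X^2))
  expect_equal(again, X, tolerance = 1e-14)
})

test_that("whitening solves the 2-D closed-form case", {
  # sample covariance exactly diag(4, 1): eigendecomposition is known
  X <- rbind(c(2 * sqrt(2), 0), c(-2 * sqrt(2), 0),
             c(0, sqrt(2)), c(0, -sqrt(2)))
  wt <- fit_whitening(X, 2)
  expect_equal(wt$eigenvalues, c(4, 1), tolerance = 1e-12)
  Z <- apply_whitening(wt, X)$data
  expect_equal(crossprod(Z) / nrow(Z), diag(2), tolerance = 1e-12)
})

test_that("whitened covariance is the identity and the transform inverts", {
  set.seed(42)
  n <- 4000
  A <- matrix(rnorm(36), 6, 6)
  X <- matrix(rnorm(n * 6), n, 6) %*% A
  wt <- fit_whitening(X, 6)
  Z <- apply_whitening(wt, X)$data
  expect_lt(max(abs(crossprod(Z) / n - diag(6))), 1e-6)
  expect_lt(max(abs(wt$forward %*% wt$inverse - diag(6))), 1e-8)
  expect_true(all(diff(wt$eigenvalues) <= 0))
  # reconstruction with k = full dimension recovers the data
  Xr <- sweep(Z %*% t(wt$inverse), 2, wt$mean_vector, `+`)
  expect_equal(Xr, X, tolerance = 1e-8)
})

test_that("projection onto fewer dimensions reconstructs up to the discarded subspace", {
  set.seed(43)
  X <- matrix(rnorm(500 * 5), 500, 5)
  X[, 5] <- X[, 5] * 0.01
  wt <- fit_whitening(X, 4)
  Z <- apply_whitening(wt, X)$data
  Xr <- sweep(Z %*% t(wt$inverse), 2, wt$mean_vector, `+`)
  resid <- X - Xr
  # residual lies in the discarded (low variance) principal direction
  expect_lt(max(abs(resid %*% wt$inverse)), 1e-8)
})

test_that("requesting more dimensions than the rank is rejected with a rank report", {
  set.seed(44)
  B <- matrix(rnorm(20 * 3), 20, 3)
  X <- B %*% matrix(rnorm(3 * 8), 3, 8) # rank 3 in 8 dims
  expect_error(fit_whitening(X, 5), "rank")
  expect_silent(fit_whitening(X, 3))
})

test_that("pixel-space filters reproduce whitened-space responses exactly", {
  set.seed(45)
  X <- matrix(rnorm(300 * 8), 300, 8)
  wt <- fit_whitening(X, 8)
  W <- matrix(rnorm(3 * 8), 3, 8)
  Fpix <- filters_to_pixel_space(wt, W)
  x <- rnorm(8)
  two_path_gap <- max(abs(Fpix %*% x - W %*% (wt$forward %*% x)))
  expect_lt(two_path_gap, 1e-10)
  # identity whitening leaves filters unchanged; zero maps to zero
  idw <- identity_whitening(8)
  expect_equal(filters_to_pixel_space(idw, W), W)
  expect_equal(as.vector(filters_to_pixel_space(wt, rep(0, 8))), rep(0, 8))
  expect_error(filters_to_pixel_space(wt, matrix(0, 2, 5)), "dimension")
})
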