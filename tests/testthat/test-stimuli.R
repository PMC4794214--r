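test_that("gratings are periodic, zero-mean over whole cycles, and trigonometrically exact", {
  g1 <- make_grating(25, 0.2, 0.3, 1.1)
  g2 <- make_grating(25, 0.2, 0.3, 1.1 + 2 * pi)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_lt(abs(mean(make_grating(25, 0.2, 0, 0.4))), 1e-10) # 5 whole cycles
  # f = 0.25 along x: period 4 px, constant along y
  g <- make_grating(16, 0.25, 0, 0.7)
  cx <- seq_len(16) - 8.5
  expect_equal(g[1, ], sin(2 * pi * 0.25 * cx + 0.7), tolerance = 1e-12)
  expect_equal(g[1, ], g[9, ], tolerance = 1e-12)
  expect_equal(g[, 1], g[, 5], tolerance = 1e-12)
  expect_error(make_grating(16, 0), "frequency")
})

test_that("bars are centered, conserve mass while inside, and vanish outside", {
  b0 <- make_bar(25, 4, 0, 0)
  expect_equal(b0, b0[, 25:1], tolerance = 1e-12) # symmetric about midline
  masses <- vapply(seq(-6, 6, by = 0.5),
                   function(s) sum(make_bar(25, 4, 0, s)), 0)
  expect_lt(diff(range(masses)) / mean(masses), 0.005)
  expect_true(all(make_bar(25, 4, 0, 40) == 0))
  expect_error(make_bar(25, 0, 0, 0), "bar_width")
})

test_that("stimulus normalisation makes responses contrast invariant", {
  det <- make_ideal_detector(15, 0.15, 0.5, 0)
  gl <- make_grating(15, 0.15, 0.5, 0.3)
  gr <- make_grating(15, 0.15, 0.5, -0.4)
  x1 <- preprocess_stimulus(gl, gr)
  x7 <- preprocess_stimulus(7 * gl, 7 * gr)
  expect_equal(x1, x7, tolerance = 1e-12)
  expect_equal(complex_response(det, x1), complex_response(det, x7))
})

test_that("phase-phase maps agree with direct per-stimulus evaluation", {
  # dual route: separable fast path vs preprocess_stimulus + complex_response
  for (rule in c("energy", "maxpool")) {
    det <- make_ideal_detector(15, 0.15, 0.5, pi / 3, rule = rule)
    mp <- phase_phase_map(det, n_steps = 12)
    for (cell in list(c(1, 1), c(3, 9), c(12, 5))) {
      gl <- make_grating(15, 0.15, 0.5, mp$left_axis[cell[1]])
      gr <- make_grating(15, 0.15, 0.5, mp$right_axis[cell[2]])
      direct <- complex_response(det, preprocess_stimulus(gl, gr))
      expect_equal(mp$values[cell[1], cell[2]], direct, tolerance = 1e-10)
    }
  }
})

test_that("the map ridge of an ideal detector tracks its phase disparity", {
  for (dphi in c(0, pi / 2)) {
    det <- make_ideal_detector(25, 0.12, 0.4, dphi)
    mp <- phase_phase_map(det, n_steps = 100)
    step <- diff(mp$left_axis[1:2])
    offsets <- vapply(seq_len(100), function(i) {
      j <- which.max(mp$values[i, ])
      d <- (mp$right_axis[j] - mp$left_axis[i] - dphi + pi) %% (2 * pi) - pi
      abs(d)
    }, 0)
    expect_lt(max(offsets), step + 1e-9)
  }
})

test_that("monocular models yield maps constant along the silent eye's axis", {
  mono <- make_monocular_detector(15, 0.15, 0.5)
  mp <- phase_phase_map(mono, n_steps = 20)
  expect_lt(max(apply(mp$values, 1, function(r) diff(range(r)))),
            1e-10 * max(mp$values))
  bm <- bar_shift_map(mono, shift_min = -6, shift_max = 6, n_steps = 13)
  expect_lt(max(apply(bm$values, 1, function(r) diff(range(r)))),
            1e-9 * max(bm$values))
})

test_that("ideal-detector maps are invariant to a common phase shift of both eyes", {
  # carrier with several cycles under the envelope keeps the quadrature
  # pair clean enough for the sub-percent invariance bound
  det <- make_ideal_detector(25, 0.16, 0.4, 0)
  mp <- phase_phase_map(det, n_steps = 50)
  v <- mp$values
  for (k in c(7, 23)) {
    idx <- ((seq_len(50) - 1 + k) %% 50) + 1
    rolled <- v[idx, idx]
    expect_lt(max(abs(rolled - v)), 0.01 * max(v))
  }
})

test_that("grating maps wrap continuously across the +-pi seam", {
  det <- make_ideal_detector(25, 0.12, 0.4, 0)
  mp <- phase_phase_map(det, n_steps = 60)
  # response at the first grid phase vs a grating evaluated at +pi
  gl <- make_grating(25, 0.12, 0.4, pi)
  gr <- make_grating(25, 0.12, 0.4, mp$right_axis[10])
  direct <- complex_response(det, preprocess_stimulus(gl, gr))
  expect_equal(mp$values[1, 10], direct, tolerance = 1e-10)
})

test_that("bar maps of an ideal detector peak on the diagonal and decay at the border", {
  det <- make_ideal_detector(25, 0.12, 0, 0)
  bm <- bar_shift_map(det)
  expect_equal(dim(bm$values), c(51, 51))
  peak <- arrayInd(which.max(bm$values), dim(bm$values))
  expect_lt(abs(bm$left_axis[peak[1]] - bm$right_axis[peak[2]]), 1.01)
  corners <- bm$values[c(1, 1, 51, 51), c(1, 51, 1, 51)]
  expect_lt(max(corners), 0.1 * max(bm$values))
})

test_that("response map construction validates axes and values", {
  expect_error(response_map(matrix(1, 2, 3), 1:2, 1:2, "grating"), "axis")
  expect_error(response_map(matrix(-1, 2, 2), 1:2, 1:2, "grating"),
               "non-negative")
  expect_error(response_map(matrix(1, 2, 2), c(2, 1), 1:2, "grating"),
               "increasing")
})
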