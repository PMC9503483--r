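test_that("steering phases follow the half-wavelength geometry", {
  expect_equal(steering_delay(0, 1:8), rep(0, 8))
  expect_equal(steering_delay(30, 3), pi)       # pi * 2 * sin(30 deg)
  expect_equal(steering_delay(90, 2), pi)
  # general spacing: quarter-wavelength halves the phase
  expect_equal(steering_delay(30, 3, d = 1.25e-3, lambda = 5e-3), pi / 2)
})

test_that("steering weights are unit-modulus with the documented phases", {
  w0 <- steering_weights(0, 8)
  expect_equal(as.complex(w0), rep(1 + 0i, 8))
  w30 <- steering_weights(30, 8)
  expect_equal(Mod(as.complex(w30)), rep(1, 8))
  # per-element evaluation: phases 0, -pi/2, -pi, ... for theta = 30
  expected <- exp(-1i * pi * (0:7) * sin(pi / 6))
  expect_equal(as.complex(w30), expected, tolerance = 1e-12)
  # conjugate symmetry in the steering angle
  expect_equal(as.complex(steering_weights(-17, 8)),
               Conj(as.complex(steering_weights(17, 8))))
})

test_that("matched beamforming gives the full coherent gain", {
  cfg <- radar_config()
  theta <- 20
  cube <- slow_time_cube(cfg, chest_scene(1.2, theta), duration = 0.5)
  bin <- range_to_bin(1.2, attr(cube, "bin_spacing"))
  bf <- apply_beamforming(cube, steering_weights(theta, 8))
  ratio <- Mod(bf[, bin + 1]) / Mod(unclass(cube)[, bin + 1, 1])
  expect_equal(ratio, rep(8, nrow(bf)), tolerance = 1e-9)
})

test_that("beamforming degenerates correctly at boresight and one channel", {
  cfg <- small_config()
  cube <- slow_time_cube(cfg, chest_scene(1.0, 0), duration = 0.3)
  bf <- apply_beamforming(cube, steering_weights(0, 8))
  plain_sum <- apply(unclass(cube), c(1, 2), sum)
  expect_rel_equal(unclass(bf), plain_sum)

  one <- array(unclass(cube)[, , 1], dim = c(dim(cube)[1], dim(cube)[2], 1))
  id <- apply_beamforming(one, steering_weights(0, 1))
  expect_equal(unclass(id), one[, , 1], ignore_attr = TRUE)
  expect_error(apply_beamforming(cube, steering_weights(0, 4)), "mismatch")
})

test_that("beam_scan equals a brute-force steering loop on a toy cube", {
  set.seed(42)
  toy <- array(complex(real = rnorm(3 * 8 * 4), imaginary = rnorm(3 * 8 * 4)),
               dim = c(3, 8, 4))                       # 3 slices, 8 bins, 4 ch
  angles <- seq(-90, 90, by = 10)
  map <- beam_scan(toy, angles)
  # independent oracle: explicit loops and the weight formula written out
  oracle <- matrix(0, 8, length(angles))
  for (a in seq_along(angles)) {
    w <- exp(-1i * pi * (0:3) * sin(angles[a] * pi / 180))
    for (r in 1:8) {
      p <- 0
      for (s in 1:3) p <- p + Mod(sum(toy[s, r, ] * w))^2
      oracle[r, a] <- sqrt(p / 3)
    }
  }
  expect_rel_equal(unclass(map), oracle, tol = 1e-12)
  expect_equal(attr(map, "angles"), angles)
  expect_error(beam_scan(toy, numeric(0)), "empty")
})

test_that("the range-angle map localizes one and two targets", {
  cfg <- radar_config()
  cube <- slow_time_cube(cfg, static_scene(1.2, 40), duration = 0.25)
  map <- beam_scan(cube)
  idx <- arrayInd(which.max(map), dim(map))
  expect_equal(idx[1] - 1, 31)                          # range bin
  expect_equal(attr(map, "angles")[idx[2]], 40)         # scan angle

  two <- make_scene(0.5, 0, sigma = 0, noise_std = 0,
                    clutter = data.frame(range = c(0.9, 1.5),
                                         amplitude = c(1, 1),
                                         angle = c(-30, 20)))
  map2 <- beam_scan(slow_time_cube(cfg, two, duration = 0.25))
  bs <- attr(map2, "bin_spacing")
  for (tgt in list(c(0.9, -30), c(1.5, 20))) {
    bin <- range_to_bin(tgt[1], bs)
    ai <- which.min(abs(attr(map2, "angles") - tgt[2]))
    # the target cell dominates a window around itself
    local <- map2[bin + 1 + (-2:2), ai + (-3:3)]
    expect_equal(max(local), map2[bin + 1, ai])
  }
  zero <- array(0 + 0i, dim = c(2, 8, 4))
  expect_true(all(beam_scan(zero) == 0))
})

test_that("AoA estimation stays within one scan step", {
  cfg <- radar_config()
  cube <- slow_time_cube(cfg, chest_scene(1.2, 20), duration = 0.25)
  map <- beam_scan(cube)
  expect_lte(abs(estimate_aoa(map) - 20), 2)
  # threshold 1 returns exactly the argmax angle
  idx <- arrayInd(which.max(map), dim(map))
  expect_equal(estimate_aoa(map, threshold = 1),
               attr(map, "angles")[idx[2]])

  # symmetric equal-power pair averages to boresight
  sym <- make_scene(0.5, 0, sigma = 0, noise_std = 0,
                    clutter = data.frame(range = c(1.2, 1.2),
                                         amplitude = c(1, 1),
                                         angle = c(-30, 30)))
  msym <- beam_scan(slow_time_cube(cfg, sym, duration = 0.25))
  expect_equal(estimate_aoa(msym), 0, tolerance = 1e-8)

  zero_map <- structure(matrix(0, 4, 5), angles = seq(-4, 4, by = 2),
                        class = c("range_angle_map", "matrix"))
  expect_error(estimate_aoa(zero_map), "all-zero")
})

test_that("matched steering maximizes output power over the scan grid", {
  cfg <- radar_config()
  for (theta in c(-40, 0, 20)) {
    cube <- slow_time_cube(cfg, chest_scene(1.2, theta), duration = 0.25)
    bin <- range_to_bin(1.2, attr(cube, "bin_spacing"))
    grid <- seq(-90, 90, by = 2)
    p <- vapply(grid, function(a) {
      bf <- apply_beamforming(cube, steering_weights(a, 8))
      mean(Mod(bf[, bin + 1])^2)
    }, numeric(1))
    pm <- mean(Mod(apply_beamforming(cube,
                                     steering_weights(theta, 8))[, bin + 1])^2)
    expect_true(all(pm >= p - 1e-9 * pm))
  }
})

test_that("phase alignment residual is zero when matched, closed-form when not", {
  cfg <- radar_config()
  cube <- slow_time_cube(cfg, chest_scene(1.2, 40), duration = 0.25)
  bin <- range_to_bin(1.2, attr(cube, "bin_spacing"))
  expect_lt(phase_alignment_check(cube, steering_weights(40, 8), bin), 1e-6)

  # steering at 0 leaves the residual ramp pi*(n-1)*sin(40 deg): compare to
  # the closed-form circular standard deviation of those phases
  psi <- pi * (0:7) * sin(40 * pi / 180)
  closed <- sqrt(-2 * log(Mod(mean(exp(1i * psi)))))
  expect_equal(phase_alignment_check(cube, steering_weights(0, 8), bin),
               closed, tolerance = 1e-6)

  one <- array(unclass(cube)[, , 1], dim = c(dim(cube)[1], dim(cube)[2], 1))
  expect_equal(phase_alignment_check(one, steering_weights(0, 1), bin), 0)
})
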