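# small waveform config for fast unit tests: same chirp slope and frame rate
# as the default profile, fewer samples and chirps
small_config <- function(M = 4, n_samples = 64)
  radar_config(M = M, n_samples = n_samples)

# static point scene (no micro-motion to speak of: heartbeat amplitude is
# forced tiny and frequencies irrational so tests that want "static" use
# sigma-only reflectors via clutter instead)
static_scene <- function(range = 1.2, angle = 0, amplitude = 1) {
  make_scene(0.5, 0, sigma = 0, noise_std = 0,
             clutter = data.frame(range = range, amplitude = amplitude,
                                  angle = angle))
}

# default moving-chest scene at a grid point
chest_scene <- function(distance = 1.2, angle = 20, br = 15, hr = 75,
                        noise_std = 0, seed = 1L, ...)
  make_scene(distance, angle,
             motion = chest_motion(f_br = br / 60, f_hr = hr / 60),
             noise_std = noise_std, seed = seed, ...)

expect_rel_equal <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), 1e-300), tol)
}
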