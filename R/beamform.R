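#' Per-element steering phase
#'
#' Phase that element `n_rx` of a uniform linear array must compensate so
#' that a plane wave from azimuth `theta` adds coherently:
#' `(n_rx - 1) * 2*pi*d*sin(theta)/lambda`, which reduces to
#' `pi*(n_rx - 1)*sin(theta)` at half-wavelength spacing.
#'
#' @param theta steering azimuth \[deg\].
#' @param n_rx element index, 1-based (vectorized).
#' @param d element spacing \[m\].
#' @param lambda carrier wavelength \[m\].
#' @return phase \[rad\].
#' @export
steering_delay <- function(theta, n_rx, d = 2.5e-3, lambda = 5e-3) {
  stopifnot(all(n_rx >= 1))
  (n_rx - 1) * 2 * pi * d * sin(theta * pi / 180) / lambda
}

#' Delay-and-sum steering weights
#'
#' Unit-modulus weights `w_n = exp(-1i * steering_delay(theta, n))`.  The
#' simulator writes the arriving-wavefront phase with a plus sign, so these
#' conjugate weights make a matched-angle target sum coherently across the
#' virtual array.
#'
#' @param theta steering azimuth \[deg\].
#' @param n_virt number of virtual channels.
#' @param d,lambda array geometry; defaults give half-wavelength spacing.
#' @return complex vector of class `steering_weights` with attribute `theta`.
#' @export
steering_weights <- function(theta, n_virt = 8, d = 2.5e-3, lambda = 5e-3) {
  stopifnot(n_virt >= 1)
  w <- exp(-1i * steering_delay(theta, seq_len(n_virt), d, lambda))
  structure(w, theta = theta, class = "steering_weights")
}

#' Apply delay-and-sum beamforming to a cube
#'
#' Conjugate-phase weighting and summation across the virtual channels:
#' for every (slice, range bin), `out = sum_n X[.,.,n] * w_n`.  For a
#' noiseless target matched by the steering angle the output magnitude at
#' the target bin is `n_virt` times a single channel's.
#'
#' @param X a `radar_cube` `(M, R, N)`, a `slow_cube` `(frames, R, N)`, or
#'   any 3-d complex array with channels last.
#' @param W a [steering_weights()] vector of length `N`.
#' @return complex matrix `(slices, range bins)` with attributes `theta`,
#'   `bin_spacing` and `times` (when present on `X`).
#' @export
apply_beamforming <- function(X, W) {
  dm <- dim(X)
  if (length(dm) != 3) stop("X must be a 3-d array (slices, bins, channels)")
  if (dm[3] != length(W))
    stop("channel count mismatch: cube has ", dm[3], ", weights ", length(W))
  out <- matrix(matrix(X, ncol = dm[3]) %*% as.complex(W), dm[1], dm[2])
  structure(out, theta = attr(W, "theta"),
            bin_spacing = attr(X, "bin_spacing"), times = attr(X, "times"))
}

#' Beam-scanned range-angle map
#'
#' Steers the array over a grid of azimuths (default -90 to +90 degrees in
#' 2-degree steps) and records, for every range bin, the RMS magnitude of
#' the beamformed signal over slices (chirps or frames).  The map peaks at
#' the (range, angle) cell of a reflector.
#'
#' @param X cube as in [apply_beamforming()].
#' @param angles scan grid \[deg\].
#' @return matrix `(range bins, angles)` of class `range_angle_map` with
#'   attributes `angles` and `bin_spacing`.
#' @export
beam_scan <- function(X, angles = seq(-90, 90, by = 2)) {
  if (length(angles) < 1) stop("empty scan grid")
  dm <- dim(X)
  flat <- matrix(X, ncol = dm[3])
  map <- matrix(0, dm[2], length(angles))
  for (a in seq_along(angles)) {
    w <- steering_weights(angles[a], dm[3])
    bf <- matrix(flat %*% as.complex(w), dm[1], dm[2])
    map[, a] <- sqrt(colMeans(Mod(bf)^2))
  }
  structure(map, angles = angles, bin_spacing = attr(X, "bin_spacing"),
            class = c("range_angle_map", "matrix"))
}

#' Estimate the angle of arrival from a range-angle map
#'
#' Magnitude-weighted mean of the scan angle over all map cells whose
#' magnitude exceeds `threshold` times the map maximum.  The human chest is
#' not a point target, so averaging over the bright region is more stable
#' than the raw argmax; `threshold = 1` degenerates to the argmax angle.
#'
#' @param map a [beam_scan()] result.
#' @param threshold relative magnitude threshold in (0, 1\].
#' @return estimated azimuth \[deg\].
#' @export
estimate_aoa <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "range_angle_map"), threshold > 0, threshold <= 1)
  mx <- max(map)
  if (!(mx > 0)) stop("cannot estimate AoA from an all-zero map")
  keep <- map >= threshold * mx
  ang <- matrix(attr(map, "angles"), nrow(map), ncol(map), byrow = TRUE)
  sum(ang[keep] * map[keep]) / sum(map[keep])
}

#' Residual phase spread after steering
#'
#' Diagnostic for delay-and-sum alignment: the circular standard deviation,
#' across virtual channels, of the phase of each channel's weighted signal
#' at the target range bin (slices combined coherently per channel first).
#' Matched steering on a noiseless scene gives (numerically) zero spread;
#' mismatched steering leaves the residual geometric phase ramp.
#'
#' @param X cube as in [apply_beamforming()].
#' @param W a [steering_weights()] vector.
#' @param bin target range bin (0-based, matching the map convention).
#' @return circular standard deviation \[rad\].
#' @export
phase_alignment_check <- function(X, W, bin) {
  dm <- dim(X)
  stopifnot(length(dm) == 3, dm[3] == length(W))
  if (bin < 0 || bin >= dm[2]) stop("target bin out of range")
  per_ch <- colSums(matrix(X[, bin + 1, ], dm[1], dm[3])) * as.complex(W)
  if (length(per_ch) == 1) return(0)
  phases <- Arg(per_ch)
  Rbar <- Mod(mean(exp(1i * phases)))
  sqrt(pmax(0, -2 * log(Rbar)))
}

#' Range bin of a physical range
#'
#' @param R range \[m\].
#' @param bin_spacing range-bin width \[m\].
#' @return 0-based nearest bin index.
#' @export
range_to_bin <- function(R, bin_spacing) as.integer(round(R / bin_spacing))
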