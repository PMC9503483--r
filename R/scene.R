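#' Chest micro-motion model
#'
#' Radial chest-surface displacement as the sum of a breathing sinusoid and a
#' heartbeat sinusoid.  Real chest motion is neither purely sinusoidal nor
#' harmonic-free; an optional harmonic list lets stress tests add breathing
#' harmonics, but the default is two pure tones so that the ground-truth rates
#' are unambiguous.
#'
#' Default amplitudes (2 mm breathing, 0.3 mm heartbeat) keep the heartbeat
#' phase signature roughly an order of magnitude below breathing, which is the
#' regime that makes heart rate the harder quantity to recover.
#'
#' @param f_br breathing frequency \[Hz\], in (0.05, 1).
#' @param a_br breathing displacement amplitude \[m\].
#' @param f_hr heart frequency \[Hz\], in (0.6, 3).
#' @param a_hr heartbeat displacement amplitude \[m\]; must be below `a_br`.
#' @param phi_br,phi_hr phase offsets \[rad\].
#' @param harmonics optional list of `list(f, a, phi)` extra sinusoids.
#' @return object of class `chest_motion`.
#' @export
chest_motion <- function(f_br = 0.25, a_br = 2e-3, f_hr = 1.25, a_hr = 0.3e-3,
                         phi_br = 0, phi_hr = 0, harmonics = list()) {
  if (!(f_br > 0.05 && f_br < 1))
    stop("f_br must lie in (0.05, 1) Hz")
  if (!(f_hr > 0.6 && f_hr < 3))
    stop("f_hr must lie in (0.6, 3) Hz")
  if (!(a_br > 0) || !(a_hr >= 0))
    stop("amplitudes must be positive")
  if (a_hr >= a_br)
    stop("heartbeat amplitude must be smaller than breathing amplitude")
  m <- list(f_br = f_br, a_br = a_br, f_hr = f_hr, a_hr = a_hr,
            phi_br = phi_br, phi_hr = phi_hr, harmonics = harmonics)
  class(m) <- "chest_motion"
  m
}

#' Evaluate chest displacement
#'
#' @param t time \[s\], vectorized; must be non-negative.
#' @param motion a [chest_motion()].
#' @return radial displacement \[m\], same length as `t`; bounded by
#'   `a_br + a_hr` (plus harmonic amplitudes) in magnitude.
#' @examples
#' chest_displacement(0, chest_motion())            # 0
#' chest_displacement(1, chest_motion(f_br = 0.25)) # breathing peak
#' @export
chest_displacement <- function(t, motion) {
  stopifnot(inherits(motion, "chest_motion"), all(t >= 0))
  x <- motion$a_br * sin(2 * pi * motion$f_br * t + motion$phi_br) +
       motion$a_hr * sin(2 * pi * motion$f_hr * t + motion$phi_hr)
  for (h in motion$harmonics)
    x <- x + h$a * sin(2 * pi * h$f * t + h$phi)
  x
}

#' Angle-dependent antenna gain taper
#'
#' One-way relative amplitude gain of the radar antenna as a function of
#' azimuth, modeled as a cosine-power taper `cos(theta)^k`.  The taper stands
#' in for the measured radiation pattern of a directional on-chip antenna:
#' unity at boresight, even in angle, and monotonically decreasing away from
#' zero degrees.  The default exponent `k = 1.3` places the two-way gain at
#' 40 degrees about 6 dB below boresight.
#'
#' @param theta azimuth \[deg\], vectorized; must satisfy `|theta| <= 90`.
#' @param k cosine exponent (> 0).
#' @return relative one-way amplitude gain in \[0, 1\].
#' @examples
#' antenna_gain(0)        # 1
#' antenna_gain(40, k = 2)  # cos(40 deg)^2 ~ 0.587
#' @export
antenna_gain <- function(theta, k = 1.3) {
  if (any(abs(theta) > 90))
    stop("antenna gain is defined for |theta| <= 90 degrees")
  stopifnot(k > 0)
  cos(theta * pi / 180)^k
}

#' Assemble a measurement scene
#'
#' A scene is one target-plus-environment configuration: a point-like chest at
#' nominal range `distance` and azimuth `angle`, with micro-motion `motion`,
#' optional static clutter reflectors, and additive complex noise.
#'
#' @param distance target nominal range R0 \[m\] (> 0).
#' @param angle target azimuth \[deg\] in \[-90, 90\].
#' @param motion a [chest_motion()].
#' @param sigma target reflection amplitude (relative, dimensionless).
#' @param clutter data.frame with columns `range`, `amplitude` and optionally
#'   `angle` (defaults to 0 deg) describing static reflectors, or `NULL`.
#' @param noise_std standard deviation of the circularly-symmetric complex
#'   noise added per ADC sample (total complex sd; each quadrature gets
#'   `noise_std/sqrt(2)`).
#' @param taper_k antenna taper exponent passed to [antenna_gain()].
#' @param seed integer seed consumed by the simulator for noise draws.
#' @return object of class `scene`.
#' @export
make_scene <- function(distance, angle, motion = chest_motion(), sigma = 1,
                       clutter = NULL, noise_std = 0, taper_k = 1.3,
                       seed = 1L) {
  if (!(distance > 0)) stop("target range must be positive")
  if (abs(angle) > 90) stop("|angle| must be <= 90 degrees")
  if (sigma < 0 || noise_std < 0) stop("amplitudes must be non-negative")
  if (!is.null(clutter)) {
    clutter <- as.data.frame(clutter)
    if (!all(c("range", "amplitude") %in% names(clutter)))
      stop("clutter needs columns 'range' and 'amplitude'")
    if (is.null(clutter$angle)) clutter$angle <- 0
    if (any(clutter$range <= 0) || any(clutter$amplitude < 0))
      stop("clutter ranges must be positive and amplitudes non-negative")
  }
  stopifnot(inherits(motion, "chest_motion"))
  sc <- list(R0 = distance, theta = angle, sigma = sigma, motion = motion,
             clutter = clutter, noise_std = noise_std, taper_k = taper_k,
             seed = as.integer(seed))
  class(sc) <- "scene"
  sc
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> target R0 = %g m, theta = %g deg, sigma = %g\n",
              x$R0, x$theta, x$sigma))
  cat(sprintf("  motion: BR %.3g Hz (%.1f /min, %.2g m), HR %.3g Hz (%.1f /min, %.2g m)\n",
              x$motion$f_br, 60 * x$motion$f_br, x$motion$a_br,
              x$motion$f_hr, 60 * x$motion$f_hr, x$motion$a_hr))
  cat(sprintf("  clutter: %d reflector(s); noise_std = %g; taper k = %g; seed = %d\n",
              if (is.null(x$clutter)) 0L else nrow(x$clutter),
              x$noise_std, x$taper_k, x$seed))
  invisible(x)
}

#' The distance-by-angle measurement grid
#'
#' Enumerates the experimental grid: three distances crossed with five
#' azimuth angles, 15 measurement points in total.
#'
#' @param distances distances \[m\].
#' @param angles azimuths \[deg\].
#' @return data.frame with columns `point`, `distance`, `angle`.
#' @export
grid_points <- function(distances = c(0.9, 1.2, 1.5),
                        angles = c(-40, -20, 0, 20, 40)) {
  g <- expand.grid(distance = distances, angle = angles,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$distance, g$angle), , drop = FALSE]
  data.frame(point = seq_len(nrow(g)), distance = g$distance, angle = g$angle)
}
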