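#' Radar waveform and array configuration
#'
#' Bundles all waveform and antenna-array constants of the frequency-modulated
#' continuous-wave (FMCW) radar into a validated list.  Defaults follow a
#' 60 GHz off-the-shelf MIMO sensor with 2 TX and 4 RX antennas that combine
#' into an 8-element half-wavelength virtual uniform linear array (VULA).
#'
#' The ADC sampling parameters (`n_samples`, implied rate `n_samples / T`) are
#' not part of the published sensor sheet; the defaults of 256 complex samples
#' over a 50 us chirp give a 5.12 MHz IF rate and an unambiguous range extent
#' of about 9.9 m, close to the sensor's stated 11 m maximum range.
#'
#' @param fc chirp start frequency \[Hz\].
#' @param B chirp bandwidth \[Hz\].
#' @param T_chirp chirp duration \[s\].
#' @param M chirps per frame.
#' @param frame_rate frames per second \[1/s\].
#' @param n_samples complex ADC samples per chirp.
#' @param n_tx,n_rx number of transmit / receive antennas.
#' @param d virtual-element spacing \[m\]; defaults to half the carrier
#'   wavelength `c_light / fc / 2`.
#' @param c_light propagation speed \[m/s\].
#'
#' @return An object of class `radar_config`: a named list with the arguments
#'   above plus `lambda` (carrier wavelength) and `fs` (IF sampling rate).
#' @examples
#' cfg <- radar_config()
#' range_resolution(cfg)      # ~0.0386 m
#' virtual_array_size(cfg)    # 8
#' @export
radar_config <- function(fc = 60e9, B = 3.89e9, T_chirp = 50e-6, M = 50,
                         frame_rate = 20, n_samples = 256,
                         n_tx = 2, n_rx = 4, d = NULL, c_light = 3e8) {
  stopifnot(fc > 0, B > 0, T_chirp > 0, M >= 1, frame_rate > 0,
            n_samples >= 2, n_tx >= 1, n_rx >= 1, c_light > 0)
  lambda <- c_light / fc
  if (is.null(d)) d <- lambda / 2
  stopifnot(d > 0)
  if (M * T_chirp > 1 / frame_rate)
    stop("chirps do not fit in one frame period: M * T_chirp > 1/frame_rate")
  cfg <- list(fc = fc, B = B, T_chirp = T_chirp, M = M,
              frame_rate = frame_rate, n_samples = n_samples,
              n_tx = n_tx, n_rx = n_rx, d = d, c_light = c_light,
              lambda = lambda, fs = n_samples / T_chirp)
  class(cfg) <- "radar_config"
  cfg
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  fc = %.2f GHz, B = %.2f GHz, T = %.1f us, fs = %.2f MHz\n",
              x$fc / 1e9, x$B / 1e9, x$T_chirp * 1e6, x$fs / 1e6))
  cat(sprintf("  %d chirps/frame @ %g frames/s, %d samples/chirp\n",
              x$M, x$frame_rate, x$n_samples))
  cat(sprintf("  %d TX x %d RX -> %d virtual channels, d = %.3g m (lambda/2 = %.3g m)\n",
              x$n_tx, x$n_rx, virtual_array_size(x), x$d, x$lambda / 2))
  cat(sprintf("  range resolution %.4f m, max range %.2f m\n",
              range_resolution(x), range_resolution(x) * x$n_samples))
  invisible(x)
}

#' Range resolution of an FMCW chirp
#'
#' `c / (2 B)`: the range-bin width obtained when the fast-time FFT length
#' equals the number of ADC samples.
#'
#' @param config a [radar_config()].
#' @return resolution \[m\].
#' @export
range_resolution <- function(config) {
  stopifnot(inherits(config, "radar_config"))
  config$c_light / (2 * config$B)
}

#' Number of virtual receive channels
#'
#' A MIMO radar with orthogonal transmitters synthesizes a virtual uniform
#' linear array of `n_tx * n_rx` elements.
#'
#' @param config a [radar_config()].
#' @return integer channel count.
#' @export
virtual_array_size <- function(config) {
  stopifnot(inherits(config, "radar_config"))
  as.integer(config$n_tx * config$n_rx)
}
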