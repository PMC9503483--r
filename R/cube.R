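# fast-time window; periodic Hann so that sum(w) = n/2 and sum(w^2) = 3n/8
.fft_window <- function(n, type = c("hann", "rect")) {
  type <- match.arg(type)
  switch(type,
         hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n),
         rect = rep(1, n))
}

#' Range FFT: ADC frame to radar data cube
#'
#' Applies a fast-time window and FFT to every chirp and channel of one ADC
#' frame, producing the radar data cube slice `(chirp, range bin, channel)`.
#' Range bin `k` (0-based) is centered at `k * bin_spacing` with
#' `bin_spacing = c/(2B) * n_samples / fft_size`; the DC bin is zero range.
#'
#' The default Hann window trades resolution for sidelobe suppression so that
#' strong static clutter near the chest bin does not capture the peak; the
#' rectangular window preserves Parseval's identity exactly.
#'
#' @param frame complex array `(M, n_samples, N)` from [simulate_frame()].
#' @param config a [radar_config()].
#' @param fft_size FFT length `>= n_samples` (zero-padded); default
#'   `n_samples`.
#' @param window `"hann"` or `"rect"`.
#' @return complex array `(M, fft_size, N)` of class `radar_cube` with
#'   attribute `bin_spacing`.
#' @export
range_fft <- function(frame, config, fft_size = NULL,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  stopifnot(inherits(config, "radar_config"), length(dim(frame)) == 3)
  M <- dim(frame)[1]; ns <- dim(frame)[2]; N <- dim(frame)[3]
  stopifnot(ns == config$n_samples)
  if (is.null(fft_size)) fft_size <- ns
  if (fft_size < ns) stop("fft_size must be >= n_samples")
  w <- .fft_window(ns, window)
  out <- array(0 + 0i, dim = c(M, fft_size, N))
  for (n in seq_len(N)) {
    padded <- rbind(t(frame[, , n, drop = TRUE] * rep(w, each = M)),
                    matrix(0 + 0i, fft_size - ns, M))
    out[, , n] <- t(stats::mvfft(padded))
  }
  structure(out,
            bin_spacing = range_resolution(config) * ns / fft_size,
            window = window, t0 = attr(frame, "t0"),
            class = c("radar_cube", "array"))
}

#' Coherent chirp average of a cube slice
#'
#' Averages the chirp (slow-time-within-frame) dimension of a radar data
#' cube, yielding one complex range profile per channel.
#'
#' @param cube a `radar_cube` (or any `(M, R, N)` complex array).
#' @return complex matrix `(R, N)`.
#' @export
chirp_average <- function(cube) {
  stopifnot(length(dim(cube)) == 3)
  colMeans(unclass(cube))
}

#' Assemble the slow-time cube of an ADC recording
#'
#' Convenience wrapper giving the same `(frames, range bins, channels)` cube
#' as [slow_time_cube()] but starting from materialized ADC frames: each
#' frame is range-FFT'd and chirp-averaged.
#'
#' @param rec an [simulate_recording()] result.
#' @inheritParams range_fft
#' @return a `slow_cube`.
#' @export
recording_to_cube <- function(rec, fft_size = NULL,
                              window = c("hann", "rect")) {
  window <- match.arg(window)
  stopifnot(inherits(rec, "adc_recording"))
  config <- rec$config
  if (is.null(fft_size)) fft_size <- config$n_samples
  slices <- lapply(rec$frames, function(f)
    chirp_average(range_fft(f, config, fft_size, window)))
  N <- virtual_array_size(config)
  cube <- array(0 + 0i, dim = c(length(slices), fft_size, N))
  for (f in seq_along(slices)) cube[f, , ] <- slices[[f]]
  structure(cube, config = config, scene = rec$scene, times = rec$times,
            bin_spacing = range_resolution(config) * config$n_samples / fft_size,
            window = window, class = c("slow_cube", "array"))
}
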