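#' Recursive clutter (static background) filter
#'
#' Loop-back background subtraction along slow time: the running background
#' estimate `b_k = alpha * b_(k-1) + (1 - alpha) * x_k` (with `b_0 = 0`) is
#' subtracted from the input, `y_k = x_k - b_k`.  A constant input decays
#' geometrically at rate `alpha`; the transfer function is the first-order
#' high-pass `H(z) = alpha * (1 - z^-1) / (1 - alpha * z^-1)`, so slow-time
#' DC (static clutter) is removed while the breathing/heartbeat passband is
#' nearly untouched for `alpha` close to 1 at typical frame rates.
#'
#' @param x complex (or numeric) vector, or a matrix with slow time along
#'   rows (one column per range bin).
#' @param alpha forgetting factor in (0, 1).
#' @return filtered series, same shape as `x`.
#' @export
clutter_filter <- function(x, alpha = 0.95) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  rec <- function(v) {
    b <- stats::filter((1 - alpha) * v, alpha, method = "recursive")
    as.numeric(v - b)
  }
  run <- function(v) {
    if (is.complex(v)) complex(real = rec(Re(v)), imaginary = rec(Im(v)))
    else rec(v)
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- run(x[, j])
    out
  } else run(x)
}

#' Select the range bin occupied by the (breathing) target
#'
#' The human chest is the strongest *time-varying* reflector: after clutter
#' filtering, its bin has the largest slow-time variance of magnitude.  Ties
#' break toward the smaller bin.
#'
#' The recursive filter starts from an all-zero background estimate, so its
#' output carries a decaying transient of the static scene for the first few
#' time constants; `settle` initial frames (default three time constants,
#' `3/(1-alpha)`) are discarded before the variance scan so that a strong
#' clutter transient cannot outvote the breathing bin.
#'
#' @param x complex matrix `(frames, range bins)` (e.g. a beamformed slice),
#'   or a `slow_cube` whose channel 1 is used.
#' @param alpha clutter-filter forgetting factor; `NULL` skips filtering
#'   (input already filtered).
#' @param settle number of initial frames excluded from the variance scan;
#'   default `ceiling(3 / (1 - alpha))` when `alpha` is given, else 0.
#' @return 0-based range-bin index.
#' @export
select_target_bin <- function(x, alpha = 0.95, settle = NULL) {
  if (length(dim(x)) == 3)
    x <- matrix(unclass(x)[, , 1], dim(x)[1], dim(x)[2])
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (!is.null(alpha)) {
    x <- clutter_filter(x, alpha)
    if (is.null(settle)) settle <- ceiling(3 / (1 - alpha))
  }
  if (is.null(settle)) settle <- 0L
  if (settle >= nrow(x) - 1) settle <- 0L
  v <- apply(Mod(x[(settle + 1):nrow(x), , drop = FALSE]), 2, stats::var)
  if (diff(range(v)) == 0)
    stop("target detection failed: all range bins have equal variance")
  as.integer(which.max(v)) - 1L
}

#' Unwrap a phase series
#'
#' Adds multiples of `2*pi` so that successive differences stay within
#' `(-pi, pi]`.
#'
#' @param p phase \[rad\].
#' @return unwrapped phase \[rad\].
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  p[1] + c(0, cumsum(d - 2 * pi * round(d / (2 * pi))))
}

#' Extract the slow-time phase at the target bin
#'
#' Per-frame argument of the complex value at the target range bin,
#' unwrapped over slow time.  Chest displacement `x(t)` appears here as
#' `4*pi*x(t)/lambda` (two-way path).  Frames with (near) zero magnitude
#' give no reliable phase; their phase is held from the previous frame and a
#' low-SNR warning is raised.
#'
#' @param x complex matrix `(frames, range bins)`; chirps within a frame are
#'   assumed already coherently averaged (see [slow_time_cube()]).
#' @param bin 0-based target range bin.
#' @param frame_rate sampling rate of the series \[1/s\].
#' @param beamformed logical flag recorded on the result.
#' @return numeric vector of class `phase_series` with attributes
#'   `frame_rate`, `bin`, `beamformed`.
#' @export
extract_phase <- function(x, bin, frame_rate = 20, beamformed = NA) {
  stopifnot(is.matrix(x))
  if (bin < 0 || bin >= ncol(x)) stop("target bin out of range")
  z <- x[, bin + 1]
  dead <- Mod(z) < .Machine$double.eps
  raw <- Arg(z)
  if (any(dead)) {
    warning("zero-magnitude samples at target bin: holding previous phase")
    for (k in which(dead)) raw[k] <- if (k == 1) 0 else raw[k - 1]
  }
  structure(unwrap_phase(raw), frame_rate = frame_rate, bin = bin,
            beamformed = beamformed, class = "phase_series")
}

#' Zero-phase band-pass filter
#'
#' Spectral-mask band-pass: the FFT of the (mean-removed) input is
#' multiplied by a raised-cosine-edged mask that passes `band` and applied
#' symmetrically to positive and negative frequencies, so the filter has
#' exactly zero phase and no group delay to bias windowed rate estimates.
#'
#' @param x real vector.
#' @param fs sampling rate \[Hz\].
#' @param band `c(low, high)` \[Hz\], inside `(0, fs/2)`.
#' @param edge transition half-width \[Hz\].
#' @return filtered real vector.
#' @export
bandpass_filter <- function(x, fs, band, edge = 0.04) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                       # two-sided frequency magnitude
  mask <- rep(0, n)
  lo <- band[1]; hi <- band[2]
  mask[f >= lo & f <= hi] <- 1
  ramp_in <- f > lo - edge & f < lo
  mask[ramp_in] <- 0.5 + 0.5 * cos(pi * (lo - f[ramp_in]) / edge)
  ramp_out <- f > hi & f < hi + edge
  mask[ramp_out] <- 0.5 + 0.5 * cos(pi * (f[ramp_out] - hi) / edge)
  Re(fft(fft(x - mean(x)) * mask, inverse = TRUE)) / n
}

# single-window spectral rate estimate [Hz]; NA when the band is silent.
# notch: optional matrix with columns lo, hi [Hz] of bands to exclude.
.window_peak_freq <- function(x, fs, band, resolution_hz, notch = NULL) {
  n <- length(x)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))   # remove mean + linear trend
  x <- bandpass_filter(x, fs, band)
  nfft <- 2^ceiling(log2(max(n, fs / resolution_hz)))
  spec <- Mod(fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  if (!is.null(notch))
    for (r in seq_len(nrow(notch)))
      in_band <- in_band & !(freq >= notch[r, 1] & freq <= notch[r, 2])
  if (!any(in_band)) return(NA_real_)
  cand <- which(in_band)
  if (max(spec[cand]) <= n * .Machine$double.eps * 100) return(NA_real_)
  freq[cand[which.max(spec[cand])]]
}

#' Windowed spectral rate estimation with moving-mean smoothing
#'
#' Slides a window over the unwrapped phase; in each window the signal is
#' detrended, band-pass filtered ([bandpass_filter()]), zero-padded so the
#' spectral grid is at most `resolution` per minute, and the in-band peak
#' frequency is taken as the rate.  A trailing moving mean over `smooth`
#' window estimates reduces estimator noise.  Windows whose band is silent
#' yield `NA` (estimation failure, never a fabricated number).
#'
#' @param phase a [extract_phase()] series (or plain numeric + `frame_rate`).
#' @param band `c(low, high)` \[Hz\].
#' @param window window length \[s\]; must be at least `2 / band[1]` and not
#'   exceed the recording.
#' @param stride window step \[s\].
#' @param smooth number of window estimates in the moving mean.
#' @param resolution spectral grid \[breaths-or-beats per minute\].
#' @param frame_rate sampling rate, read from `phase` when present.
#' @param notch_freqs optional per-window fundamental frequencies \[Hz\]
#'   whose 2nd to 4th harmonics are notched (+-0.05 Hz) before peak picking
#'   (used to keep breathing harmonics out of the heart-rate band).
#' @return data.frame of class `rate_series` with columns `time` (window
#'   end \[s\]), `rate` (smoothed, \[1/min\]), `rate_raw` (unsmoothed).
#' @export
bandpass_rates <- function(phase, band, window = 30, stride = 1, smooth = 5,
                           resolution = 0.25, frame_rate = NULL,
                           notch_freqs = NULL) {
  fs <- frame_rate %||% attr(phase, "frame_rate")
  if (is.null(fs)) stop("frame_rate must be supplied")
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  if (window < 2 / band[1])
    stop("window must cover at least two periods of the lower band edge")
  n <- length(phase)
  wlen <- round(window * fs)
  if (wlen > n) stop("window longer than the recording")
  starts <- seq(1L, n - wlen + 1L, by = max(1L, round(stride * fs)))
  raw <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    seg <- as.numeric(phase[starts[i]:(starts[i] + wlen - 1L)])
    notch <- NULL
    if (!is.null(notch_freqs) && is.finite(notch_freqs[i]))
      notch <- cbind(2:4 * notch_freqs[i] - 0.05, 2:4 * notch_freqs[i] + 0.05)
    f <- .window_peak_freq(seg, fs, band, resolution / 60, notch)
    raw[i] <- 60 * f
  }
  sm <- raw
  for (i in seq_along(raw)) {
    lo <- max(1L, i - smooth + 1L)
    v <- raw[lo:i]
    sm[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out <- data.frame(time = (starts + wlen - 1L) / fs, rate = sm,
                    rate_raw = raw)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' End-to-end vital-sign extraction from a slow-time cube
#'
#' Runs the full chain on a `(frames, range bins, channels)` cube:
#' beamform at the desired (or estimated) angle -- or keep only virtual
#' channel 1 when `beamform = FALSE` --, clutter-filter the slow-time series
#' of every range bin, select the target bin by slow-time variance, extract
#' and unwrap the phase, then estimate breathing and heart rates with two
#' band-pass filters and windowed spectral peaks.  Breathing harmonics
#' (2nd-4th, +-0.05 Hz around the per-window breathing estimate) are notched
#' out of the heart-rate band before peak picking.
#'
#' @param cube a [slow_time_cube()] / [recording_to_cube()] result.
#' @param beamform apply delay-and-sum beamforming?  `FALSE` reproduces the
#'   single-receiver baseline (virtual channel 1 only).
#' @param angle steering azimuth \[deg\]; `NULL` estimates it with
#'   [beam_scan()] + [estimate_aoa()].
#' @param br_band,hr_band breathing / heart-rate pass bands \[Hz\].
#' @param window,stride,smooth see [bandpass_rates()].
#' @param alpha clutter-filter forgetting factor.
#' @return object of class `vitals_result`: data.frame with columns `time`,
#'   `br`, `hr` (smoothed rates \[1/min\]) and attributes `bin`, `angle`,
#'   `beamformed`.
#' @export
extract_vitals <- function(cube, beamform = TRUE, angle = NULL,
                           br_band = c(0.1, 0.6), hr_band = c(0.8, 2.2),
                           window = 30, stride = 1, smooth = 5,
                           alpha = 0.95) {
  stopifnot(length(dim(cube)) == 3)
  config <- attr(cube, "config")
  fs <- if (!is.null(config)) config$frame_rate else
    1 / diff(attr(cube, "times")[1:2])
  if (beamform) {
    if (is.null(angle)) angle <- estimate_aoa(beam_scan(cube))
    slice <- apply_beamforming(cube, steering_weights(angle, dim(cube)[3]))
  } else {
    angle <- NA_real_
    slice <- matrix(unclass(cube)[, , 1], dim(cube)[1], dim(cube)[2])
  }
  filtered <- clutter_filter(slice, alpha)
  bin <- select_target_bin(filtered, alpha = NULL,
                           settle = ceiling(3 / (1 - alpha)))
  phase <- extract_phase(filtered, bin, frame_rate = fs,
                         beamformed = beamform)
  br <- bandpass_rates(phase, br_band, window, stride, smooth)
  hr <- bandpass_rates(phase, hr_band, window, stride, smooth,
                       notch_freqs = br$rate_raw / 60)
  out <- data.frame(time = br$time, br = br$rate, hr = hr$rate)
  attr(out, "bin") <- bin
  attr(out, "angle") <- angle
  attr(out, "beamformed") <- beamform
  class(out) <- c("vitals_result", "data.frame")
  out
}

#' @export
print.vitals_result <- function(x, ...) {
  cat(sprintf("<vitals_result> %d windows, %s, target bin %d\n",
              nrow(x),
              if (isTRUE(attr(x, "beamformed")))
                sprintf("beamformed @ %.1f deg", attr(x, "angle"))
              else "single channel (no beamforming)",
              attr(x, "bin")))
  cat(sprintf("  median BR %.2f breaths/min, median HR %.2f beats/min\n",
              stats::median(x$br, na.rm = TRUE),
              stats::median(x$hr, na.rm = TRUE)))
  invisible(x)
}
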