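#' Round-trip propagation delay
#'
#' Two-way delay of an echo from a target at range `R` moving radially at
#' `v_r`: `2 (R + v_r t) / c`.
#'
#' @param R range \[m\], > 0.
#' @param v_r radial velocity \[m/s\].
#' @param t elapsed time \[s\].
#' @param c_light propagation speed \[m/s\].
#' @return delay \[s\].
#' @examples
#' round_trip_delay(1.2)   # 8 ns
#' @export
round_trip_delay <- function(R, v_r = 0, t = 0, c_light = 3e8) {
  if (any(R <= 0)) stop("range must be positive")
  2 * (R + v_r * t) / c_light
}

# geometric inter-channel phase increment [rad] per element for arrival
# angle theta [deg]; equals pi*sin(theta) at half-wavelength spacing
.channel_phase_step <- function(config, theta) {
  2 * pi * config$d * sin(theta * pi / 180) / config$lambda
}

#' IF signal of one chirp at one virtual channel
#'
#' Complex intermediate-frequency (mixer output) samples for a single point
#' reflector during one chirp.  The sample at fast time t carries phase
#' `2*pi*(fc*dt + (B/T)*dt*t - (B/(2T))*dt^2)` where `dt` is the round-trip
#' delay, plus the inter-channel plane-wave phase
#' `(n_ch - 1) * 2*pi*d*sin(theta)/lambda`.  The chest is frozen within one
#' chirp (stop-and-hop): `R` is a scalar.
#'
#' @param config a [radar_config()].
#' @param R reflector range at the chirp start \[m\].
#' @param n_ch virtual-channel index, 1-based.
#' @param theta arrival azimuth \[deg\].
#' @param amplitude reflection amplitude (before the antenna taper).
#' @param taper_k antenna taper exponent, or `NULL` to disable the two-way
#'   gain taper.
#' @return complex vector of length `config$n_samples`.
#' @export
if_signal <- function(config, R, n_ch, theta = 0, amplitude = 1,
                      taper_k = NULL) {
  stopifnot(inherits(config, "radar_config"), length(R) == 1)
  N <- virtual_array_size(config)
  if (n_ch < 1 || n_ch > N) stop("channel index out of range 1..", N)
  dt <- round_trip_delay(R, c_light = config$c_light)
  tf <- (seq_len(config$n_samples) - 1) / config$fs
  slope <- config$B / config$T_chirp
  phase <- 2 * pi * (config$fc * dt + slope * dt * tf - slope * dt^2 / 2)
  a <- amplitude
  if (!is.null(taper_k)) a <- a * antenna_gain(theta, taper_k)^2
  a * exp(1i * (phase + (n_ch - 1) * .channel_phase_step(config, theta)))
}

# all reflectors of a scene in one table: the moving chest plus static clutter
.scene_reflectors <- function(scene) {
  refl <- data.frame(range = scene$R0, theta = scene$theta,
                     amplitude = scene$sigma * antenna_gain(scene$theta, scene$taper_k)^2,
                     moving = TRUE)
  if (!is.null(scene$clutter) && nrow(scene$clutter) > 0)
    refl <- rbind(refl, data.frame(
      range = scene$clutter$range, theta = scene$clutter$angle,
      amplitude = scene$clutter$amplitude *
        antenna_gain(scene$clutter$angle, scene$taper_k)^2,
      moving = FALSE))
  refl
}

# deterministic fast-time matrix (n_chirps x n_samples) for one reflector,
# given the chirp start times; `ranges` has one entry per chirp
.fast_time_matrix <- function(config, ranges, amplitude) {
  dt <- round_trip_delay(ranges, c_light = config$c_light)
  tf <- (seq_len(config$n_samples) - 1) / config$fs
  slope <- config$B / config$T_chirp
  const <- amplitude * exp(1i * (2 * pi * config$fc * dt - pi * slope * dt^2))
  const * exp(2i * pi * slope * outer(dt, tf))
}

#' Simulate one ADC frame
#'
#' Deterministic echoes of every reflector in the scene plus (optionally)
#' complex white noise, for the `M` chirps of one frame starting at `t0`.
#' Noise draws use the current RNG state; seed management belongs to the
#' caller ([simulate_recording()]).
#'
#' @param config a [radar_config()].
#' @param scene a [make_scene()].
#' @param t0 frame start time \[s\].
#' @param add_noise draw per-ADC-sample complex noise of sd
#'   `scene$noise_std`?
#' @return complex array `(M, n_samples, N_virt)` of class `adc_frame` with
#'   attribute `t0`.
#' @export
simulate_frame <- function(config, scene, t0 = 0, add_noise = TRUE) {
  stopifnot(inherits(config, "radar_config"), inherits(scene, "scene"))
  M <- config$M; ns <- config$n_samples; N <- virtual_array_size(config)
  t_chirp <- t0 + (seq_len(M) - 1) * config$T_chirp
  out <- array(0 + 0i, dim = c(M, ns, N))
  refl <- .scene_reflectors(scene)
  for (r in seq_len(nrow(refl))) {
    ranges <- rep(refl$range[r], M)
    if (refl$moving[r])
      ranges <- ranges + chest_displacement(t_chirp, scene$motion)
    ft <- .fast_time_matrix(config, ranges, refl$amplitude[r])
    ch <- exp(1i * .channel_phase_step(config, refl$theta[r]) * (seq_len(N) - 1))
    for (n in seq_len(N)) out[, , n] <- out[, , n] + ft * ch[n]
  }
  if (add_noise && scene$noise_std > 0) {
    s <- scene$noise_std / sqrt(2)
    out <- out + array(complex(real = rnorm(M * ns * N, sd = s),
                               imaginary = rnorm(M * ns * N, sd = s)),
                       dim = c(M, ns, N))
  }
  structure(out, t0 = t0, class = c("adc_frame", "array"))
}

#' Simulate a full recording as a sequence of ADC frames
#'
#' Frame `f` starts at `(f-1)/frame_rate`; the chest range is re-evaluated at
#' every chirp start.  Deterministic given `seed`.  Memory grows with
#' `duration * frame_rate * M * n_samples * N`; for long recordings prefer
#' the streaming [slow_time_cube()], which stores only one complex value per
#' frame, range bin and channel.
#'
#' @param config a [radar_config()].
#' @param scene a [make_scene()].
#' @param duration recording length \[s\]; at least one frame period.
#' @param seed RNG seed; defaults to `scene$seed`.
#' @return object of class `adc_recording`: list with `frames` (list of
#'   [simulate_frame()] outputs), `times`, `config`, `scene`.
#' @export
simulate_recording <- function(config, scene, duration, seed = scene$seed) {
  stopifnot(duration > 0)
  n_frames <- floor(duration * config$frame_rate)
  if (n_frames < 1)
    stop("duration shorter than one frame period (", 1 / config$frame_rate, " s)")
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) / config$frame_rate
  frames <- lapply(times, function(t0)
    simulate_frame(config, scene, t0, add_noise = TRUE))
  structure(list(frames = frames, times = times, config = config,
                 scene = scene), class = "adc_recording")
}

#' @export
print.adc_recording <- function(x, ...) {
  cat(sprintf("<adc_recording> %d frames (%.1f s), dim/frame = %s\n",
              length(x$frames), length(x$frames) / x$config$frame_rate,
              paste(dim(x$frames[[1]]), collapse = " x ")))
  invisible(x)
}

#' Stream a recording directly into a slow-time range cube
#'
#' Synthesizes the recording frame-by-frame and immediately reduces each
#' frame to its chirp-coherent range profile: a Hann (or rectangular)
#' windowed fast-time FFT after averaging the `M` chirps of the frame.  The
#' result is the complex array `(frames, range bins, virtual channels)` that
#' the vital-sign chain consumes, at a small fraction of the memory of
#' [simulate_recording()].
#'
#' Noise models: `"adc"` draws per-ADC-sample noise exactly as
#' [simulate_frame()] does; `"spectral"` draws the distribution-identical
#' per-bin noise directly after the FFT (complex sd
#' `noise_std * sqrt(sum(w^2) / M)` for window `w`), which is much faster for
#' long noisy recordings.  The deterministic part is identical in both modes.
#'
#' @param config a [radar_config()].
#' @param scene a [make_scene()].
#' @param duration recording length \[s\].
#' @param seed RNG seed; defaults to `scene$seed`.
#' @param fft_size fast-time FFT length, `>= n_samples`; default `n_samples`.
#' @param window `"hann"` or `"rect"`.
#' @param noise_model `"adc"` or `"spectral"`.
#' @return complex array `(n_frames, fft_size, N_virt)` of class `slow_cube`
#'   with attributes `config`, `scene`, `times`, `bin_spacing`, `window`.
#' @export
slow_time_cube <- function(config, scene, duration, seed = scene$seed,
                           fft_size = NULL, window = c("hann", "rect"),
                           noise_model = c("adc", "spectral")) {
  window <- match.arg(window)
  noise_model <- match.arg(noise_model)
  stopifnot(duration > 0)
  n_frames <- floor(duration * config$frame_rate)
  if (n_frames < 1)
    stop("duration shorter than one frame period (", 1 / config$frame_rate, " s)")
  M <- config$M; ns <- config$n_samples; N <- virtual_array_size(config)
  if (is.null(fft_size)) fft_size <- ns
  if (fft_size < ns) stop("fft_size must be >= n_samples")
  w <- .fft_window(ns, window)
  times <- (seq_len(n_frames) - 1) / config$frame_rate
  set.seed(seed)

  cube <- array(0 + 0i, dim = c(n_frames, fft_size, N))
  refl <- .scene_reflectors(scene)
  for (r in seq_len(nrow(refl))) {
    ch <- exp(1i * .channel_phase_step(config, refl$theta[r]) * (seq_len(N) - 1))
    if (!refl$moving[r]) {
      # static reflector: one chirp equals every chirp; FFT once
      ft <- .fast_time_matrix(config, refl$range[r], refl$amplitude[r])
      spec <- fft(c(as.vector(ft) * w, rep(0 + 0i, fft_size - ns)))
      for (n in seq_len(N))
        cube[, , n] <- cube[, , n] +
          matrix(spec * ch[n], n_frames, fft_size, byrow = TRUE)
    } else {
      # chest target: chunked over frames to bound the chirp-matrix size
      chunk <- max(1L, floor(2e6 / (M * ns)))
      for (f0 in seq(1L, n_frames, by = chunk)) {
        f1 <- min(f0 + chunk - 1L, n_frames)
        nf <- f1 - f0 + 1L
        t_all <- rep(times[f0:f1], each = M) +
          rep((seq_len(M) - 1) * config$T_chirp, nf)
        ranges <- refl$range[r] + chest_displacement(t_all, scene$motion)
        ft <- .fast_time_matrix(config, ranges, refl$amplitude[r]) # (nf*M) x ns
        avg <- colMeans(array(ft, dim = c(M, nf, ns)))             # nf x ns
        padded <- rbind(t(avg) * w, matrix(0 + 0i, fft_size - ns, nf))
        spec <- t(stats::mvfft(padded))                            # nf x fft
        for (n in seq_len(N))
          cube[f0:f1, , n] <- cube[f0:f1, , n] + spec * ch[n]
      }
    }
  }
  if (scene$noise_std > 0) {
    if (noise_model == "adc") {
      for (f in seq_len(n_frames)) {
        s <- scene$noise_std / sqrt(2)
        nz <- array(complex(real = rnorm(M * ns * N, sd = s),
                            imaginary = rnorm(M * ns * N, sd = s)),
                    dim = c(M, ns, N))
        for (n in seq_len(N)) {
          avg <- colMeans(nz[, , n]) * w
          cube[f, , n] <- cube[f, , n] + fft(c(avg, rep(0 + 0i, fft_size - ns)))
        }
      }
    } else {
      s_bin <- scene$noise_std * sqrt(sum(w^2) / M) / sqrt(2)
      cube <- cube + array(complex(real = rnorm(length(cube), sd = s_bin),
                                   imaginary = rnorm(length(cube), sd = s_bin)),
                           dim = dim(cube))
    }
  }
  structure(cube, config = config, scene = scene, times = times,
            bin_spacing = range_resolution(config) * ns / fft_size,
            window = window, class = c("slow_cube", "array"))
}

#' @export
print.slow_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<slow_cube> %d frames x %d range bins x %d channels, bin spacing %.4f m\n",
              d[1], d[2], d[3], attr(x, "bin_spacing")))
  invisible(x)
}

#' Write / read a recording container
#'
#' Recordings and cubes are stored with base-R serialization (one object per
#' file) together with a plain-text CSV sidecar (`<path>.truth.csv`) logging
#' the ground-truth breathing/heart rates and target position, so that batch
#' evaluations can score files without deserializing them.
#'
#' @param x an `adc_recording` or `slow_cube`.
#' @param path output file path (conventionally `.rds`).
#' @return `path` invisibly for the writer; the object for the reader.
#' @export
write_recording <- function(x, path) {
  scene <- if (inherits(x, "slow_cube")) attr(x, "scene") else x$scene
  saveRDS(x, path)
  if (!is.null(scene))
    utils::write.csv(data.frame(
      br = 60 * scene$motion$f_br, hr = 60 * scene$motion$f_hr,
      R0 = scene$R0, theta = scene$theta, noise_std = scene$noise_std),
      paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) readRDS(path)
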