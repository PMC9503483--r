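#' Read a scene/motion configuration file
#'
#' Plain-text key-value format with `[section]` headers (INI style).  Numeric
#' values and comma-separated numeric vectors are parsed; everything else is
#' kept as a string.  Lines starting with `#` or `;` are comments.
#'
#' Recognized sections: `[radar]` (fields of [radar_config()], with `T` for
#' the chirp duration), `[motion]` (fields of [chest_motion()]), `[scene]`
#' (`distance`, `angle`, `sigma`, `noise_std`, `taper_k`, `seed`),
#' `[clutter]` (`range`, `amplitude`, optionally `angle`, as equal-length
#' vectors), and any number of `[point.N]` sections each with `distance` and
#' `angle`, which define a measurement grid.
#'
#' @param path file path.
#' @return named list of sections; each section a named list of values.
#' @seealso [scene_from_config()], [write_grid_config()]
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside of any [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      out[[section]][[key]] <- if (!anyNA(num)) num else val
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  out
}

#' Write a scene configuration file
#'
#' Inverse of [read_scene_config()]; numeric vectors are comma-joined.
#'
#' @param config named list of sections (named lists of values).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sec in names(config)) {
    writeLines(sprintf("[%s]", sec), con)
    for (key in names(config[[sec]])) {
      val <- config[[sec]][[key]]
      writeLines(sprintf("%s = %s", key,
                         paste(format(val, digits = 15, scientific = FALSE,
                                      trim = TRUE), collapse = ", ")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Emit the 15-point measurement-grid configuration
#'
#' Writes a config file containing the default radar parameters, the default
#' chest motion, and one `[point.N]` section per grid point (three distances
#' crossed with five angles).
#'
#' @param path output file path.
#' @param grid a grid as returned by [grid_points()].
#' @return `path`, invisibly.
#' @export
write_grid_config <- function(path, grid = grid_points()) {
  cfg <- radar_config()
  m <- chest_motion()
  out <- list(
    radar = list(fc = cfg$fc, B = cfg$B, T = cfg$T_chirp, M = cfg$M,
                 frame_rate = cfg$frame_rate, n_samples = cfg$n_samples,
                 n_tx = cfg$n_tx, n_rx = cfg$n_rx),
    motion = list(f_br = m$f_br, a_br = m$a_br, f_hr = m$f_hr, a_hr = m$a_hr),
    scene = list(sigma = 1, noise_std = 0, taper_k = 1.3, seed = 1)
  )
  for (i in seq_len(nrow(grid)))
    out[[sprintf("point.%d", grid$point[i])]] <-
      list(distance = grid$distance[i], angle = grid$angle[i])
  write_scene_config(out, path)
}

#' Build objects from a parsed configuration
#'
#' @param config parsed config list from [read_scene_config()].
#' @param point grid-point number to use when the config defines `[point.N]`
#'   sections; ignored when a `[scene]` section carries its own
#'   `distance`/`angle`.
#' @return list with elements `radar` ([radar_config()]) and `scene`
#'   ([make_scene()]).
#' @export
scene_from_config <- function(config, point = 1L) {
  r <- config$radar
  radar <- if (is.null(r)) radar_config() else
    radar_config(fc = r$fc %||% 60e9, B = r$B %||% 3.89e9,
                 T_chirp = (r$T %||% r$T_chirp) %||% 50e-6,
                 M = r$M %||% 50, frame_rate = r$frame_rate %||% 20,
                 n_samples = r$n_samples %||% 256,
                 n_tx = r$n_tx %||% 2, n_rx = r$n_rx %||% 4)
  mo <- config$motion
  motion <- if (is.null(mo)) chest_motion() else
    chest_motion(f_br = mo$f_br %||% 0.25, a_br = mo$a_br %||% 2e-3,
                 f_hr = mo$f_hr %||% 1.25, a_hr = mo$a_hr %||% 0.3e-3,
                 phi_br = mo$phi_br %||% 0, phi_hr = mo$phi_hr %||% 0)
  sc <- config$scene %||% list()
  pos <- if (!is.null(sc$distance) && !is.null(sc$angle)) sc else {
    p <- config[[sprintf("point.%d", point)]]
    if (is.null(p)) stop("config has no [scene] position and no [point.",
                         point, "] section")
    p
  }
  clut <- config$clutter
  if (!is.null(clut))
    clut <- data.frame(range = clut$range, amplitude = clut$amplitude,
                       angle = clut$angle %||% 0)
  scene <- make_scene(distance = pos$distance, angle = pos$angle,
                      motion = motion, sigma = sc$sigma %||% 1,
                      clutter = clut, noise_std = sc$noise_std %||% 0,
                      taper_k = sc$taper_k %||% 1.3,
                      seed = sc$seed %||% 1)
  list(radar = radar, scene = scene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
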