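#' Diffraction geometry of the tracked ring
#'
#' Derives the wavelength, Bragg angle and Debye-Scherrer ring radius from the
#' beam energy, lattice spacing and camera length:
#' `wavelength = 12.3984 / E_keV` (Angstrom), `sin(bragg) = wavelength /
#' (2 * d_spacing)`, `ring_radius = camera_length * tan(2 * bragg)`.
#' For a 15 keV beam on Au(111) (d = 2.355 A) at 50 mm this gives a 0.8266 A
#' wavelength, a scattering angle 2theta_B of 0.3528 rad and an 18.41 mm ring.
#'
#' @param acq An [acquisition_config()], or `NULL` to pass parameters directly.
#' @param beam_energy,d_spacing,camera_length,pixel_size,image_shape,beam_center
#'   Geometry parameters, used when `acq` is `NULL` (same meaning and units as
#'   in [acquisition_config()]).
#' @return An object of class `diffraction_geometry` with derived fields
#'   `wavelength` (A), `bragg_angle` (rad) and `ring_radius` (mm).
#' @examples
#' geom <- diffraction_geometry(acquisition_config())
#' geom$ring_radius  # 18.41 mm
#' @export
diffraction_geometry <- function(acq = NULL, beam_energy = 15.0,
                                 d_spacing = 2.355, camera_length = 50.0,
                                 pixel_size = 150,
                                 image_shape = c(256L, 256L),
                                 beam_center = NULL) {
  if (!is.null(acq)) {
    beam_energy <- acq$beam_energy; d_spacing <- acq$d_spacing
    camera_length <- acq$camera_length; pixel_size <- acq$pixel_size
    image_shape <- acq$image_shape; beam_center <- acq$beam_center
  }
  if (beam_energy <= 0 || d_spacing <= 0 || camera_length <= 0) {
    abort("`beam_energy`, `d_spacing` and `camera_length` must be > 0.")
  }
  wavelength <- 12.3984 / beam_energy
  s <- wavelength / (2 * d_spacing)
  if (s >= 1) abort("No Bragg solution: wavelength >= 2 * d_spacing.")
  bragg <- asin(s)
  if (is.null(beam_center)) beam_center <- c(image_shape[2] / 2, image_shape[1] / 2)
  structure(
    list(wavelength = wavelength, d_spacing = d_spacing, bragg_angle = bragg,
         ring_radius = camera_length * tan(2 * bragg),
         camera_length = camera_length, pixel_size = pixel_size,
         image_shape = as.integer(image_shape),
         beam_center = as.numeric(beam_center)),
    class = "diffraction_geometry"
  )
}

#' @export
print.diffraction_geometry <- function(x, ...) {
  cat("<diffraction_geometry>\n")
  cat(sprintf("  lambda = %.4f A, 2*bragg = %.4f rad, ring radius = %.3f mm (%.1f px)\n",
              x$wavelength, 2 * x$bragg_angle, x$ring_radius,
              x$ring_radius * 1000 / x$pixel_size))
  invisible(x)
}

#' Map crystal angles to a detector position
#'
#' The twist angle chi sets the azimuth of the diffraction spot on the ring
#' (counter-clockwise positive); the tilt angle theta offsets the radial
#' position through the Bragg condition:
#' `r = camera_length * tan(2 * bragg + 2 * theta)`. Image rows increase
#' downward, so increasing chi moves the spot up the image, keeping the
#' clockwise (negative delta-chi) convention intact in angle space.
#'
#' @param theta_mrad,chi_mrad Numeric vectors of tilt and twist angles, mrad.
#' @param geom A [diffraction_geometry()].
#' @return A tibble with continuous pixel coordinates `x`, `y`.
#' @export
angles_to_pixel <- function(theta_mrad, chi_mrad, geom) {
  r_mm <- geom$camera_length * tan(2 * geom$bragg_angle + 2 * theta_mrad / 1000)
  phi <- chi_mrad / 1000
  px_per_mm <- 1000 / geom$pixel_size
  tibble(
    x = geom$beam_center[1] + r_mm * cos(phi) * px_per_mm,
    y = geom$beam_center[2] - r_mm * sin(phi) * px_per_mm
  )
}

#' Convert linked detector tracks to angular trajectories
#'
#' Exact inverse of [angles_to_pixel()] applied per observation. Observations
#' at the beam centre (undefined azimuth) are dropped with a warning.
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `x_px`, `y_px`.
#' @param geom A [diffraction_geometry()].
#' @return Trajectory tibble with `track_id`, `frame`, `theta_mrad`,
#'   `chi_mrad` (plus `intensity` if present in the input).
#' @export
pixel_to_angles <- function(tracks, geom) {
  assert_cols(tracks, c("track_id", "frame", "x_px", "y_px"), "`tracks`")
  px_per_mm <- 1000 / geom$pixel_size
  dx <- (tracks$x_px - geom$beam_center[1]) / px_per_mm
  dy <- (geom$beam_center[2] - tracks$y_px) / px_per_mm
  r <- sqrt(dx^2 + dy^2)
  bad <- r < 1e-9
  if (any(bad)) {
    warn(sprintf("Dropping %d observation(s) at the beam centre (undefined azimuth).",
                 sum(bad)))
  }
  out <- tibble(
    track_id = tracks$track_id, frame = tracks$frame,
    theta_mrad = (atan(r / geom$camera_length) - 2 * geom$bragg_angle) / 2 * 1000,
    chi_mrad = atan2(dy, dx) * 1000
  )
  if ("intensity" %in% names(tracks)) out$intensity <- tracks$intensity
  out[!bad, ]
}

#' Origin-referenced displacement series
#'
#' For each track, the displacement at each frame is taken from the track's
#' first observation (the "travel distance from the original point"), so the
#' series starts at 0 and negative twist displacements mean clockwise
#' rotation. Set `origin = "step"` for frame-to-frame increments instead.
#'
#' @param trajs Trajectory tibble with `track_id`, `frame`, `theta_mrad`,
#'   `chi_mrad`.
#' @param frame_time Frame time, microseconds.
#' @param origin `"first"` (default) references every displacement to the
#'   track origin; `"step"` returns per-frame increments.
#' @return Tibble with `track_id`, `frame`, `lag_ms`, `d_theta_mrad`,
#'   `d_chi_mrad`.
#' @export
displacement_series <- function(trajs, frame_time = 100,
                                origin = c("first", "step")) {
  origin <- match.arg(origin)
  assert_cols(trajs, c("track_id", "frame", "theta_mrad", "chi_mrad"), "`trajs`")
  lens <- trajs |> dplyr::count(.data$track_id)
  if (any(lens$n < 2)) {
    abort("Every track needs >= 2 observations; apply a lifetime filter first.")
  }
  out <- trajs |>
    group_by(.data$track_id) |>
    arrange(.data$frame, .by_group = TRUE)
  if (origin == "first") {
    out <- out |> mutate(
      lag_ms = (.data$frame - first(.data$frame)) * frame_time / 1000,
      d_theta_mrad = .data$theta_mrad - first(.data$theta_mrad),
      d_chi_mrad = .data$chi_mrad - first(.data$chi_mrad))
  } else {
    out <- out |> mutate(
      lag_ms = (.data$frame - first(.data$frame)) * frame_time / 1000,
      d_theta_mrad = .data$theta_mrad - lag(.data$theta_mrad),
      d_chi_mrad = .data$chi_mrad - lag(.data$chi_mrad))
  }
  out |> ungroup() |>
    select("track_id", "frame", "lag_ms", "d_theta_mrad", "d_chi_mrad")
}
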