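#' Render diffraction-spot image stacks from trajectories
#'
#' Places a 2D Gaussian spot at the detector position of every live trajectory
#' in every frame (via [angles_to_pixel()]), attenuates the peak intensity by
#' a Gaussian Ewald-acceptance factor in tilt (width derived from the beam
#' bandwidth: `sigma_accept = 1000 * tan(bragg) * bandwidth / 2` mrad, a
#' rendering convenience, not a physical diffraction model), adds a constant
#' background, and draws per-pixel Poisson counts. Observations mapping
#' outside the detector are clipped with a warning.
#'
#' @param trajs Trajectory tibble (`track_id`, `frame`, `theta_mrad`,
#'   `chi_mrad`).
#' @param acq An [acquisition_config()] (sets detector size and frame count).
#' @param psf_sigma Spot point-spread width, pixels (> 0).
#' @param photon_scale Peak photon count of an unattenuated spot.
#' @param background Constant background level, counts.
#' @param poisson Add Poisson noise (default `TRUE`); `FALSE` returns the
#'   expected counts, useful for oracle tests.
#' @param seed Seed for the Poisson draws; defaults to `acq$rng_seed + 1`.
#' @return Integer array `[ny, nx, n_frames]` of nonnegative counts
#'   (clipped at 65535, i.e. unsigned 16-bit).
#' @export
render_frames <- function(trajs, acq = acquisition_config(), psf_sigma = 1.5,
                          photon_scale = 1000, background = 10,
                          poisson = TRUE, seed = acq$rng_seed + 1L) {
  if (psf_sigma <= 0) abort("`psf_sigma` must be > 0.")
  if (background < 0) abort("`background` must be >= 0.")
  geom <- diffraction_geometry(acq)
  ny <- acq$image_shape[1]; nx <- acq$image_shape[2]
  expected <- array(background, dim = c(ny, nx, acq$n_frames))
  sigma_accept <- 1000 * tan(geom$bragg_angle) * acq$bandwidth / 2

  n_clipped <- 0L
  if (nrow(trajs) > 0) {
    pos <- angles_to_pixel(trajs$theta_mrad, trajs$chi_mrad, geom)
    amp <- photon_scale * exp(-trajs$theta_mrad^2 / (2 * sigma_accept^2))
    half <- ceiling(4 * psf_sigma)
    for (k in seq_len(nrow(trajs))) {
      f <- trajs$frame[k] + 1L
      if (f < 1 || f > acq$n_frames) next
      x0 <- pos$x[k]; y0 <- pos$y[k]
      if (x0 < 0 || x0 > nx || y0 < 0 || y0 > ny) {
        n_clipped <- n_clipped + 1L
        next
      }
      # pixel (r, c) has centre (c - 0.5, r - 0.5)
      cc <- max(1L, floor(x0 + 0.5) - half):min(nx, floor(x0 + 0.5) + half)
      rr <- max(1L, floor(y0 + 0.5) - half):min(ny, floor(y0 + 0.5) + half)
      gx <- exp(-((cc - 0.5) - x0)^2 / (2 * psf_sigma^2))
      gy <- exp(-((rr - 0.5) - y0)^2 / (2 * psf_sigma^2))
      expected[rr, cc, f] <- expected[rr, cc, f] + amp[k] * outer(gy, gx)
    }
  }
  if (n_clipped > 0) {
    warn(sprintf("%d observation(s) mapped outside the detector and were clipped.",
                 n_clipped))
  }
  if (poisson) {
    set.seed(seed)
    counts <- array(rpois(length(expected), expected), dim = dim(expected))
  } else {
    counts <- round(expected)
  }
  counts[counts > 65535L] <- 65535L
  storage.mode(counts) <- "integer"
  counts
}

#' Read and write multi-frame 16-bit grayscale TIFF stacks
#'
#' @param stack Integer array `[ny, nx, n_frames]` of counts in 0-65535.
#' @param path File path.
#' @return `read_frames()` returns an integer count array; `write_frames()`
#'   returns `path` invisibly.
#' @export
write_frames <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0L, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) out[, , f] <- as.integer(round(frames[[f]] * 65535))
  out
}
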