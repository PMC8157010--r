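# Draw a track lifetime in frames: geometric with the requested mean,
# truncated to [1, n_frames]. Never returns 0.
draw_lifetime_frames <- function(lifetime_mean_ms, frame_time_ms, n_frames) {
  if (!is.finite(lifetime_mean_ms)) return(as.integer(n_frames))
  mean_frames <- lifetime_mean_ms / frame_time_ms
  p <- min(1, 1 / max(mean_frames, 1))
  L <- rgeom(1L, p) + 1L
  min(L, as.integer(n_frames))
}

# One axis of Euler-Maruyama motion: Gaussian increments of variance 2*D*dt
# plus drift*dt per frame, with an optional reflecting fold at x0 +/- radius.
evolve_axis <- function(n, x0, D, drift, radius, dt) {
  if (n == 1) return(x0)
  steps <- rnorm(n - 1L, mean = drift * dt, sd = sqrt(2 * D * dt))
  if (!is.finite(radius)) return(x0 + c(0, cumsum(steps)))
  x <- numeric(n)
  x[1] <- x0
  pos <- 0
  for (i in seq_len(n - 1L)) {
    pos <- pos + steps[i]
    # reflect about +/- radius relative to the start
    while (pos > radius || pos < -radius) {
      if (pos > radius) pos <- 2 * radius - pos else pos <- -2 * radius - pos
    }
    x[i + 1L] <- x0 + pos
  }
  x
}

#' Simulate rotational trajectories of labelled molecules
#'
#' Forward model for DXT trajectories: each track is assigned to a population
#' by weight, given a geometric lifetime (truncated to the recording), and
#' evolved by Euler-Maruyama steps (Gaussian increments of variance
#' `2 * D * dt` per axis plus `drift * dt`, reflecting fold at the confinement
#' radius). An observed copy of each angle adds i.i.d. Gaussian measurement
#' error of standard deviation `noise_beta`, matching the `2 * beta^2`
#' intercept of the anomalous MSD model.
#'
#' Randomness is fully determined by `seed`: every trajectory uses its own
#' deterministic substream, so any subset of trajectory ids is reproducible.
#'
#' @param populations A list of [population_spec()] objects; weights must sum
#'   to 1 (within 1e-9).
#' @param n_traj Number of trajectories to simulate.
#' @param acq An [acquisition_config()].
#' @param noise_beta Measurement error standard deviation, mrad (>= 0).
#' @param seed Integer master seed; defaults to `acq$rng_seed`.
#' @return A tibble with one row per observation and columns `track_id`,
#'   `population`, `frame` (0-based), `theta_mrad`, `chi_mrad` (noise-added
#'   observed angles) and `theta_true_mrad`, `chi_true_mrad` (ground truth).
#' @examples
#' acq <- acquisition_config(n_frames = 20)
#' trajs <- simulate_trajectories(default_populations(), 10, acq, seed = 1)
#' dplyr::count(trajs, track_id)
#' @export
simulate_trajectories <- function(populations, n_traj, acq = acquisition_config(),
                                  noise_beta = 0, seed = acq$rng_seed) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (length(populations) == 0) abort("`populations` must be non-empty.")
  for (p in populations) {
    if (!inherits(p, "population_spec")) abort("Each population must be a `population_spec`.")
  }
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (any(w < 0)) abort("Population weights must be >= 0.")
  if (abs(sum(w) - 1) > 1e-9) abort("Population weights must sum to 1.")
  if (noise_beta < 0) abort("`noise_beta` must be >= 0.")
  if (n_traj < 1) abort("`n_traj` must be >= 1.")

  labels <- vapply(seq_along(populations), function(j) {
    populations[[j]]$label %||% names(populations)[j] %||% paste0("pop", j)
  }, character(1))
  dt <- acq$frame_time / 1000  # ms per frame
  lens <- integer(n_traj); pop_idx <- integer(n_traj); t0s <- integer(n_traj)
  thetas <- vector("list", n_traj); chis <- vector("list", n_traj)
  eths <- vector("list", n_traj); echs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(derive_seed(seed, i))
    j <- sample.int(length(populations), 1L, prob = w)
    pop <- populations[[j]]
    L <- draw_lifetime_frames(pop$lifetime_mean, dt, acq$n_frames)
    t0 <- if (L < acq$n_frames) sample.int(acq$n_frames - L + 1L, 1L) - 1L else 0L
    th0 <- rnorm(1, 0, pop$start_dispersion)
    ch0 <- rnorm(1, 0, pop$start_dispersion)
    lens[i] <- L; pop_idx[i] <- j; t0s[i] <- t0
    thetas[[i]] <- evolve_axis(L, th0, pop$D_theta, pop$drift_theta,
                               pop$confinement_radius, dt)
    chis[[i]] <- evolve_axis(L, ch0, pop$D_chi, pop$drift_chi,
                             pop$confinement_radius, dt)
    eths[[i]] <- if (noise_beta > 0) rnorm(L, 0, noise_beta) else numeric(L)
    echs[[i]] <- if (noise_beta > 0) rnorm(L, 0, noise_beta) else numeric(L)
  }
  theta <- unlist(thetas); chi <- unlist(chis)
  tibble(
    track_id = rep(seq_len(n_traj), lens),
    population = rep(labels[pop_idx], lens),
    frame = unlist(lapply(seq_len(n_traj),
                          function(i) t0s[i] + seq_len(lens[i]) - 1L)),
    theta_mrad = theta + unlist(eths),
    chi_mrad = chi + unlist(echs),
    theta_true_mrad = theta, chi_true_mrad = chi)
}

#' Track lifetimes of a trajectory table
#'
#' @param trajs Trajectory tibble with `track_id` and `frame` columns.
#' @param frame_time Frame time, microseconds.
#' @return Tibble with `track_id`, `n_obs`, `lifetime_ms` (and `population`
#'   if present in the input).
#' @export
track_lifetimes <- function(trajs, frame_time = 100) {
  assert_cols(trajs, c("track_id", "frame"), "`trajs`")
  grp <- trajs |> group_by(.data$track_id)
  if ("population" %in% names(trajs)) {
    out <- grp |> summarise(population = first(.data$population),
                            n_obs = n(), .groups = "drop")
  } else {
    out <- grp |> summarise(n_obs = n(), .groups = "drop")
  }
  out |> mutate(lifetime_ms = .data$n_obs * frame_time / 1000)
}
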