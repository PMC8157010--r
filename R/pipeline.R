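#' Default run configuration
#'
#' A plain nested list (YAML-serialisable) holding every stage's parameters:
#' acquisition, simulation, tracking, lifetime filter, MSD fit and
#' displacement-distribution settings, plus the condition names and the
#' master seed. All randomness in a run derives from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_traj Trajectories simulated per condition.
#' @param render If `TRUE`, each condition goes through the full image path
#'   (render, background-subtract, detect, link, convert to angles) instead of
#'   using the simulated angular observations directly.
#' @return A run-config list.
#' @export
default_run_config <- function(seed = 1L, n_traj = 10000, render = FALSE) {
  list(
    seed = as.integer(seed),
    acquisition = list(frame_time = 100, n_frames = 100, beam_energy = 15,
                       bandwidth = 0.02, camera_length = 50, pixel_size = 150,
                       image_shape = c(256L, 256L), d_spacing = 2.355),
    simulation = list(n_traj = n_traj, noise_beta = 0.3, render = render,
                      psf_sigma = 1.5, photon_scale = 2000, background = 20),
    tracking = list(min_intensity = 300, min_separation = 3, max_disp = 3,
                    min_frames = 2),
    filter = list(drop_max = 0.4, keep_min = 0.5, keep_max = 10),
    msd = list(fit_fraction = 0.25, regime_tol = 0.05),
    popdist = list(lags_ms = c(1, 1.6), bin_width = 1, n_components = "auto",
                   chi_range = 20, theta_max = 30),
    conditions = c("unliganded", "agonist", "inverse_agonist")
  )
}

condition_seed <- function(config, condition) {
  derive_seed(config$seed, sum(utf8ToInt(condition)))
}

#' Run the full analysis pipeline for one condition
#'
#' Executes simulate -> (optional image path: render, background-subtract,
#' detect, link, convert to angles) -> lifetime filter -> per-axis
#' time-averaged MSD with anomalous-diffusion fits -> displacement samples at
#' the configured lags with Gaussian mixture fits and two-axis maps. All
#' randomness is derived from the config seed and the condition name, so a
#' rerun with the same config reproduces the report exactly. Mixture fits at
#' lags with too few surviving tracks are recorded as skipped rather than
#' aborting the run (sparse long tracks are expected under the short-lifetime
#' distribution).
#'
#' @param config A run-config list (see [default_run_config()]).
#' @param condition Condition name (see [condition_populations()]).
#' @param out_dir Optional directory for intermediate artifacts (trajectory
#'   CSV, MSD CSV, fit JSON, map matrices).
#' @return An object of class `dxt_report`: counts, lifetime-filter summary,
#'   per-axis `anomalous_fit`s, per-lag mixture fits and maps, seed and
#'   config hash.
#' @export
run_condition <- function(config = default_run_config(), condition = "unliganded",
                          out_dir = NULL) {
  acq <- do.call(acquisition_config,
                 c(config$acquisition, list(rng_seed = condition_seed(config, condition))))
  pops <- condition_populations(condition, acq$frame_time)
  sim <- config$simulation
  trajs <- simulate_trajectories(pops, sim$n_traj, acq,
                                 noise_beta = sim$noise_beta)

  if (isTRUE(sim$render)) {
    stack <- render_frames(trajs, acq, psf_sigma = sim$psf_sigma,
                           photon_scale = sim$photon_scale,
                           background = sim$background)
    # background level is known in simulation; temporal-median estimation
    # would swallow near-stationary (confined) spots
    clean <- subtract_background(stack, "constant", constant = sim$background)
    det <- detect_stack(clean, min_intensity = config$tracking$min_intensity,
                        min_separation = config$tracking$min_separation)
    tracks <- link_tracks(det, max_disp = config$tracking$max_disp,
                          min_frames = config$tracking$min_frames)
    obs <- pixel_to_angles(tracks, diffraction_geometry(acq))
  } else {
    obs <- trajs |> select("track_id", "frame", "theta_mrad", "chi_mrad",
                           "population")
  }

  flt <- lifetime_filter(obs, drop_max = config$filter$drop_max,
                         keep_min = config$filter$keep_min,
                         keep_max = config$filter$keep_max,
                         frame_time = acq$frame_time)

  fits <- lapply(c(theta = "theta", chi = "chi"), function(ax) {
    curves <- time_avg_msd(flt$kept, axis = ax, frame_time = acq$frame_time)
    ens <- ensemble_msd(curves)
    fit_anomalous(ens, fit_range = c(0, config$msd$fit_fraction * max(ens$lag_ms)),
                  regime_tol = config$msd$regime_tol)
  })

  ce <- chi_bin_edges(config$popdist$chi_range, config$popdist$bin_width)
  te <- theta_bin_edges(max_edge = config$popdist$theta_max)
  per_lag <- lapply(config$popdist$lags_ms, function(l) {
    smp <- displacement_sample(flt$kept, l, acq$frame_time, condition = condition)
    mix <- tryCatch(
      fit_mixture(smp, n_components = config$popdist$n_components,
                  bin_width = config$popdist$bin_width),
      error = function(e) conditionMessage(e))
    map <- if (nrow(smp) > 0)
      two_axis_map(smp, ce, te, label = condition) else NULL
    list(lag_ms = l, n_points = nrow(smp), sample = smp, mixture = mix,
         map = map)
  })
  names(per_lag) <- paste0("lag_", config$popdist$lags_ms)

  report <- structure(
    list(condition = condition,
         n_traj = sim$n_traj,
         n_tracks_observed = dplyr::n_distinct(obs$track_id),
         n_tracks_kept = flt$long_count,
         ratio_short_to_long = flt$ratio_short_to_long,
         msd_fits = fits,
         per_lag = per_lag,
         seed = config$seed,
         config_hash = rlang::hash(config),
         version = as.character(packageVersion("dxtr"))),
    class = "dxt_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectories(obs, file.path(out_dir, paste0(condition, "_tracks.csv")))
    msd_tbl <- bind_rows(lapply(fits, function(f) f$fitted |>
                                  mutate(axis = f$axis %||% NA_character_)))
    readr::write_csv(msd_tbl, file.path(out_dir, paste0(condition, "_msd.csv")))
    jsonlite::write_json(
      list(condition = condition,
           fits = lapply(fits, function(f)
             list(D_alpha = f$D_alpha, alpha = f$alpha, beta = f$beta,
                  regime = f$regime, fit_range = f$fit_range))),
      file.path(out_dir, paste0(condition, "_fits.json")),
      auto_unbox = TRUE, digits = NA)
    for (pl in per_lag) {
      if (!is.null(pl$map)) {
        write_map(pl$map, file.path(out_dir, sprintf("%s_map_%gms.txt",
                                                     condition, pl$lag_ms)))
      }
    }
  }
  report
}

#' @export
print.dxt_report <- function(x, ...) {
  cat(sprintf("<dxt_report> condition %s\n", x$condition))
  cat(sprintf("  %d simulated, %d observed tracks, %d kept (short:long = %.2f)\n",
              x$n_traj, x$n_tracks_observed, x$n_tracks_kept,
              x$ratio_short_to_long))
  for (ax in names(x$msd_fits)) {
    f <- x$msd_fits[[ax]]
    cat(sprintf("  %s: alpha = %.3f, D_alpha = %.3g, beta = %.3g [%s]\n",
                ax, f$alpha, f$D_alpha, f$beta, f$regime))
  }
  for (pl in x$per_lag) {
    if (inherits(pl$mixture, "mixture_fit")) {
      cat(sprintf("  lag %g ms: %d points, %d mixture component(s)\n",
                  pl$lag_ms, pl$n_points, pl$mixture$n_components))
    } else {
      cat(sprintf("  lag %g ms: %d points, mixture skipped (%s)\n",
                  pl$lag_ms, pl$n_points, pl$mixture))
    }
  }
  invisible(x)
}

#' Compare analysed conditions by subtraction
#'
#' For each requested ordered pair of condition reports, subtracts the
#' two-axis maps at every shared lag (both pair orders are reported; the
#' reverse order is the sign-flipped map) and tabulates deltas of the fitted
#' anomalous exponents and of the main mixture-component variance.
#'
#' @param reports A named list of `dxt_report` objects (names are condition
#'   labels), as returned by [run_condition()].
#' @param pairs List of length-2 character vectors of condition names;
#'   default: every ordered pair.
#' @return An object of class `dxt_comparison`: `deltas` tibble and a `maps`
#'   tibble with a list-column of `subtraction_map` objects.
#' @export
compare_conditions <- function(reports, pairs = NULL) {
  nms <- names(reports)
  if (is.null(nms)) abort("`reports` must be a named list.")
  if (is.null(pairs)) {
    pairs <- list()
    for (a in nms) for (b in nms) if (a != b) pairs <- c(pairs, list(c(a, b)))
  }
  deltas <- list(); maps <- list()
  for (p in pairs) {
    a <- reports[[p[1]]]; b <- reports[[p[2]]]
    if (is.null(a) || is.null(b)) abort("Unknown condition in `pairs`.")
    for (ax in names(a$msd_fits)) {
      d_alpha <- a$msd_fits[[ax]]$alpha - b$msd_fits[[ax]]$alpha
      deltas[[length(deltas) + 1]] <- tibble(
        a = p[1], b = p[2], quantity = paste0("alpha_", ax), delta = d_alpha)
    }
    for (lg in intersect(names(a$per_lag), names(b$per_lag))) {
      pa <- a$per_lag[[lg]]; pb <- b$per_lag[[lg]]
      if (inherits(pa$mixture, "mixture_fit") &&
          inherits(pb$mixture, "mixture_fit")) {
        d_var <- pa$mixture$components$variance[1] -
          pb$mixture$components$variance[1]
        deltas[[length(deltas) + 1]] <- tibble(
          a = p[1], b = p[2],
          quantity = paste0("main_variance_", sub("lag_", "", lg), "ms"),
          delta = d_var)
      }
      if (!is.null(pa$map) && !is.null(pb$map)) {
        sm <- subtract_maps(pa$map, pb$map)
        maps[[length(maps) + 1]] <- tibble(
          a = p[1], b = p[2], lag_ms = pa$lag_ms, map = list(sm))
      }
    }
  }
  structure(list(deltas = bind_rows(deltas), maps = bind_rows(maps)),
            class = "dxt_comparison")
}

#' @export
print.dxt_comparison <- function(x, ...) {
  cat("<dxt_comparison>\n")
  print(as.data.frame(x$deltas), digits = 3)
  invisible(x)
}
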