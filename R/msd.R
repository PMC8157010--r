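#' Lifetime filtering of tracks
#'
#' Partitions tracks by lifetime: short-lived tracks (lifetime <= `drop_max`)
#' are excluded as noise, long-lived tracks (`keep_min` <= lifetime <=
#' `keep_max`) are kept for analysis, and anything else (possible only on
#' grids finer than the defaults, or beyond `keep_max`) is removed and counted
#' separately. At 0.1 ms frames the default window (drop <= 0.4 ms, keep
#' 0.5-10 ms) is exhaustive. The short:long count ratio is reported; under the
#' calibrated default lifetime distribution it is 2.5.
#'
#' @param trajs Trajectory tibble (`track_id`, `frame`, ...).
#' @param drop_max Maximum lifetime of the excluded short-lived class, ms.
#' @param keep_min,keep_max Lifetime window of the retained class, ms.
#' @param frame_time Frame time, microseconds.
#' @return An object of class `lifetime_filter`: list with `kept` and
#'   `removed` trajectory tibbles, `short_count`, `long_count`, `other_count`,
#'   and `ratio_short_to_long`.
#' @export
lifetime_filter <- function(trajs, drop_max = 0.4, keep_min = 0.5,
                            keep_max = 10, frame_time = 100) {
  if (drop_max <= 0 || keep_min <= 0 || keep_max <= 0 || frame_time <= 0) {
    abort("Durations must be positive.")
  }
  if (!(drop_max < keep_min && keep_min <= keep_max)) {
    abort("Require drop_max < keep_min <= keep_max.")
  }
  if (nrow(trajs) == 0) {
    res <- list(kept = trajs, removed = trajs, short_count = 0L,
                long_count = 0L, other_count = 0L,
                ratio_short_to_long = NaN,
                thresholds = c(drop_max = drop_max, keep_min = keep_min,
                               keep_max = keep_max),
                lifetimes = track_lifetimes(trajs[0, ], frame_time))
    class(res) <- "lifetime_filter"
    return(res)
  }
  lt <- track_lifetimes(trajs, frame_time)
  lt$class <- ifelse(lt$lifetime_ms <= drop_max, "short",
              ifelse(lt$lifetime_ms >= keep_min & lt$lifetime_ms <= keep_max,
                     "long", "other"))
  kept_ids <- lt$track_id[lt$class == "long"]
  res <- list(
    kept = trajs |> filter(.data$track_id %in% kept_ids),
    removed = trajs |> filter(!.data$track_id %in% kept_ids),
    short_count = sum(lt$class == "short"),
    long_count = sum(lt$class == "long"),
    other_count = sum(lt$class == "other"),
    ratio_short_to_long = sum(lt$class == "short") / sum(lt$class == "long"),
    thresholds = c(drop_max = drop_max, keep_min = keep_min,
                   keep_max = keep_max),
    lifetimes = lt
  )
  class(res) <- "lifetime_filter"
  res
}

#' @export
print.lifetime_filter <- function(x, ...) {
  cat("<lifetime_filter>\n")
  cat(sprintf("  short (<= %.2g ms): %d   long (%.2g-%.2g ms): %d   other: %d\n",
              x$thresholds["drop_max"], x$short_count,
              x$thresholds["keep_min"], x$thresholds["keep_max"],
              x$long_count, x$other_count))
  cat(sprintf("  short:long ratio = %.3g\n", x$ratio_short_to_long))
  invisible(x)
}

# FFT-based time-averaged MSD of one series:
# msd[k] = mean_i (x[i+k] - x[i])^2, computed via cumulative sums (S1) and a
# zero-padded autocorrelation (S2).
msd_fft <- function(x, max_lag) {
  x <- x - x[1]  # MSD is shift-invariant; anchoring improves conditioning
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nfft - n)))
  s2 <- Re(fft(Mod(fx)^2, inverse = TRUE)) / nfft
  css <- cumsum(x^2)
  k <- seq_len(max_lag)
  s1 <- css[n - k] + (css[n] - css[k])
  (s1 - 2 * s2[k + 1]) / (n - k)
}

#' Time-averaged mean square displacement per track
#'
#' Computes, for each track and axis, the temporal MSD
#' `msd(k) = mean_i (x[i+k] - x[i])^2` over all start frames `i`, with
#' `n_pairs(k) = n - k` averaging pairs at lag `k`. `axis = "both"` returns
#' the sum of the two per-axis curves (total squared angular displacement).
#' Uses an FFT autocorrelation fast path, algebraically identical to the
#' naive double loop.
#'
#' @param trajs Trajectory tibble; each track needs >= 2 observations at
#'   consecutive frames.
#' @param axis `"theta"`, `"chi"` or `"both"`.
#' @param max_lag_frames Largest lag to evaluate; `NULL` (default) uses
#'   `n - 1` per track. Must be `< n` for every track.
#' @param frame_time Frame time, microseconds.
#' @return Tibble with `track_id`, `axis`, `lag_ms`, `msd` (mrad^2),
#'   `n_pairs`.
#' @export
time_avg_msd <- function(trajs, axis = c("both", "theta", "chi"),
                         max_lag_frames = NULL, frame_time = 100) {
  axis <- match.arg(axis)
  assert_cols(trajs, c("track_id", "frame", "theta_mrad", "chi_mrad"), "`trajs`")
  dt <- frame_time / 1000
  trajs <- trajs |> arrange(.data$track_id, .data$frame)
  split_idx <- split(seq_len(nrow(trajs)), trajs$track_id)
  out <- lapply(split_idx, function(idx) {
    n <- length(idx)
    if (n < 2) abort("Every track needs >= 2 observations.")
    ml <- max_lag_frames %||% (n - 1L)
    if (ml >= n) abort("`max_lag_frames` must be < the track length.")
    ml <- min(ml, n - 1L)
    m <- switch(axis,
      theta = msd_fft(trajs$theta_mrad[idx], ml),
      chi = msd_fft(trajs$chi_mrad[idx], ml),
      both = msd_fft(trajs$theta_mrad[idx], ml) + msd_fft(trajs$chi_mrad[idx], ml))
    tibble(track_id = trajs$track_id[idx[1]], axis = axis,
           lag_ms = seq_len(ml) * dt, msd = m, n_pairs = n - seq_len(ml))
  })
  bind_rows(out)
}

#' Ensemble average of per-track MSD curves
#'
#' Pair-count-weighted mean of time-averaged MSD curves across tracks at each
#' lag, equal to pooling every squared displacement across the ensemble.
#'
#' @param curves Output of [time_avg_msd()] (one or more tracks).
#' @return Tibble with `axis`, `lag_ms`, `msd`, `n_pairs` (summed).
#' @export
ensemble_msd <- function(curves) {
  if (nrow(curves) == 0) abort("`curves` must be non-empty.")
  assert_cols(curves, c("axis", "lag_ms", "msd", "n_pairs"), "`curves`")
  curves |>
    group_by(.data$axis, .data$lag_ms) |>
    summarise(msd = weighted.mean(.data$msd, .data$n_pairs),
              n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    arrange(.data$axis, .data$lag_ms)
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of `msd(t) = D_alpha * t^alpha +
#' 2 * beta^2` (weights = pair counts), with bounds `D_alpha >= 0`,
#' `alpha` in (0, 3] and `beta >= 0`, multi-start initialisation over
#' `alpha` in {0.5, 1, 1.5, 2} with best-residual selection. `alpha < 1`
#' indicates subdiffusion (confined motion), `alpha = 1` simple Brownian
#' rotation (slope `4 D` over both axes), and `alpha > 1` superdiffusion
#' (directed motion); `beta` is the static measurement error.
#'
#' @param curve A single-axis MSD tibble (`lag_ms`, `msd`, `n_pairs`), e.g.
#'   from [ensemble_msd()].
#' @param fit_range Numeric `c(min, max)` lag window in ms; `NULL` (default)
#'   uses lags up to 25% of the largest available lag.
#' @param regime_tol Half-width of the Brownian band around `alpha = 1` used
#'   by [classify_regime()].
#' @return An object of class `anomalous_fit` with fields `D_alpha`, `alpha`,
#'   `beta`, `regime`, `fit_range`, `residual_norm`, `n_lags`, and a `fitted`
#'   tibble.
#' @export
fit_anomalous <- function(curve, fit_range = NULL, regime_tol = 0.05) {
  assert_cols(curve, c("lag_ms", "msd", "n_pairs"), "`curve`")
  if ("axis" %in% names(curve) && length(unique(curve$axis)) > 1) {
    abort("`curve` must contain a single axis; fit each axis separately.")
  }
  if (is.null(fit_range)) fit_range <- c(0, 0.25 * max(curve$lag_ms))
  dat <- curve |> filter(.data$lag_ms >= fit_range[1],
                         .data$lag_ms <= fit_range[2])
  if (nrow(dat) < 4) abort("Need >= 4 lags within `fit_range`.")
  if (any(!is.finite(dat$msd))) abort("MSD values must be finite.")

  t <- dat$lag_ms; y <- dat$msd; w <- dat$n_pairs
  model <- function(p) p[1] * t^p[2] + 2 * p[3]^2
  resid_fn <- function(p) sqrt(w) * (y - model(p))
  lower <- c(0, 1e-6, 0); upper <- c(Inf, 3, Inf)
  d0 <- max((max(y) - min(y)) / max(max(t)^1, 1e-12), 1e-6)
  b0 <- sqrt(max(min(y), 0) / 2)
  best <- NULL
  for (a0 in c(0.5, 1, 1.5, 2)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(d0, a0, b0), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("Anomalous-diffusion fit failed from every start.")
  p <- best$par
  out <- structure(
    list(D_alpha = p[1], alpha = p[2], beta = p[3],
         regime = classify_regime(p[2], regime_tol),
         fit_range = fit_range, residual_norm = sqrt(best$deviance),
         n_lags = nrow(dat), regime_tol = regime_tol,
         axis = if ("axis" %in% names(dat)) dat$axis[1] else NA_character_,
         fitted = tibble(lag_ms = t, msd = y, n_pairs = w,
                         fitted = model(p))),
    class = "anomalous_fit")
  out
}

#' Classify the diffusion regime from the anomalous exponent
#'
#' `alpha < 1 - tol` is subdiffusion, `alpha > 1 + tol` superdiffusion
#' (e.g. the directed exponents 1.67 and 1.74 seen for twisting motion of
#' unliganded and agonist-bound receptors), otherwise Brownian.
#'
#' @param alpha Anomalous exponent, or an `anomalous_fit` object.
#' @param tol Half-width of the Brownian band (default 0.05).
#' @return One of `"subdiffusion"`, `"Brownian"`, `"superdiffusion"`.
#' @export
classify_regime <- function(alpha, tol = 0.05) {
  if (inherits(alpha, "anomalous_fit")) alpha <- alpha$alpha
  if (alpha < 1 - tol) "subdiffusion"
  else if (alpha > 1 + tol) "superdiffusion"
  else "Brownian"
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat("<anomalous_fit>\n")
  cat(sprintf("  msd(t) = %.4g * t^%.3f + 2 * %.3g^2   [%s]\n",
              x$D_alpha, x$alpha, x$beta, x$regime))
  cat(sprintf("  %d lags in [%.3g, %.3g] ms, residual norm %.4g\n",
              x$n_lags, x$fit_range[1], x$fit_range[2], x$residual_norm))
  invisible(x)
}
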