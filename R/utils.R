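#' Angle unit conversions
#'
#' Convert between milliradians, the working unit of every trajectory table in
#' this package, and degrees, used only for reporting. 1 mrad = 180 / (1000 pi)
#' degrees, so e.g. a 10.1 mrad twist is 0.58 degrees.
#'
#' @param x Numeric vector of angles.
#' @return Numeric vector of converted angles.
#' @examples
#' mrad_to_deg(10.1)   # 0.579
#' deg_to_mrad(1)      # 17.45
#' @export
mrad_to_deg <- function(x) x * 180 / (1000 * pi)

#' @rdname mrad_to_deg
#' @export
deg_to_mrad <- function(x) x * 1000 * pi / 180

#' Convert a lag time to an integer frame count
#'
#' DXT recordings are strictly frame-based, so displacement lags must be exact
#' multiples of the frame time. A lag of 1.6 ms at 100 microseconds per frame
#' is 16 frames.
#'
#' @param lag_ms Lag time(s), ms.
#' @param frame_time_us Frame time, microseconds (default 100).
#' @return Integer vector of frame counts.
#' @export
lag_to_frames <- function(lag_ms, frame_time_us = 100) {
  k <- lag_ms * 1000 / frame_time_us
  if (any(!is.finite(k)) || any(k < 1 - 1e-9)) {
    abort("`lag_ms` must be a positive finite multiple of the frame time.")
  }
  if (any(abs(k - round(k)) > 1e-9)) {
    abort("`lag_ms` must be an integer multiple of the frame time.")
  }
  as.integer(round(k))
}

# Deterministic 31-bit substream seed derived from a master seed and an index.
# Keeps per-trajectory randomness reproducible for any subset of indices.
derive_seed <- function(master, i) {
  as.integer((abs(as.numeric(master)) * 48271 + 11 * as.numeric(i)) %% 2147483647)
}

# sum of squared residuals helper
wrss <- function(resid, w = 1) sum(w * resid^2)

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
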