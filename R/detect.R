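#' Subtract background from an image stack
#'
#' `"rolling_median"` removes a per-pixel temporal median (computed over the
#' whole stack when `window` is `NULL` or >= the stack depth is rejected;
#' otherwise a running median of the given odd window length along time);
#' `"constant"` removes a scalar. Results are clipped at 0.
#'
#' @param stack Numeric/integer array `[ny, nx, n_frames]`.
#' @param method `"rolling_median"` or `"constant"`.
#' @param window Odd temporal window length for the rolling median; `NULL`
#'   (default) uses the full stack (static background estimate).
#' @param constant Scalar background level for `method = "constant"`.
#' @return Array of the same shape, background-subtracted and clipped at 0.
#' @export
subtract_background <- function(stack, method = c("rolling_median", "constant"),
                                window = NULL, constant = 0) {
  method <- match.arg(method)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || d[3] < 1) {
    abort("`stack` must be a non-empty [ny, nx, n_frames] array.")
  }
  if (method == "constant") {
    out <- stack - constant
  } else {
    m <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
    if (is.null(window)) {
      bg <- apply(m, 1, median)
      out <- array(m - bg, dim = d)
    } else {
      if (window > d[3]) abort("`window` must not exceed the stack depth.")
      if (window %% 2 == 0) abort("`window` must be odd.")
      bg <- t(apply(m, 1, function(px) runmed(px, window)))
      out <- array(m - bg, dim = d)
    }
  }
  out[out < 0] <- 0
  out
}

#' Detect diffraction spots in a single frame
#'
#' Finds local maxima above `min_intensity` (3x3 neighbourhood), suppresses
#' detections closer than `min_separation` pixels (keeping the brighter), and
#' refines each position to sub-pixel precision by the intensity-weighted
#' centroid of a `(2 * min_separation + 1)^2` window.
#'
#' @param frame Numeric matrix (one background-subtracted image).
#' @param min_intensity Peak-count detection threshold.
#' @param min_separation Minimum distance between detections, pixels (>= 1);
#'   also sets the centroid window half-width.
#' @return A tibble with `x`, `y` (sub-pixel, continuous pixel coordinates)
#'   and `intensity` (integrated window counts); may be empty.
#' @export
detect_spots <- function(frame, min_intensity, min_separation = 3) {
  if (min_separation < 1) abort("`min_separation` must be >= 1.")
  ny <- nrow(frame); nx <- ncol(frame)
  cand <- which(frame > min_intensity, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  }
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1]; c <- cand[k, 2]
    nb <- frame[max(1, r - 1):min(ny, r + 1), max(1, c - 1):min(nx, c + 1)]
    frame[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  }
  vals <- frame[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]

  keep_r <- numeric(0); keep_c <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    if (length(keep_r) > 0 &&
        any((keep_r - r)^2 + (keep_c - c)^2 < min_separation^2)) next
    keep_r <- c(keep_r, r); keep_c <- c(keep_c, c)
  }

  s <- as.integer(min_separation)
  res <- lapply(seq_along(keep_r), function(k) {
    r <- keep_r[k]; c <- keep_c[k]
    rr <- max(1L, r - s):min(ny, r + s)
    cc <- max(1L, c - s):min(nx, c + s)
    w <- pmax(frame[rr, cc, drop = FALSE], 0)
    tot <- sum(w)
    # pixel (r, c) centre is (c - 0.5, r - 0.5)
    list(x = sum(t(w) * (cc - 0.5)) / tot,
         y = sum(w * (rr - 0.5)) / tot,
         intensity = tot)
  })
  tibble(
    x = vapply(res, `[[`, numeric(1), "x"),
    y = vapply(res, `[[`, numeric(1), "y"),
    intensity = vapply(res, `[[`, numeric(1), "intensity")
  )
}

#' Detect spots in every frame of a stack
#'
#' @param stack Array `[ny, nx, n_frames]`.
#' @inheritParams detect_spots
#' @return Tibble with `frame` (0-based), `x`, `y`, `intensity`.
#' @export
detect_stack <- function(stack, min_intensity, min_separation = 3) {
  d <- dim(stack)
  out <- lapply(seq_len(d[3]), function(f) {
    det <- detect_spots(stack[, , f], min_intensity, min_separation)
    if (nrow(det) > 0) det$frame <- f - 1L
    det
  })
  bind_rows(out) |>
    (\(x) if (nrow(x) == 0) tibble(frame = integer(0), x = numeric(0),
                                   y = numeric(0), intensity = numeric(0))
          else select(x, "frame", "x", "y", "intensity"))()
}

#' Link per-frame detections into tracks
#'
#' Greedy frame-to-frame nearest-neighbour assignment: candidate pairs within
#' `max_disp` are assigned in order of increasing distance (ties broken by
#' lower track id, then by detection order after a canonical within-frame sort,
#' which makes linking invariant to the input detection order). Unmatched
#' detections start new tracks; a track ends as soon as it is unmatched (no
#' gap closing, so a track's length is its physical lifetime). Tracks shorter
#' than `min_frames` are discarded and ids renumbered consecutively.
#'
#' @param detections Tibble with `frame` (0-based integer), `x`, `y` and
#'   optionally `intensity`.
#' @param max_disp Maximum frame-to-frame displacement, pixels (> 0).
#' @param min_frames Minimum track length in frames (default 2: a displacement
#'   needs two observations; apply [lifetime_filter()] for the stricter
#'   physical cut).
#' @return Tibble with `track_id`, `frame`, `x_px`, `y_px`, `intensity`.
#' @export
link_tracks <- function(detections, max_disp, min_frames = 2) {
  if (max_disp <= 0) abort("`max_disp` must be > 0.")
  assert_cols(detections, c("frame", "x", "y"), "`detections`")
  if (!"intensity" %in% names(detections)) detections$intensity <- NA_real_
  if (nrow(detections) == 0) {
    return(tibble(track_id = integer(0), frame = integer(0),
                  x_px = numeric(0), y_px = numeric(0), intensity = numeric(0)))
  }
  det <- detections |> arrange(.data$frame, .data$x, .data$y, .data$intensity)
  frames <- sort(unique(det$frame))

  next_id <- 0L
  rows <- vector("list", length(frames))
  active <- NULL  # tibble: track_id, x, y, last_frame
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- det[det$frame == f, ]
    nd <- nrow(cur)
    assigned <- rep(NA_integer_, nd)
    link <- if (!is.null(active)) active[active$last_frame == f - 1L, ] else NULL
    if (!is.null(link) && nrow(link) > 0 && nd > 0) {
      dx <- outer(link$x, cur$x, "-"); dy <- outer(link$y, cur$y, "-")
      dist <- sqrt(dx^2 + dy^2)
      pairs <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        ord <- order(dist[pairs], link$track_id[pairs[, 1]], pairs[, 2])
        used_tr <- logical(nrow(link)); used_det <- logical(nd)
        for (k in ord) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          if (used_tr[i] || used_det[j]) next
          used_tr[i] <- TRUE; used_det[j] <- TRUE
          assigned[j] <- link$track_id[i]
        }
      }
    }
    new <- which(is.na(assigned))
    if (length(new) > 0) {
      assigned[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    rows[[fi]] <- tibble(track_id = assigned, frame = f,
                         x_px = cur$x, y_px = cur$y, intensity = cur$intensity)
    upd <- tibble(track_id = assigned, x = cur$x, y = cur$y, last_frame = f)
    active <- if (is.null(active)) upd else
      bind_rows(active[!active$track_id %in% assigned, ], upd)
  }
  out <- bind_rows(rows)
  keep <- out |> dplyr::count(.data$track_id) |> filter(.data$n >= min_frames)
  out <- out |> filter(.data$track_id %in% keep$track_id) |>
    mutate(track_id = dense_rank(.data$track_id)) |>
    arrange(.data$track_id, .data$frame)
  out
}
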