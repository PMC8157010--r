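acq_small <- acquisition_config(n_frames = 10, image_shape = c(64L, 64L),
                                pixel_size = 600)

test_that("background subtraction removes constant and median backgrounds", {
  set.seed(1)
  clean <- array(rpois(32 * 32 * 5, 3), dim = c(32, 32, 5))
  expect_equal(subtract_background(clean, "constant", constant = 0), clean,
               ignore_attr = TRUE)
  flat <- array(7, dim = c(16, 16, 5))
  expect_true(all(subtract_background(flat, "rolling_median") == 0))
  expect_error(subtract_background(array(1, c(4, 4, 3)), "rolling_median",
                                   window = 5), "stack depth")
  expect_error(subtract_background(array(1, c(4, 4)), "constant"), "array")
})

test_that("median subtraction of a pure-background stack leaves Poisson residue", {
  tr <- tibble::tibble(track_id = integer(0), frame = integer(0),
                       theta_mrad = numeric(0), chi_mrad = numeric(0))
  st <- render_frames(tr, acq_small, background = 50)
  # oracle: the same renderer with background 0 produces all-zero frames
  st0 <- render_frames(tr, acq_small, background = 0)
  expect_true(all(st0 == 0))
  resid <- subtract_background(st, "rolling_median")
  # clipping at zero folds the residual, mean stays below the Poisson floor
  expect_lt(mean(resid), sqrt(50))
})

test_that("spot detection is sub-pixel accurate and suppresses close peaks", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), 10)), 0)
  g <- diffraction_geometry(acq_small)
  # azimuth chosen to keep the spot well inside the detector (edge clipping
  # of the centroid window would otherwise bias the estimate)
  tr <- tibble::tibble(track_id = 1L, frame = 0L,
                       theta_mrad = 0.7, chi_mrad = -800)
  truth <- angles_to_pixel(0.7, -800, g)
  st <- render_frames(tr, acq_small, psf_sigma = 1.5, photon_scale = 5000,
                      background = 0, poisson = FALSE)
  det <- detect_spots(st[, , 1], min_intensity = 500, min_separation = 4)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - truth$x), 0.1)
  expect_lt(abs(det$y - truth$y), 0.1)

  # two peaks 2 px apart with min_separation 5 -> one detection (brighter kept)
  img <- matrix(0, 32, 32)
  img[16, 16] <- 100; img[16, 18] <- 80
  det2 <- detect_spots(img, min_intensity = 10, min_separation = 5)
  expect_equal(nrow(det2), 1)
  # oracle: brute-force pairwise separation check
  expect_true(all(dist(cbind(det2$x, det2$y)) >= 5 | nrow(det2) < 2))
})

test_that("linking follows an unambiguous drifting spot", {
  det <- tibble::tibble(frame = 0:9, x = 10 + 0.5 * (0:9), y = 20 - 0.3 * (0:9),
                        intensity = 100)
  tk <- link_tracks(det, max_disp = 2)
  expect_equal(dplyr::n_distinct(tk$track_id), 1)
  expect_equal(nrow(tk), 10)
  expect_equal(tk$frame, 0:9)
})

test_that("well-separated spots never swap identities", {
  set.seed(2)
  # two spots always > 2 * max_disp apart; ground truth by construction
  f <- 0:19
  det <- dplyr::bind_rows(
    tibble::tibble(frame = f, x = 10 + cumsum(rnorm(20, 0, 0.3)),
                   y = 10 + cumsum(rnorm(20, 0, 0.3)), truth = 1),
    tibble::tibble(frame = f, x = 40 + cumsum(rnorm(20, 0, 0.3)),
                   y = 40 + cumsum(rnorm(20, 0, 0.3)), truth = 2))
  tk <- link_tracks(det |> dplyr::mutate(intensity = 1), max_disp = 3)
  expect_equal(dplyr::n_distinct(tk$track_id), 2)
  joined <- dplyr::inner_join(tk, det, by = c("frame", "x_px" = "x", "y_px" = "y"))
  swap <- joined |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(n_ids = dplyr::n_distinct(truth))
  expect_true(all(swap$n_ids == 1))
})

test_that("linking recovers 1291 sparse non-overlapping tracks", {
  set.seed(3)
  n_tracks <- 1291
  grid <- expand.grid(gx = 1:37, gy = 1:35)[seq_len(n_tracks), ]
  det <- dplyr::bind_rows(lapply(seq_len(n_tracks), function(i) {
    tibble::tibble(frame = 0:7,
                   x = grid$gx[i] * 10 + cumsum(runif(8, -0.4, 0.4)),
                   y = grid$gy[i] * 10 + cumsum(runif(8, -0.4, 0.4)),
                   intensity = 1)
  }))
  tk <- link_tracks(det, max_disp = 2)
  expect_equal(dplyr::n_distinct(tk$track_id), n_tracks)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(4)
  det <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(frame = 0:9, x = i * 15 + cumsum(rnorm(10, 0, 0.5)),
                   y = i * 7 + cumsum(rnorm(10, 0, 0.5)), intensity = i)
  }))
  shuffled <- det[sample(nrow(det)), ]
  t1 <- link_tracks(det, max_disp = 3)
  t2 <- link_tracks(shuffled, max_disp = 3)
  expect_equal(t1, t2)
})

test_that("every retained detection belongs to exactly one track", {
  set.seed(5)
  det <- tibble::tibble(frame = rep(0:9, each = 4),
                        x = rep(c(5, 20, 35, 50), 10) + rnorm(40, 0, 0.3),
                        y = rep(c(5, 20, 35, 50), 10) + rnorm(40, 0, 0.3),
                        intensity = 1)
  tk <- link_tracks(det, max_disp = 2)
  expect_equal(nrow(tk), nrow(dplyr::distinct(tk, frame, x_px, y_px)))
  expect_equal(nrow(tk), 40)
  expect_lte(max(table(paste(tk$frame, tk$x_px, tk$y_px))), 1)
})

test_that("short tracks are discarded by min_frames", {
  det <- tibble::tibble(frame = c(0L, 1L, 2L, 5L), x = c(1, 1, 1, 30),
                        y = c(1, 1, 1, 30), intensity = 1)
  tk <- link_tracks(det, max_disp = 2, min_frames = 2)
  expect_equal(dplyr::n_distinct(tk$track_id), 1)
  expect_equal(nrow(tk), 3)
})

test_that("tiff round trip preserves count stacks", {
  set.seed(6)
  st <- array(sample(0:4000, 16 * 16 * 3, replace = TRUE), dim = c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frames(st, path)
  expect_equal(read_frames(path), st, ignore_attr = TRUE)
})
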