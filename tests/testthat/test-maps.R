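sample_tbl <- function(d_theta, d_chi, lag = 1) {
  out <- tibble::tibble(track_id = seq_along(d_chi),
                        d_theta_mrad = d_theta, d_chi_mrad = d_chi)
  attr(out, "lag_ms") <- lag
  out
}

test_that("two-axis maps conserve probability mass", {
  m1 <- two_axis_map(sample_tbl(0.5, -3))
  expect_equal(sum(m1$density), 1, tolerance = 1e-12)
  expect_equal(sum(m1$density == 1), 1)  # single point, one cell

  set.seed(5)
  m <- two_axis_map(sample_tbl(rnorm(500, sd = 10), rnorm(500, sd = 15)))
  expect_equal(sum(m$density), 1, tolerance = 1e-9)
  expect_true(all(m$density >= 0))
  expect_error(two_axis_map(sample_tbl(numeric(0), numeric(0))), "non-empty")
  expect_error(two_axis_map(sample_tbl(1, 1), chi_edges = c(0, 0, 1)),
               "strictly increasing")
})

test_that("binning equals brute-force point-in-cell counting", {
  set.seed(6)
  n <- 1000
  dth <- rnorm(n, sd = 8); dch <- rnorm(n, sd = 12)
  m <- two_axis_map(sample_tbl(dth, dch))
  counts <- brute_bin(dth, dch, chi_bin_edges(), theta_bin_edges())
  expect_equal(m$density, counts / n, tolerance = 1e-12)
})

test_that("a clockwise-drift cohort concentrates at negative twist, high tilt", {
  pop <- population_spec(weight = 1, D_theta = 1, D_chi = 1,
                         drift_theta = 3, drift_chi = -10.1,
                         lifetime_mean = Inf)
  tr <- simulate_trajectories(pop, 300, acquisition_config(n_frames = 11),
                              seed = 15)
  m <- two_axis_map(displacement_sample(tr, 1.0))
  cells <- tidy(m)
  cw_mass <- sum(cells$density[cells$chi_mid < 0])
  expect_gt(cw_mass, 0.95)
  high_theta <- sum(cells$density[cells$theta_mid > 1])
  expect_gt(high_theta, 0.8)
})

test_that("map subtraction is zero-sum, self-cancelling and grid-checked", {
  set.seed(8)
  a <- two_axis_map(sample_tbl(rnorm(400, sd = 5), rnorm(400, sd = 8)), )
  b <- two_axis_map(sample_tbl(rnorm(300, sd = 5), rnorm(300, 2, 8)))
  s <- subtract_maps(a, b)
  expect_equal(sum(s$difference), 0, tolerance = 1e-9)
  self <- subtract_maps(a, a)
  expect_true(all(self$difference == 0))
  odd <- two_axis_map(sample_tbl(rnorm(300), rnorm(300)),
                      chi_edges = seq(-10, 10, 1))
  expect_error(subtract_maps(a, odd), "identical bin edges")
})

test_that("an unliganded-like minus agonist-like map is positive in the CW tail", {
  acq <- acquisition_config(n_frames = 11)
  un <- simulate_trajectories(condition_populations("unliganded"), 4000, acq,
                              seed = 17)
  un <- dplyr::mutate(un, track_id = track_id)
  ag <- simulate_trajectories(condition_populations("agonist"), 4000, acq,
                              seed = 18)
  ma <- two_axis_map(displacement_sample(un, 1.0), label = "unliganded")
  mb <- two_axis_map(displacement_sample(ag, 1.0), label = "agonist")
  s <- subtract_maps(ma, mb)
  cells <- tidy(s)
  cw_cells <- cells[cells$chi_mid < -5 & is.finite(cells$chi_mid), ]
  occupied <- cw_cells[abs(cw_cells$difference) > 0, ]
  expect_gt(nrow(occupied), 0)
  expect_true(all(occupied$difference > 0))
  expect_true(all(s$dominant[s$difference > 0] == "unliganded"))
})

test_that("mirroring the twist axis mirrors maps about chi = 0", {
  set.seed(9)
  dth <- rnorm(300, sd = 5); dch <- rnorm(300, -3, 6)
  m <- two_axis_map(sample_tbl(dth, dch))
  mm <- two_axis_map(sample_tbl(dth, -dch))
  expect_equal(mm$density, m$density[, rev(seq_len(ncol(m$density)))],
               tolerance = 1e-12)
})

test_that("time-course series share binning and scale drift peaks with lag", {
  pop <- population_spec(weight = 1, drift_chi = -10.1, lifetime_mean = Inf)
  tr <- simulate_trajectories(pop, 100, acquisition_config(n_frames = 17),
                              seed = 25)
  tc <- timecourse_series(tr, c(1.0, 1.6), op = "chi_histogram")
  peak <- tc |>
    dplyr::group_by(lag_ms) |>
    dplyr::summarise(mode = mid[which.max(density)])
  # pure drift: peak bin centre tracks v * t (-10.1 then -16.16 mrad)
  expect_equal(peak$mode[peak$lag_ms == 1.0], -10.5, tolerance = 1)
  expect_equal(peak$mode[peak$lag_ms == 1.6], -16.5, tolerance = 1)

  maps <- timecourse_series(tr, c(0.5, 1.0), op = "two_axis_map")
  expect_equal(nrow(maps), 2)
  expect_s3_class(maps$map[[1]], "two_axis_map")
  # static cohort: identical maps at all lags
  stat <- simulate_trajectories(population_spec(weight = 1, lifetime_mean = Inf),
                                50, acquisition_config(n_frames = 17), seed = 26)
  ms <- timecourse_series(stat, c(0.5, 1.0), op = "two_axis_map")
  expect_equal(ms$map[[1]]$density, ms$map[[2]]$density)
  # single lag -> singleton series; invalid lag rejects the whole series
  expect_equal(nrow(timecourse_series(tr, 1.0, op = "two_axis_map")), 1)
  expect_error(timecourse_series(tr, c(1.0, 1.55)), "multiple|increasing")
  expect_error(timecourse_series(tr, c(1.0, 0.5)), "increasing")
})
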