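test_that("lifetime filter partitions tracks per the stated window", {
  # lifetimes 0.1..1.0 ms in 0.1 steps: oracle count of >= 0.5 ms is 6
  trajs <- dplyr::bind_rows(lapply(1:10, function(i) {
    traj_tbl(rep(0, i), rep(0, i), id = i)
  }))
  fl <- lifetime_filter(trajs)
  expect_equal(fl$long_count, 6)
  expect_equal(fl$short_count, 4)
  expect_equal(fl$other_count, 0)
  expect_setequal(unique(fl$kept$track_id), 5:10)
  # partition: kept and removed are disjoint and exhaustive
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(trajs))
  expect_length(intersect(fl$kept$track_id, fl$removed$track_id), 0)
  # idempotence on the kept set
  fl2 <- lifetime_filter(fl$kept)
  expect_identical(fl2$kept, fl$kept)
  expect_equal(fl2$short_count, 0)

  empty <- lifetime_filter(trajs[0, ])
  expect_equal(empty$short_count + empty$long_count, 0)
  expect_error(lifetime_filter(trajs, drop_max = 0.6), "drop_max < keep_min")
})

test_that("calibrated lifetime distribution reproduces the 2.5 short:long ratio", {
  tr <- simulate_trajectories(default_populations(), 10000,
                              acquisition_config(), seed = 11)
  fl <- lifetime_filter(tr)
  # oracle: direct counting on the simulated set
  lt <- track_lifetimes(tr)
  expect_equal(fl$short_count, sum(lt$lifetime_ms <= 0.4))
  expect_equal(fl$long_count, sum(lt$lifetime_ms >= 0.5 & lt$lifetime_ms <= 10))
  expect_equal(fl$ratio_short_to_long, 2.5, tolerance = 0.2 / 2.5)
})

test_that("fast MSD path equals the naive quadratic oracle", {
  expect_equal(time_avg_msd(traj_tbl(rep(0, 4), c(0, 1, 2, 3)), "chi")$msd,
               c(1, 4, 9))
  expect_true(all(time_avg_msd(traj_tbl(rep(1, 6), rep(-2, 6)), "both")$msd == 0))
  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:64, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    fast <- time_avg_msd(traj_tbl(x, x), "theta")$msd
    expect_equal(fast, naive_msd(x), tolerance = 1e-10)
  }
})

test_that("MSD curves have non-increasing pair counts and correct lags", {
  x <- rnorm(30)
  cv <- time_avg_msd(traj_tbl(x, x), "chi")
  expect_true(all(diff(cv$n_pairs) <= 0))
  expect_equal(cv$n_pairs, 30 - seq_len(29))
  expect_equal(cv$lag_ms, seq_len(29) * 0.1)
  expect_error(time_avg_msd(traj_tbl(x, x), "chi", max_lag_frames = 30),
               "max_lag_frames")
})

test_that("ensemble MSD equals the pooled squared-displacement mean", {
  set.seed(4)
  trajs <- dplyr::bind_rows(lapply(1:5, function(i) {
    n <- sample(5:20, 1)
    traj_tbl(rnorm(n), rnorm(n), id = i)
  }))
  ens <- ensemble_msd(time_avg_msd(trajs, "chi"))
  # oracle: brute-force pooled mean over every (i, i+k) pair of every track
  xs <- split(trajs$chi_mrad, trajs$track_id)
  for (k in 1:4) {
    sq <- unlist(lapply(xs, function(x) {
      if (length(x) <= k) return(NULL)
      i <- seq_len(length(x) - k)
      (x[i + k] - x[i])^2
    }))
    got <- ens$msd[abs(ens$lag_ms - k * 0.1) < 1e-9]
    expect_equal(got, mean(sq), tolerance = 1e-12)
  }
  # single curve -> itself
  one <- time_avg_msd(traj_tbl(rnorm(8), rnorm(8)), "chi")
  expect_equal(ensemble_msd(one)$msd, one$msd)
  expect_error(ensemble_msd(one[0, ]), "non-empty")
})

test_that("anomalous fit recovers Brownian, ballistic and noisy parameters", {
  lag <- seq(0.1, 2.5, by = 0.1)
  brown <- tibble::tibble(lag_ms = lag, msd = 4 * lag, n_pairs = 100)
  fb <- fit_anomalous(brown, fit_range = c(0, 2.5))
  expect_equal(fb$alpha, 1, tolerance = 0.02)
  expect_equal(fb$D_alpha, 4, tolerance = 0.1 / 4)
  expect_lt(fb$beta, 0.05)
  expect_equal(fb$regime, "Brownian")

  ball <- tibble::tibble(lag_ms = lag, msd = 100 * lag^2, n_pairs = 100)
  fba <- fit_anomalous(ball, fit_range = c(0, 2.5))
  expect_equal(fba$alpha, 2, tolerance = 0.02 / 2)
  expect_equal(fba$regime, "superdiffusion")

  # known measurement error enters as the 2 beta^2 intercept
  noisy <- tibble::tibble(lag_ms = lag, msd = 2 * lag + 2 * 0.5^2, n_pairs = 100)
  fn <- fit_anomalous(noisy, fit_range = c(0, 2.5))
  expect_equal(fn$beta, 0.5, tolerance = 0.05)

  expect_error(fit_anomalous(brown[1:3, ], fit_range = c(0, 2.5)), ">= 4")
})

test_that("fitted beta recovers the generating measurement error", {
  pop <- population_spec(weight = 1, D_chi = 1, lifetime_mean = Inf)
  tr <- simulate_trajectories(pop, 1000, acquisition_config(n_frames = 50),
                              noise_beta = 0.8, seed = 21)
  ens <- ensemble_msd(time_avg_msd(tr, "chi"))
  fit <- fit_anomalous(ens)
  expect_equal(fit$beta, 0.8, tolerance = 0.15)
  expect_equal(fit$D_alpha, 2, tolerance = 0.15)
})

test_that("the anomalous fit is scale-equivariant", {
  lag <- seq(0.1, 2.0, by = 0.1)
  set.seed(9)
  base <- tibble::tibble(lag_ms = lag,
                         msd = 3 * lag^1.3 + 0.4 + rnorm(20, sd = 0.02),
                         n_pairs = rep(c(50, 40, 30, 20), each = 5))
  f1 <- fit_anomalous(base, fit_range = c(0, 2))
  f2 <- fit_anomalous(dplyr::mutate(base, msd = msd * 7), fit_range = c(0, 2))
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$D_alpha, 7 * f1$D_alpha, tolerance = 1e-6)
  expect_equal(f2$beta^2, 7 * f1$beta^2, tolerance = 1e-6)
})

test_that("regime classification uses the alpha band", {
  expect_equal(classify_regime(0.5), "subdiffusion")
  expect_equal(classify_regime(1.0), "Brownian")
  expect_equal(classify_regime(1.67), "superdiffusion")
  expect_equal(classify_regime(1.74), "superdiffusion")
  expect_equal(classify_regime(1.04), "Brownian")
  expect_equal(classify_regime(0.94), "subdiffusion")
})

test_that("confined motion saturates below the confinement span", {
  pop <- population_spec(weight = 1, D_theta = 1.3, D_chi = 1.3,
                         confinement_radius = 3, lifetime_mean = Inf,
                         start_dispersion = 0)
  tr <- simulate_trajectories(pop, 200, acquisition_config(n_frames = 100),
                              seed = 31)
  ens <- ensemble_msd(time_avg_msd(tr, "chi"))
  fit <- fit_anomalous(ens)
  expect_equal(fit$regime, "subdiffusion")
  expect_true(all(ens$msd < 36))  # below (confinement diameter)^2
})
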