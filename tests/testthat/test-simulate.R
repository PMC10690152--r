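test_that("fBm simulation is seed-deterministic and exact at alpha = 1", {
  a <- simulate_fbm(0.5, 0.05, N = 200, tau = 1 / 60, seed = 3)
  b <- simulate_fbm(0.5, 0.05, N = 200, tau = 1 / 60, seed = 3)
  expect_identical(a$positions, b$positions)
  expect_true(attr(a, "sim_method") %in% c("circulant", "cholesky"))

  # alpha = 1: increments are independent -> lag-1 autocorrelation near 0
  set.seed(17)
  ac <- replicate(200, {
    tr <- simulate_fbm(1, 0.1, N = 100, tau = 1 / 60)
    inc <- diff(tr$positions[, 1])
    cor(inc[-1], inc[-length(inc)])
  })
  expect_lt(abs(mean(ac)), 3 / sqrt(200 * 99))
})

test_that("static noise shifts the ensemble MSD by 2 d sigma^2", {
  set.seed(31)
  sigma <- 0.1
  msds <- replicate(300, {
    tr <- simulate_fbm(0.5, 0.02, N = 80, tau = 1 / 60)
    empirical_msd(add_static_noise(tr, sigma), max_lag = 10)$msd
  })
  emp <- rowMeans(msds)
  se <- apply(msds, 1, sd) / sqrt(ncol(msds))
  theory <- noisy_fbm_msd(0.5, 0.02, sigma, (1:10) / 60, d = 2)
  expect_true(all(abs(emp - theory) < 4 * se))
  # sigma = 0 is the identity
  tr <- simulate_fbm(0.5, 0.02, N = 50, tau = 1 / 60, seed = 1)
  expect_identical(add_static_noise(tr, 0)$positions, tr$positions)
})

test_that("full-shutter motion blur cuts the Brownian lag-1 MSD toward 2/3", {
  set.seed(41)
  S <- 30L
  ratio <- replicate(300, {
    fine <- simulate_fbm(1, 0.1, N = 40L * S, tau = (1 / 60) / S)
    blur <- add_dynamic_blur(fine, substeps = S, shutter_fraction = 1)
    empirical_msd(blur, max_lag = 1)$msd
  })
  theory <- fbm_msd(1, 0.1, 1 / 60, d = 2)
  expect_equal(mean(ratio) / theory, 2 / 3, tolerance = 0.05)
  # long-lag asymptotics unchanged by blur
  set.seed(42)
  long_ratio <- replicate(100, {
    fine <- simulate_fbm(1, 0.1, N = 40L * S, tau = (1 / 60) / S)
    blur <- add_dynamic_blur(fine, substeps = S, shutter_fraction = 1)
    empirical_msd(blur, max_lag = 15)$msd[15] /
      fbm_msd(1, 0.1, 15 / 60, d = 2)
  })
  expect_equal(mean(long_ratio), 1, tolerance = 0.05)
  # shutter_fraction -> 0 recovers point samples
  fine <- simulate_fbm(0.7, 0.1, N = 20L * S, tau = (1 / 60) / S, seed = 9)
  pt <- add_dynamic_blur(fine, substeps = S, shutter_fraction = 1e-9)
  expect_equal(pt$positions, fine$positions[seq(1, 20L * S + 1L, by = S), ],
               ignore_attr = TRUE)
  expect_error(add_dynamic_blur(fine, substeps = 7L, shutter_fraction = 1),
               "substeps")
})

test_that("linear drift behaves as v t and is recoverable", {
  const <- trajectory_record(matrix(0, 60, 2), tau = 0.5)
  drift <- add_drift(const, c(0.2, -0.1))
  # pure drift: MSD(t) = |v|^2 t^2
  msd <- empirical_msd(drift, max_lag = 5)
  expect_equal(msd$msd, (0.2^2 + 0.1^2) * msd$time^2)
  expect_identical(add_drift(const, c(0, 0))$positions, const$positions)
})

test_that("stuck beads live on the noise floor", {
  set.seed(55)
  sigma <- 0.05
  msds <- replicate(200, empirical_msd(
    simulate_stuck_bead(sigma, N = 60, tau = 1 / 60), max_lag = 10)$msd)
  emp <- rowMeans(msds)
  # flat at 2 d sigma^2 across lags
  expect_true(all(abs(emp / (4 * sigma^2) - 1) < 0.1))

  # LS exponent over the full band stays below the 0.1 noise-floor cutoff
  set.seed(56)
  alphas <- replicate(60, {
    tr <- simulate_stuck_bead(0.05, N = 300, tau = 1 / 60)
    ls_fit(empirical_msd(tr))$alpha
  })
  expect_gte(mean(alphas < 0.1), 0.95)

  expect_equal(max(abs(simulate_stuck_bead(0, N = 10, tau = 1)$positions)), 0)
})

test_that("ensemble generator honors weights and returns exact ground truth", {
  specs <- list(water_like_spec(0.5), flake_like_spec(0.5))
  sim <- simulate_ensemble(specs, M = 60, N = 30, tau = 1 / 60, seed = 77,
                           n_stuck = 6)
  expect_length(sim$trajectories, 66)
  expect_equal(sum(sim$truth$label == "noise_floor"), 6)
  # within-range truncated draws
  sig <- sim$truth[sim$truth$label != "noise_floor", ]
  expect_true(all(sig$alpha > 0 & sig$alpha <= 1 & sig$D_alpha > 0))
  # determinism
  sim2 <- simulate_ensemble(specs, M = 60, N = 30, tau = 1 / 60, seed = 77,
                            n_stuck = 6)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$trajectories[[10]]$positions,
                   sim2$trajectories[[10]]$positions)
  expect_error(simulate_ensemble(list(cluster_spec(0, c(0.5, 0.1),
                                                   c(0, 0), "z")),
                                 M = 2, N = 10), "zero")

  # label proportions follow the weights (binomial CI)
  set.seed(78)
  big <- simulate_ensemble(specs, M = 400, N = 3, tau = 1 / 60)
  p <- mean(big$truth$label == "water_like")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 400))

  # cluster means within CI of the study-condition specs
  set.seed(79)
  pts <- draw_cluster_points(water_like_spec(), 200)
  expect_lt(abs(mean(pts[, 1]) - 0.85), 3 * 0.03 / sqrt(200))
  pts_f <- draw_cluster_points(flake_like_spec(), 200)
  expect_lt(abs(mean(pts_f[, 1]) - 0.3), 3 * 0.07 / sqrt(200))
})
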