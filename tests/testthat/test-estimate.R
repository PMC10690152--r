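test_that("LS fit is exact on a pure power-law MSD", {
  tt <- (1:60) / 60
  msd <- data.frame(time = tt, msd = 2 * 2 * 0.1 * tt^0.6)
  fit <- ls_fit(msd, d = 2)
  expect_equal(fit$alpha, 0.6, tolerance = 1e-10)
  expect_equal(fit$D_alpha, 0.1, tolerance = 1e-10)
  expect_error(ls_fit(msd, bandwidth = c(0.01, 0.02)), "3 lags")
})

test_that("LS on the analytic noise-contaminated MSD is biased toward
           smaller exponents (sign fixed by the closed-form oracle)", {
  # oracle: OLS on the exact curve 2 d D t^a + 2 d sigma^2; the local
  # log-log slope a * signal / (signal + offset) is everywhere below a,
  # so the fitted slope must under-estimate alpha.
  tt <- seq(0.1, 2, by = 1 / 60)
  curve <- data.frame(time = tt,
                      msd = noisy_fbm_msd(0.3, 0.05, 0.05, tt, d = 2))
  oracle <- coef(lm(log(curve$msd) ~ log(curve$time)))[2]
  expect_lt(oracle, 0.3)
  fit <- ls_fit(curve, bandwidth = c(0.1, 2), d = 2)
  expect_equal(fit$alpha, unname(oracle), tolerance = 1e-10)
  expect_lt(fit$alpha, 0.3)
})

test_that("fARMAs recovers clean subdiffusive fBm within its standard errors", {
  set.seed(301)
  n_rep <- 20
  ses <- alphas <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_fbm(0.5, 0.05, N = 600, tau = 1 / 60)
    f <- farmas_fit(tr)
    alphas[i] <- f$alpha
    ses[i] <- sqrt(f$cov_alpha_logD[1, 1])
  }
  ok <- is.finite(ses)
  expect_gte(mean(ok), 0.8)
  expect_gte(mean(abs(alphas[ok] - 0.5) <= 2 * ses[ok]), 0.85)
  expect_lt(abs(mean(alphas) - 0.5), 0.03)
})

test_that("fARMAs denoises the low-SNR flake scenario better than LS", {
  # noise-floor-dominated short lags: 2 d sigma^2 = 0.04 um^2 against a
  # signal of 0.059 um^2 at the first lag
  set.seed(302)
  n_rep <- 10
  err_f <- err_ls <- numeric(n_rep)
  track_ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- add_static_noise(simulate_fbm(0.3, 0.05, N = 1800, tau = 1 / 60),
                           0.1)
    ls <- ls_fit(empirical_msd(tr))     # full-band LS
    f <- farmas_fit(tr, init = ls, compute_cov = FALSE)
    err_ls[i] <- ls$alpha - 0.3
    err_f[i] <- f$alpha - 0.3
    # the denoised curve should track the pure signal, not the
    # contaminated MSD, at short lags where the noise floor dominates
    t_short <- 1 / 60
    pure <- fbm_msd(0.3, 0.05, t_short, d = 2)
    contaminated <- noisy_fbm_msd(0.3, 0.05, 0.1, t_short, d = 2)
    track_ok[i] <- abs(implied_msd(f, t_short) - pure) <
      abs(implied_msd(f, t_short) - contaminated)
  }
  expect_lt(sqrt(mean(err_f^2)), sqrt(mean(err_ls^2)))
  expect_gte(mean(track_ok), 0.7)
})

test_that("fARMAs handles the Brownian boundary", {
  set.seed(303)
  alphas <- replicate(8, {
    tr <- add_static_noise(simulate_fbm(1, 0.2, N = 600, tau = 1 / 60), 0.02)
    farmas_fit(tr, compute_cov = FALSE)$alpha
  })
  # alpha is capped at 1, so estimation error is one-sided; the mean sits
  # just below the boundary
  expect_gte(mean(alphas), 0.93)
  expect_gte(mean(alphas >= 0.9), 0.75)
})

test_that("classifier covariance is symmetric PSD and shrinks with N", {
  set.seed(304)
  v_small <- replicate(6, {
    f <- farmas_fit(simulate_fbm(0.5, 0.05, N = 300, tau = 1 / 60))
    f$cov_alpha_logD[1, 1]
  })
  v_big <- replicate(6, {
    f <- farmas_fit(simulate_fbm(0.5, 0.05, N = 1200, tau = 1 / 60))
    f$cov_alpha_logD[1, 1]
  })
  expect_lt(median(v_big), median(v_small))
  f <- farmas_fit(simulate_fbm(0.4, 0.05, N = 400, tau = 1 / 60))
  V <- classifier_covariance(f)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values > 0))
})

test_that("nominal 95% intervals for alpha have near-nominal coverage", {
  set.seed(305)
  n_rep <- 40
  cover <- rep(NA, n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_fbm(0.5, 0.05, N = 600, tau = 1 / 60)
    f <- farmas_fit(tr)
    se <- sqrt(f$cov_alpha_logD[1, 1])
    if (is.finite(se)) cover[i] <- abs(f$alpha - 0.5) <= qnorm(0.975) * se
  }
  expect_gte(mean(cover, na.rm = TRUE), 0.85)  # 95% nominal, 40 reps
})

test_that("likelihood at the truth is a local maximum on large samples", {
  set.seed(306)
  tr <- simulate_fbm(0.5, 0.05, N = 1500, tau = 1 / 60)
  Y <- apply(tr$positions, 2, diff)
  nll0 <- pptmstats:::.nll_profile(c(0.5, 0, -20), Y, 1 / 60)
  for (da in c(-0.1, 0.1))
    expect_gt(pptmstats:::.nll_profile(c(0.5 + da, 0, -20), Y, 1 / 60), nll0)
})

test_that("drift is estimated and removable", {
  set.seed(307)
  tr <- add_drift(simulate_fbm(0.8, 0.1, N = 900, tau = 1 / 60),
                  c(0.05, -0.02))
  dd <- remove_drift(tr)
  expect_equal(dd$velocity, c(0.05, -0.02), tolerance = 0.25)
  # constant trajectory is unchanged (slope and residual trend are zero)
  const <- trajectory_record(matrix(1.5, 50, 2), tau = 0.1)
  expect_equal(max(abs(remove_drift(const)$trajectory$positions)), 0)
  # the likelihood's increment-mean drift estimate also recovers v
  f <- farmas_fit(tr, compute_cov = FALSE)
  expect_equal(f$drift, c(0.05, -0.02), tolerance = 0.3)
})

test_that("covariance of (alpha, log Delta) at 1 s equals that of
           (alpha, log D_alpha)", {
  # log Delta(1 s) = log(2 d) + log D_alpha: a constant offset, so the
  # covariance is unchanged under the transform
  set.seed(308)
  f <- farmas_fit(simulate_fbm(0.6, 0.1, N = 400, tau = 1 / 60))
  A <- matrix(c(1, 0, 0, 1), 2)      # Jacobian of the offset map
  expect_equal(A %*% f$cov_alpha_logD %*% t(A), f$cov_alpha_logD,
               ignore_attr = TRUE)
  expect_equal(log(delta_at(f)), log(2 * 2) + log(f$D_alpha))
})
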