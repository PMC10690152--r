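# Well-separated two-cluster data in the classifier plane (alpha, log Delta)
# at the water-like and flake-like locations; Gaussian in the clustered
# coordinates (the mixture model's own generative assumption), with log
# Delta spreads from the delta method on the D_alpha spreads.
two_phase_points <- function(M_each, seed) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(M_each, 0.85, 0.03),
                     rnorm(M_each, log(1.4), 0.02 / 0.35)),
               cbind(rnorm(M_each, 0.30, 0.07),
                     rnorm(M_each, log(0.2), 0.02 / 0.05)))
  colnames(pts) <- c("alpha", "logDelta")
  list(points = pts, truth = rep(1:2, each = M_each))
}

test_that("K = 1 fit is the sample mean and constraint-projected covariance", {
  set.seed(71)
  pts <- matrix(rnorm(400), 200, 2)
  for (con in c("full-varying", "diagonal-varying", "spherical-equal")) {
    m <- fit_mixture(pts, K = 1, constraint = con)
    expect_equal(as.numeric(m$means), colMeans(pts), tolerance = 1e-6)
  }
  m_full <- fit_mixture(pts, K = 1, constraint = "full-varying")
  expect_equal(m_full$covariances[, , 1], cov(pts) * (199 / 200),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_mixture(pts[1, , drop = FALSE], K = 2), "at least K")
})

test_that("well-separated clusters are recovered exactly (ARI = 1)", {
  fp <- two_phase_points(40, seed = 72)
  m <- fit_mixture(fp$points, K = 2)
  lab <- posterior_assign(m, fp$points)$label
  expect_equal(mclust::adjustedRandIndex(lab, fp$truth), 1)
})

test_that("BIC selection finds the right structure", {
  # two-cluster data: K = 2 selected, assignment correct
  fp <- two_phase_points(40, seed = 73)
  sel <- select_model(fp$points, Kmax = 4)
  expect_equal(sel$K, 2L)
  lab <- posterior_assign(sel, fp$points)$label
  expect_equal(mclust::adjustedRandIndex(lab, fp$truth), 1)
  # selected BIC is minimal over all fitted candidates
  expect_true(all(sel$bic <= sel$bic_table$bic + 1e-8))

  # single-Gaussian data: K = 1 selected in >= 90% of replicates
  set.seed(74)
  picks <- replicate(20, {
    pts <- cbind(rnorm(200, 0.5, 0.05), rnorm(200, 0, 0.3))
    select_model(pts, Kmax = 3)$K
  })
  expect_gte(mean(picks == 1L), 0.9)

  # Kmax = 1 forces K = 1
  expect_equal(select_model(fp$points, Kmax = 1)$K, 1L)
})

test_that("posterior probabilities are proper and tie-broken low", {
  fp <- two_phase_points(30, seed = 75)
  m <- fit_mixture(fp$points, K = 2)
  post <- posterior_assign(m, fp$points)
  expect_equal(rowSums(post$prob), rep(1, nrow(fp$points)))
  # point at a component mean of a well-separated model is assigned there
  mu1 <- m$means[1, , drop = FALSE]
  p1 <- posterior_assign(m, mu1)
  expect_equal(p1$label, 1L)
  expect_gt(p1$prob[1, 1], 0.99)
  # exactly equidistant point between identical components -> lower index
  twin <- fit_mixture(rbind(fp$points, fp$points + 10), K = 2)
  mid <- matrix(colMeans(twin$means), 1)
  pm <- posterior_assign(twin, mid)
  expect_equal(pm$label, which.max(pm$prob[1, ]))
})

test_that("full-covariance clustering is invariant under the classifier
           affine map; constrained families need not be", {
  # (alpha, log Delta) -> (alpha, log Dtilde): a shear by log t*
  ctx <- water_ctx(1)
  ts <- t_star(ctx); r_um <- ctx$radius * 1e6
  shear <- function(p) cbind(p[, 1], p[, 2] + p[, 1] * log(ts) -
                                      log(16 * r_um^2))
  fp <- two_phase_points(40, seed = 76)
  m_a <- fit_mixture(fp$points, K = 2, constraint = "full-varying")
  m_b <- fit_mixture(shear(fp$points), K = 2, constraint = "full-varying")
  la <- posterior_assign(m_a, fp$points)$label
  lb <- posterior_assign(m_b, shear(fp$points))$label
  expect_equal(mclust::adjustedRandIndex(la, lb), 1)

  # a diagonal-constraint case where the two classifier scales disagree:
  # overlapping clusters elongated along the shear direction
  set.seed(4)
  pts <- rbind(cbind(rnorm(60, 0.45, 0.08), rnorm(60, -0.5, 0.25)),
               cbind(rnorm(60, 0.62, 0.08), rnorm(60, 0.3, 0.25)))
  da <- posterior_assign(fit_mixture(pts, 2, "diagonal-varying"), pts)$label
  db <- posterior_assign(fit_mixture(shear(pts), 2, "diagonal-varying"),
                         shear(pts))$label
  expect_lt(mclust::adjustedRandIndex(da, db), 1)
})
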