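test_that("Delta evaluates the denoised MSD at the reference time", {
  f <- fbm_classifier(0.85, 0.35)
  expect_equal(delta_at(f), 1.4)
  # at t = 1 s the exponent is annihilated: Delta = 2 d D_alpha
  g <- fbm_classifier(0.123, 0.07)
  expect_equal(delta_at(g), 4 * 0.07)
  expect_lt(delta_at(g, t = 0.1), delta_at(g, t = 1))
  expect_error(delta_at(g, t = -1), "positive")
})

test_that("t* reproduces the printed bead-size reference times", {
  expect_equal(t_star(water_ctx(1)), 2.33, tolerance = 2e-3)
  expect_equal(t_star(water_ctx(0.2)), 0.0187, tolerance = 2e-3)
  # t* scales as r^3: factor 125 between 1 um and 200 nm
  expect_equal(t_star(water_ctx(1)) / t_star(water_ctx(0.2)), 125)
})

test_that("Dtilde identity and affine structure hold", {
  ctx <- water_ctx(1)
  # a bead diffusing in the reference fluid itself: Dtilde = 1 exactly
  f_w <- fbm_classifier(1, water_diffusivity(ctx))
  expect_equal(dtilde(f_w, ctx), 1, tolerance = 1e-12)
  # identity holds for every radius / temperature / viscosity
  for (ctx2 in list(water_ctx(0.2), material_context(2e-6, 310, 0.7e-3))) {
    f2 <- fbm_classifier(1, water_diffusivity(ctx2))
    expect_equal(dtilde(f2, ctx2), 1, tolerance = 1e-12)
  }
  # monotone in D_alpha at fixed alpha
  expect_gt(dtilde(fbm_classifier(0.5, 0.2), ctx),
            dtilde(fbm_classifier(0.5, 0.1), ctx))

  # log Dtilde is a fixed affine map of (alpha, log D_alpha)
  set.seed(61)
  ts <- t_star(ctx); r_um <- ctx$radius * 1e6
  for (i in 1:100) {
    a <- runif(1, 0.05, 1); D <- exp(runif(1, -5, 1))
    f <- fbm_classifier(a, D)
    expect_equal(log(dtilde(f, ctx)),
                 log(D) + a * log(ts) + log(4 / (16 * r_um^2)),
                 tolerance = 1e-12)
    # round trip through (alpha, log Delta) as well
    expect_equal(log(dtilde(f, ctx)),
                 log(delta_at(f)) + a * log(ts) - log(16 * r_um^2),
                 tolerance = 1e-12)
  }
})

test_that("loss tangent collapses to tan(pi alpha / 2) with sol/gel labels", {
  lt <- loss_tangent(c(0.25, 0.5, 1))
  expect_equal(lt$tan_delta[1], 0.41421, tolerance = 1e-4)
  expect_equal(lt$log10_tan_delta[1], -0.38278, tolerance = 1e-4)
  expect_equal(lt$phase, c("gel", "boundary", "sol"))
  expect_equal(lt$tan_delta[2], 1)
  expect_equal(lt$log10_tan_delta[2], 0)
  expect_identical(lt$tan_delta[3], Inf)
  # strictly increasing on (0, 1)
  grid <- loss_tangent(seq(0.05, 0.95, by = 0.05))
  expect_true(all(diff(grid$tan_delta) > 0))
  expect_error(loss_tangent(1.5), "alpha")
})

test_that("coarse classification applies the noise-floor cutoff and the
           mixture/heuristic split", {
  # strict cutoff: alpha exactly 0.1 is retained as signal
  fits <- known_cluster(c(0.05, 0.1, 0.3, 0.85), c(0.05, 0.05, 0.05, 0.35))
  labs <- coarse_classify(fits, method = "rule")
  expect_equal(as.character(labs),
               c("noise_floor", "flake_like", "flake_like", "water_like"))
  # boundary alpha = 0.5 goes to the water/sol side
  labs2 <- coarse_classify(known_cluster(rep(0.5, 3), rep(0.1, 3)),
                           method = "rule")
  expect_true(all(labs2 == "water_like"))
  expect_error(coarse_classify(list()), "no classifiers")

  # mixture split recovers the two-phase ground truth
  set.seed(62)
  w <- draw_cluster_points(water_like_spec(), 40)
  fl <- draw_cluster_points(flake_like_spec(), 40)
  fits <- known_cluster(c(w[, 1], fl[, 1]), c(w[, 2], fl[, 2]))
  truth <- rep(c("water_like", "flake_like"), each = 40)
  labs <- coarse_classify(fits, method = "mixture")
  keep <- labs != "noise_floor"
  expect_gte(mean(labs[keep] == truth[keep]), 0.95)

  # fewer than 6 beads: falls back to the heuristic
  small <- known_cluster(c(0.3, 0.8), c(0.05, 0.3))
  expect_equal(as.character(coarse_classify(small)),
               c("flake_like", "water_like"))
})

test_that("classifier table assembles all derived columns", {
  fits <- known_cluster(c(0.3, 0.85), c(0.05, 0.35))
  tab <- classifier_table(fits, water_ctx(1), method = "rule")
  expect_equal(tab$delta, c(0.2, 1.4))
  expect_equal(tab$coarse_label, c("flake_like", "water_like"))
  expect_true(all(c("d_tilde", "log10_loss_tan", "var_alpha") %in% names(tab)))
})
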