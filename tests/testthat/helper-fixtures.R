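# Shared fixtures: everything is generated in code at test time.

water_ctx <- function(diameter_um = 1)
  material_context(radius = diameter_um / 2 * 1e-6, temperature = 293.15,
                   viscosity = 1.002e-3)

# a deterministic ballistic 1-D trajectory: x_j = j
ballistic_traj <- function(n = 4, tau = 1)
  trajectory_record(matrix(0:(n - 1), ncol = 1), tau)

# quick ensemble of known classifiers
known_cluster <- function(alphas, Ds, d = 2)
  mapply(fbm_classifier, alpha = alphas, D_alpha = Ds,
         MoreArgs = list(d = d), SIMPLIFY = FALSE)

# draw (alpha, D_alpha) pairs from a cluster_spec, M at a time
draw_cluster_points <- function(spec, M) {
  t(replicate(M, pptmstats:::draw_classifier(spec)))
}
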