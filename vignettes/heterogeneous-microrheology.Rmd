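---
title: "Statistical methods for particle-tracking microrheology of heterogeneous media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for particle-tracking microrheology of heterogeneous media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Passive particle-tracking microrheology (PPTM) infers the viscoelasticity of
a soft material from the thermal motion of embedded micro-beads. In extremely
heterogeneous media — the motivating case is airway mucus burdened with dense,
phase-separated mucin "flakes" — the classical workflow breaks down three
ways at once:

1. beads inside dense domains move so little that their signal approaches the
   *noise floor* of the instrument (static localization error and camera
   blur);
2. ensembles of beads are not statistically homogeneous, so the
   ensemble-averaged mean-squared displacement (MSD) that the generalized
   Stokes–Einstein relation (GSER) normally consumes averages over physically
   distinct micro-environments;
3. cluster structure exists at several scales (inside vs outside dense
   domains; within each, further sub-populations).

`pptmstats` implements a complete statistical toolchain for this regime:
per-bead denoised fractional-Brownian-motion (fBm) classifiers, classifier
clustering and homogeneity testing, and three cluster-level GSER averaging
protocols — together with an exact synthetic-trajectory generator used to
validate every stage.

# The signal model

A tracked bead's position series \(X_j = X(j\tau)\), \(j = 0,\dots,N\)
(frame interval \(\tau\), dimension \(d = 2\)) is decomposed into

* a medium-induced fBm signal with time-averaged MSD
  \(\mathrm{MSD}(t) = 2 d D_\alpha t^\alpha\), \(0 < \alpha \le 1\) —
  the two-parameter classifier \((\alpha, D_\alpha)\);
* high-frequency *static* localization noise (iid Gaussian, SD \(\sigma\)
  per coordinate, raising the MSD by a constant \(2 d \sigma^2\)) and
  *dynamic* error (camera motion blur over the open shutter);
* low-frequency deterministic drift \(v t\).

The increment series per coordinate is modelled as
\[
Y_n = (1-b)\,\Delta X_n + b\,\Delta X_{n-1}
      + \varepsilon_n - \varepsilon_{n-1} + \mu,
\]
where \(\Delta X\) are fBm (fractional Gaussian noise) increments, \(b\) is a
single moving-average blur coefficient (the minimal dynamic-error filter),
\(\varepsilon_n \sim N(0, \sigma^2)\) iid, and \(\mu = v\tau\) a constant
drift mean per coordinate. Coordinates are exchangeable: they share
\((\alpha, D_\alpha, b, \sigma^2)\) and contribute independent likelihood
terms. Anisotropy and higher-order blur filters are out of scope.

# The LS predictor / fARMAs corrector

The classical estimator regresses \(\log \mathrm{MSD}\) on \(\log t\)
(`ls_fit()`). It fits signal *plus* noise: with a noise floor
\(2 d D_\alpha t^\alpha + 2 d\sigma^2\), the local log-log slope
\(\alpha \cdot \mathrm{signal} / (\mathrm{signal} + \mathrm{offset})\) is
everywhere below \(\alpha\), so least squares *under*-estimates the exponent
whenever the floor matters (the closed-form curve makes this sign
unambiguous, and the package tests pin it).

`farmas_fit()` therefore maximizes the exact stationary Gaussian likelihood
of the increments under the model above. Implementation choices that matter:

* **Durbin–Levinson evaluation.** The Toeplitz increment covariance is
  handled by the Durbin–Levinson innovations recursion (compiled code,
  \(O(N^2)\)), which also yields the exact GLS estimate of the drift mean
  through an auxiliary ones column.
* **Profiling.** The overall scale \(s = D_\alpha \tau^\alpha\) multiplies
  the whole covariance once the noise is expressed as the ratio
  \(\lambda = \sigma^2 / s\); \(s\) is profiled analytically, reducing the
  search to \((\alpha, b, \log\lambda)\) under box constraints
  (\(\alpha \in [0.01, 1]\), \(b \in [0, 0.49]\),
  \(\log\lambda \in [-25, 8]\)), L-BFGS-B, objective tolerance
  `factr = 1e7`.
* **Predictor–corrector with two noise basins.** The likelihood can be
  bimodal in \((\alpha, \sigma^2)\): antipersistent fGn (small \(\alpha\))
  has the same high-frequency signature as differenced static noise, so a
  spurious \(\sigma^2 = 0\), low-\(\alpha\) basin competes with the truth.
  The full-band LS fit predicts \((\alpha, D_\alpha)\); the noise level is
  separately predicted by extrapolating a mid-band LS signal fit down to
  lag 1 (the excess of the empirical lag-1 MSD over the extrapolated signal
  is the noise floor). The corrector is started from both a noise-free and
  the predicted-noise initialization and the higher-likelihood optimum is
  kept, with jittered restarts only if neither converges. Boundary hits
  (\(\hat\alpha\) at a bound, \(\hat b = 0\), \(\hat\sigma^2 = 0\)) are
  flagged, never silently dropped.
* **Classifier covariance.** `classifier_covariance()` returns the 2×2
  covariance of \((\alpha, \log D_\alpha)\) from the inverse of the
  numerically differentiated observed information (central differences) at
  the MLE, with nuisance parameters stuck at a boundary held fixed; an
  indefinite Hessian falls back to a nearest-PSD projection and is flagged.
  Since \(\log\Delta(1\,\mathrm{s}) = \log 2d + \log D_\alpha\), the same
  matrix is the covariance in the \((\alpha, \log\Delta)\) plane used
  downstream.

# Classifier scales

\(D_\alpha\) has \(\alpha\)-dependent units, so beads are compared on
derived scales: \(\Delta = 2 d D_\alpha t^\alpha\) at the reference time
\(t = 1\) s (micrometres squared, configurable), and the dimensionless
\(\tilde D_\alpha = \mathrm{MSD}(t^\*) / (4r)^2\) at the bead-size time
\(t^\* = (2r)^2 / D_w\), with \(D_w\) the Stokes–Einstein diffusivity of the
bead in water. Both \(\log\) scales are affine images of
\((\alpha, \log D_\alpha)\). A bead diffusing in water itself has
\(\tilde D_\alpha = 1\) identically. For power-law media the loss tangent
collapses to \(\tan(\pi\alpha/2)\): \(\alpha < 0.5\) is gel-like,
\(\alpha > 0.5\) sol-like (the boundary value is assigned the sol side as a
documented tie-break).

The coarse three-way classification labels beads with \(\hat\alpha < 0.1\)
(strictly; derived from stuck-bead controls) as noise floor, and splits the
rest water-like vs flake-like by a two-component mixture on
\((\alpha, \log\Delta)\), falling back to the \(\alpha = 0.5\) heuristic for
fewer than six beads or when model selection prefers one component.

# Clustering and model selection

Mixture clustering is delegated to the mclust EM machinery behind a thin
surface exposing six covariance-constraint families
(spherical/diagonal/full × equal/varying — mclust's EII, VII, EEI, VVI,
EEE, VVV). This subset covers the behavior the analysis exploits —
constrained fits for small clusters versus unconstrained fits that are
invariant under affine reparameterizations of the classifier plane — while
omitting orientation-only families. BIC is reported in the minimized
convention \(-2\ell + k\log M\); `select_model()` scans all
(K, constraint) pairs up to `Kmax`, breaking ties toward smaller K and then
simpler constraints. Initialization is mclust's deterministic model-based
hierarchical agglomeration, so clustering needs no seed. Posterior
membership is computed directly from the fitted parameters, with exact ties
broken toward the lower component index.

Two caveats the tests document: constrained families are *not* invariant
under the \((\alpha,\log\Delta) \to (\alpha,\log\tilde D_\alpha)\) shear,
and clusters that are Gaussian in \((\alpha, D_\alpha)\) are skewed after
the log map, which can legitimately lead BIC to split them — the mixture
model's ellipses are a modelling choice, not ground truth.

# Homogeneity testing

Given per-bead estimates \(\hat\theta_i\) (we use
\((\alpha, \log\Delta)\)) with covariances \(V_i\), `cochran_q()` tests
\(H_0: \theta_1 = \dots = \theta_M\). The default is the classical
inverse-variance-weighted Cochran's Q,
\[
Q = \sum_i (\hat\theta_i - \bar\theta_w)^\top V_i^{-1}
    (\hat\theta_i - \bar\theta_w), \qquad
\bar\theta_w = \Big(\sum_i V_i^{-1}\Big)^{-1} \sum_i V_i^{-1}\hat\theta_i,
\]
which is exactly \(\chi^2_{p(M-1)}\) under \(H_0\) and exactly invariant
under affine reparameterizations — so the test is identical on
\((\alpha, \log\Delta)\) and \((\alpha, \log\tilde D_\alpha)\). A compact
"whitened" variant, \(Q = \sum_i \|V_i^{-1/2}\hat\theta_i - \bar Z\|^2\)
with the symmetric eigendecomposition root, is provided as
`form = "whitened"`: it coincides with the weighted form when all \(V_i\)
are equal, but with heterogeneous covariances its null distribution is a
*noncentral* chi-squared that depends on the common classifier value
(whitening maps a shared mean to different \(Z\)-means), so it is not used
as the default. Clusters with fewer than four beads are tested but
annotated low-power.

# Dynamic moduli: three GSER protocols

For a power-law MSD the GSER has the exact closed form
\[
G^*(\omega) = \frac{k_B T\, \omega^\alpha}
     {\pi r\, \Gamma(1+\alpha)\, 2 d D_\alpha}
     \Big(\cos\tfrac{\pi\alpha}{2} + i \sin\tfrac{\pi\alpha}{2}\Big),
\]
with the printed \(d = 2\) convention (so the \(\alpha = 1\) water limit is
\(G'' = \tfrac{3}{2}\eta\omega\) rather than \(\eta\omega\); the
`d` argument generalizes the factor). Frequencies follow the
\(\omega = 1/t\) convention; the default grid is log-spaced over
\([4/(N\tau),\, 1/\tau]\).

Three cluster-level protocols are provided:

* **GSER Average** (`gser_average()`): exact per-bead moduli, then
  arithmetic per-frequency mean of \(G'\) and \(G''\), with mean ± 2 s.d.
  envelopes (floored at 0 Pa, on the linear moduli scale) for clusters of
  at least two beads. This is the protocol justified for heterogeneous
  clusters.
* **MSD Average** (`msd_average_gser()`): ensemble-average the denoised
  per-bead MSDs on the \(t = 1/\omega\) grid, then apply the local
  power-law numerical GSER (centred log-log slope as the local exponent);
  this rule reproduces the closed form exactly on pure power laws — the
  only case with analytic ground truth — and flags grid points whose local
  exponent leaves \((0, 1.2)\).
* **Classifier Average** (`classifier_average_gser()`): arithmetic mean of
  \(\alpha\) and of \(D_\alpha\), then one exact power-law curve (always a
  straight line in log-log; geometric \(D_\alpha\) averaging behind a
  flag).

For tight clusters all three coincide. A quantitative caveat the package
measures rather than hides: GSER Average scales per bead as
\(1/D_{\alpha,i}\) while the other two scale as the reciprocal of the mean,
so for clusters with a broad prefactor spread (the flake-like condition has
\(\mathrm{sd}(D_\alpha)/\bar D_\alpha = 0.4\)) the Jensen gap
\(\overline{1/D} > 1/\bar D\) already separates GSER Average from the other
protocols by 15–50% even within a nominally "homogeneous" cluster. This is
a property of frequency-domain averaging over reciprocal prefactors, visible
in any sufficiently dispersed ensemble, and is the same mechanism that makes
the three protocols diverge by integer factors on genuinely two-phase
mixtures.

# The synthetic generator

`simulate_fbm()` draws exact fractional Gaussian paths by circulant
embedding of the increment covariance (Davies–Harte), falling back to a
Cholesky factorization when the embedding is not non-negative (the path
taken is recorded). Contaminations are applied in the order the instrument
would: drift, then blur, then static noise. Motion blur is produced by
brute-force substep averaging over the open-shutter window
(`add_dynamic_blur()`), deliberately *not* through the estimator's own MA
filter, so the blur model is validated against an independent mechanism.
`simulate_stuck_bead()` provides the pure-noise control that operationally
defines the noise floor. `simulate_ensemble()` draws per-bead classifiers
from normal clusters — independent in \(\alpha\) and \(D_\alpha\),
rejected-and-resampled outside \((0,1]\) and \((0,\infty)\) — and scatters
initial positions uniformly over a 200 μm field of view so that proximity
filtering is meaningful; ground truth is returned exactly as drawn.

Reference study conditions are built in: \(\tau = 1/60\) s, 30 s of
tracking (\(N = 1800\)), \(d = 2\); a water-like cluster with means
\((\alpha, D_\alpha) = (0.85, 0.35)\), SDs \((0.03, 0.02)\); a flake-like
cluster with means \((0.3, 0.05)\), SDs \((0.07, 0.02)\); static noise
\(\sigma = 0.01\) μm for the water-like condition and 0.05 μm for the
flake-like condition. What the generator does *not* emulate: heavy-tailed
localization error, confined diffusion or CTRW alternatives to fBm, and
anisotropic media — so passing tests demonstrate correctness of the
statistical machinery under the fBm model, not model adequacy for any
particular material.

# The five-step protocol

`run_protocol()` chains the stages: proximity filter (beads within 5
diameters at any shared frame excluded pairwise — both members, since the
isolation requirement does not say which to keep; beads tracked at disjoint
times are never compared), uniformity filter (drop gapped series, truncate
to a common \(N\)), per-bead LS-fARMAs fits, coarse classification
(noise-floor beads are reported but never fitted for moduli), Cochran's Q
per coarse group, mixture clustering within rejected groups, per-cluster
homogeneity (low-power annotation below four beads), and per-cluster moduli
by all three protocols. The report is deterministic under a fixed
configuration and seed, and `write_report()` emits per-stage CSV tables
plus a JSON provenance manifest.

# Numerical choices and problem sizes

* Optimizer: L-BFGS-B, `factr = 1e7`, at most 200 iterations, up to three
  jittered restarts after the two deliberate noise-basin starts.
* MSD default `max_lag = floor(N/2)`: longer lags average too few pairs.
* Hessian steps: central differences with per-coordinate steps
  \(10^{-3}\max(|\theta_i|, 0.1)\).
* Mixture EM: mclust defaults (relative log-likelihood tolerance 1e-5),
  deterministic hierarchical initialization.
* Envelope floor 0 Pa; variance floors \(10^{-8}\)-scale eigenvalue clamps
  wherever a covariance must be inverted, always flagged.
* Test-suite problem sizes are chosen for tight runtimes while keeping
  every check statistically meaningful: ensemble-MSD oracles use hundreds
  of short paths; estimator recovery uses \(N = 600\)–1800 with 8–50
  replicates; the cluster-recovery and calibration checks use 5000
  chi-squared replicates and 20 mixture replicates; the end-to-end
  pipeline demonstration uses 40 beads at \(N = 600\). The headline
  cluster-recovery checks use the full study geometry (50 beads,
  \(N = 1800\), \(\tau = 1/60\) s).

# Known limitations

* The exact MLE carries a small finite-sample bias at the study geometry
  (\(N = 1800\)): measured over 150 replicates of the water-like
  condition, \(\hat\alpha\) is low by about 0.01 and \(\hat D_\alpha\) by
  2–3% (the \(\tau^{-\hat\alpha}\) extrapolation makes
  \(\hat D_\alpha\) errors multiplicative). This is an order of magnitude
  smaller than the classifier spreads of interest but visible in large
  ensembles.
* \(\sigma^2\) and \(\alpha\) are weakly identified near the noise floor
  (the likelihood ridge described above); estimates there carry honest,
  larger standard errors, and a bead whose signal is genuinely
  indistinguishable from the floor belongs in the noise-floor class, not
  in a moduli average.
* The mixture model assumes elliptical clusters in the chosen classifier
  plane; log-transformed prefactor clusters are skewed, and BIC may split
  them.
* GSER Average and MSD/Classifier Average answer slightly different
  questions for dispersed clusters (reciprocal-mean vs mean-reciprocal);
  report all three, as the protocol does, rather than treating any one as
  canonical for heterogeneous data.
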