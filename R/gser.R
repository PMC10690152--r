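## Dynamic moduli from denoised classifiers: the exact power-law GSER per
## bead, and the three cluster-averaging protocols (moduli averaging in
## frequency space, MSD averaging followed by a numerical GSER, classifier
## averaging). The printed formulas use the d = 2 tracking convention
## (2 d D_alpha = 4 D_alpha), so the alpha = 1 water limit is
## G'' = (3/2) eta omega; a `dimension` argument keeps the factor general.

.moduli_curve <- function(omega, Gp, Gpp, method, lo = NULL, hi = NULL) {
  out <- data.frame(omega = omega, G_storage = Gp, G_loss = Gpp)
  if (!is.null(lo)) { out$band_lo_storage <- lo[[1L]]; out$band_hi_storage <- hi[[1L]]
                      out$band_lo_loss <- lo[[2L]]; out$band_hi_loss <- hi[[2L]] }
  class(out) <- c("moduli_curve", "data.frame")
  attr(out, "method") <- method
  out
}

#' Default frequency grid
#'
#' Log-spaced frequencies over `[1 / (N tau / 4), 1 / tau]`, the band where
#' time-averaged MSDs are reliable, using the `omega = 1 / t` convention.
#'
#' @param N Number of increments.
#' @param tau Frame interval (s).
#' @param length.out Grid size.
#' @return Increasing frequency grid (1/s).
#' @export
default_omega_grid <- function(N = 1800, tau = 1 / 60, length.out = 50L) {
  exp(seq(log(4 / (N * tau)), log(1 / tau), length.out = length.out))
}

## modulus magnitude A(omega) of the exact power-law GSER (Pa); D_alpha in
## um^2/s^alpha, radius in m.
.powerlaw_A <- function(alpha, D_alpha, omega, ctx, d) {
  ctx$kB * ctx$temperature * omega^alpha /
    (pi * ctx$radius * gamma(1 + alpha) * (2 * d * D_alpha * 1e-12))
}

#' Exact power-law dynamic moduli of a single bead
#'
#' The GSER applied to the denoised power-law MSD has an exact closed form:
#' `G'(w) = A(w) cos(pi alpha / 2)`, `G''(w) = A(w) sin(pi alpha / 2)` with
#' `A(w) = kB T w^alpha / (pi r Gamma(1 + alpha) 2 d D_alpha)`. At
#' `alpha = 1` the storage modulus vanishes identically and, with the d = 2
#' convention, `G'' = (3/2) eta w` for a bead in the reference fluid.
#'
#' @param fit An `fbm_classifier` (or anything with `alpha`, `D_alpha`).
#' @param omega Frequency grid (1/s).
#' @param ctx A [material_context()].
#' @param d Spatial dimension convention (default 2, as printed).
#' @return A `moduli_curve` data frame: `omega`, `G_storage`, `G_loss` (Pa).
#' @export
powerlaw_moduli <- function(fit, omega = default_omega_grid(), ctx, d = 2) {
  alpha <- fit$alpha; D_alpha <- fit$D_alpha
  if (alpha <= 0) stop("alpha must be positive")
  A <- .powerlaw_A(alpha, D_alpha, omega, ctx, d)
  .moduli_curve(omega, A * cospi(alpha / 2), A * sinpi(alpha / 2),
                "single_bead")
}

.cluster_alphas <- function(cluster)
  vapply(cluster, `[[`, numeric(1L), "alpha")
.cluster_Ds <- function(cluster)
  vapply(cluster, `[[`, numeric(1L), "D_alpha")

#' GSER Average: frequency-domain averaging of per-bead moduli
#'
#' The protocol for heterogeneous clusters: apply the exact power-law GSER
#' to each bead's denoised classifier, then average `G'` and `G''`
#' arithmetically across beads at each frequency. Mean +/- 2 s.d. envelopes
#' (floored at 0) are attached when the cluster has at least two beads.
#'
#' @param cluster List of `fbm_classifier` objects.
#' @param omega Frequency grid (1/s).
#' @param ctx A [material_context()].
#' @param d Spatial dimension convention.
#' @return A `moduli_curve` with envelope columns when M >= 2.
#' @export
gser_average <- function(cluster, omega = default_omega_grid(), ctx, d = 2) {
  if (length(cluster) == 0L) stop("empty cluster")
  a <- .cluster_alphas(cluster); D <- .cluster_Ds(cluster)
  Gp <- sapply(seq_along(a), function(i)
    .powerlaw_A(a[i], D[i], omega, ctx, d) * cospi(a[i] / 2))
  Gpp <- sapply(seq_along(a), function(i)
    .powerlaw_A(a[i], D[i], omega, ctx, d) * sinpi(a[i] / 2))
  Gp <- matrix(Gp, nrow = length(omega)); Gpp <- matrix(Gpp, nrow = length(omega))
  mp <- rowMeans(Gp); mpp <- rowMeans(Gpp)
  if (length(a) >= 2L) {
    sp <- apply(Gp, 1L, sd); spp <- apply(Gpp, 1L, sd)
    out <- .moduli_curve(omega, mp, mpp, "gser_average",
                         lo = list(pmax(mp - 2 * sp, 0), pmax(mpp - 2 * spp, 0)),
                         hi = list(mp + 2 * sp, mpp + 2 * spp))
  } else out <- .moduli_curve(omega, mp, mpp, "gser_average")
  out
}

#' MSD Average: ensemble-averaged MSD through a numerical GSER
#'
#' The standard protocol for presumed homogeneous materials: average the
#' denoised per-bead power-law MSDs on a common time grid, then apply the
#' local power-law numerical GSER. At each frequency `w` the MSD is read at
#' `t = 1/w`, the local exponent `a(w)` is the centred log-log slope, and
#' `|G*| = kB T / (pi r <MSD>(1/w) Gamma(1 + a(w)))` with phase
#' `pi a(w) / 2`. On a pure power-law input this reproduces the exact
#' closed form. Grid points whose local exponent falls outside (0, 1.2)
#' are flagged in the `flagged` column.
#'
#' @inheritParams gser_average
#' @return A `moduli_curve` with a `local_exponent` column.
#' @export
msd_average_gser <- function(cluster, omega = default_omega_grid(), ctx,
                             d = 2) {
  if (length(cluster) == 0L) stop("empty cluster")
  a <- .cluster_alphas(cluster); D <- .cluster_Ds(cluster)
  tt <- 1 / omega                      # decreasing times
  m <- vapply(tt, function(t1) mean(2 * d * D * t1^a), numeric(1L))
  lm_ <- log(m); lt_ <- log(tt)
  k <- length(tt)
  slope <- numeric(k)
  slope[1L] <- (lm_[2L] - lm_[1L]) / (lt_[2L] - lt_[1L])
  slope[k] <- (lm_[k] - lm_[k - 1L]) / (lt_[k] - lt_[k - 1L])
  if (k > 2L)
    slope[2:(k - 1L)] <- (lm_[3:k] - lm_[1:(k - 2L)]) / (lt_[3:k] - lt_[1:(k - 2L)])
  flagged <- slope <= 0 | slope >= 1.2
  Amag <- ctx$kB * ctx$temperature /
    (pi * ctx$radius * (m * 1e-12) * gamma(1 + pmax(pmin(slope, 1.99), 1e-6)))
  out <- .moduli_curve(omega, Amag * cospi(pmin(pmax(slope, 0), 1) / 2),
                       Amag * sinpi(pmin(pmax(slope, 0), 1) / 2),
                       "msd_average")
  out$local_exponent <- slope
  out$flagged <- flagged
  out
}

#' Classifier Average: moduli of the ensemble-mean classifier
#'
#' Arithmetic averaging of the classifiers themselves (`mean alpha`,
#' `mean D_alpha`) followed by the exact power-law GSER. The result is by
#' construction an exact power law (a straight line in log-log), whatever
#' the cluster's heterogeneity; geometric averaging of `D_alpha` is
#' available via `log_D = TRUE`.
#'
#' @inheritParams gser_average
#' @param log_D Average `D_alpha` on the log scale (default `FALSE`,
#'   arithmetic as in the reference protocol).
#' @return A `moduli_curve`.
#' @export
classifier_average_gser <- function(cluster, omega = default_omega_grid(),
                                    ctx, d = 2, log_D = FALSE) {
  if (length(cluster) == 0L) stop("empty cluster")
  a <- mean(.cluster_alphas(cluster))
  D <- if (log_D) exp(mean(log(.cluster_Ds(cluster)))) else mean(.cluster_Ds(cluster))
  A <- .powerlaw_A(a, D, omega, ctx, d)
  out <- .moduli_curve(omega, A * cospi(a / 2), A * sinpi(a / 2),
                       "classifier_average")
  attr(out, "mean_classifier") <- c(alpha = a, D_alpha = D)
  out
}

#' Loss tangent along a moduli curve
#'
#' `tan(delta)(w) = G''(w) / G'(w)` per frequency, with sol (`> 1`) / gel
#' (`< 1`) phase labels and any sol-gel crossover frequencies (sign changes
#' of `log10 tan(delta)`) reported in the `"crossovers"` attribute.
#'
#' @param curve A `moduli_curve`.
#' @return A data frame `omega`, `tan_delta`, `log10_tan_delta`, `phase`.
#' @export
loss_tangent_curve <- function(curve) {
  stopifnot(inherits(curve, "moduli_curve"))
  td <- ifelse(curve$G_storage > 0, curve$G_loss / curve$G_storage, Inf)
  l10 <- log10(td)
  out <- data.frame(omega = curve$omega, tan_delta = td,
                    log10_tan_delta = l10,
                    phase = ifelse(td > 1, "sol", ifelse(td < 1, "gel", "boundary")))
  s <- sign(l10[is.finite(l10)])
  om <- curve$omega[is.finite(l10)]
  flips <- which(diff(s) != 0 & s[-length(s)] != 0)
  attr(out, "crossovers") <- sqrt(om[flips] * om[flips + 1L])
  out
}
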