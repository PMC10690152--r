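## Unit-normalizing classifier transforms and the coarse three-way
## classification (water-like / flake-like / noise floor).

#' MSD at a reference time (the Delta classifier)
#'
#' `Delta = 2 d D_alpha t^alpha`, the denoised MSD evaluated at a reference
#' time (default 1 s). Unlike `D_alpha`, whose units depend on `alpha`,
#' `Delta` has units of um^2 for every bead and so supports ensemble
#' comparison, averaging and clustering.
#'
#' @param fit An `fbm_classifier`.
#' @param t Reference time in seconds (default 1).
#' @param d Spatial dimension; defaults to the classifier's.
#' @return Delta in square micrometres.
#' @export
delta_at <- function(fit, t = 1, d = NULL) {
  stopifnot(inherits(fit, "fbm_classifier"))
  if (t <= 0) stop("reference time must be positive")
  if (is.null(d)) d <- fit$d
  2 * d * fit$D_alpha * t^fit$alpha
}

#' Bead-size reference time t*
#'
#' `t* = (2r)^2 / Dw`: the time for a bead to diffuse its own diameter in
#' the reference fluid (water). For 1 um diameter beads in water at
#' 293.15 K this is about 2.33 s; for 200 nm beads about 0.019 s.
#'
#' @param ctx A [material_context()].
#' @return Reference time in seconds.
#' @export
t_star <- function(ctx) {
  stopifnot(inherits(ctx, "material_context"))
  r_um <- ctx$radius * 1e6
  (2 * r_um)^2 / water_diffusivity(ctx)
}

#' Dimensionless rescaled prefactor D-tilde
#'
#' The denoised MSD evaluated at the bead-size reference time `t*`, in
#' units of `(4r)^2`: `Dtilde = MSD(t*) / (4r)^2 = 2 d D_alpha t*^alpha /
#' (16 r^2)`. A bead diffusing in the reference fluid itself (`alpha = 1`,
#' `D_alpha = Dw`, d = 2) has `Dtilde = 1` for every radius. `log Dtilde`
#' is an affine image of `(alpha, log D_alpha)`.
#'
#' @param fit An `fbm_classifier`.
#' @param ctx A [material_context()].
#' @param d Spatial dimension; defaults to the classifier's.
#' @return Dimensionless rescaled prefactor.
#' @export
dtilde <- function(fit, ctx, d = NULL) {
  stopifnot(inherits(fit, "fbm_classifier"), inherits(ctx, "material_context"))
  if (is.null(d)) d <- fit$d
  r_um <- ctx$radius * 1e6
  ts <- t_star(ctx)
  2 * d * fit$D_alpha * ts^fit$alpha / (4 * r_um)^2
}

#' Loss tangent of a power-law medium
#'
#' For a pure power-law MSD the loss tangent collapses to a function of the
#' exponent alone: `tan(delta) = tan(pi alpha / 2)`, independent of
#' frequency and prefactor. Values above 1 (`alpha > 0.5`) are sol-like
#' (viscous-dominated), below 1 gel-like (elastic-dominated); `alpha = 1`
#' is purely viscous with infinite loss tangent.
#'
#' @param alpha Exponent in (0, 1]; vectorized.
#' @return A data frame with `tan_delta`, `log10_tan_delta` and `phase`
#'   (`"gel"`, `"sol"`, or `"boundary"` at exactly 0.5).
#' @export
loss_tangent <- function(alpha) {
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must lie in (0, 1]")
  td <- rep(Inf, length(alpha))
  td[alpha < 1] <- tanpi(alpha[alpha < 1] / 2)
  phase <- ifelse(alpha < 0.5, "gel", ifelse(alpha > 0.5, "sol", "boundary"))
  data.frame(alpha = alpha, tan_delta = td, log10_tan_delta = log10(td),
             phase = phase)
}

#' Coarse three-way classification of a classifier ensemble
#'
#' Labels each bead `noise_floor`, `flake_like` or `water_like`. Beads with
#' `alpha < 0.1` (strictly) are assigned to the noise floor, the cutoff
#' derived from stuck-bead controls; beads at exactly 0.1 are retained as
#' signal. The remaining beads are split water-like vs flake-like either by
#' a two-component normal mixture on `(alpha, log Delta)` with the
#' higher-mean-alpha component labelled water-like (default), or by the
#' sol-gel heuristic at `alpha = 0.5` (`"rule"`). The mixture falls back to
#' the heuristic when fewer than 6 beads remain or when model selection
#' prefers a single component; exactly `alpha = 0.5` is assigned the
#' water/sol side.
#'
#' @param fits List of `fbm_classifier` objects.
#' @param method `"mixture"` (default) or `"rule"`.
#' @param noise_cutoff Noise-floor cutoff on alpha (default 0.1, strict).
#' @return A character vector of labels, one per bead, with the fitted
#'   mixture (if any) in attribute `"mixture"`.
#' @export
coarse_classify <- function(fits, method = c("mixture", "rule"),
                            noise_cutoff = 0.1) {
  method <- match.arg(method)
  if (length(fits) == 0L) stop("no classifiers supplied")
  alpha <- vapply(fits, `[[`, numeric(1L), "alpha")
  labels <- rep(NA_character_, length(fits))
  labels[alpha < noise_cutoff] <- "noise_floor"
  sig <- which(alpha >= noise_cutoff)
  if (length(sig) == 0L) return(labels)
  mix <- NULL
  use_rule <- method == "rule" || length(sig) < 6L
  if (!use_rule) {
    pts <- cbind(alpha = alpha[sig],
                 logDelta = log(vapply(fits[sig], delta_at, numeric(1L))))
    mix <- tryCatch(select_model(pts, Kmax = 2L), error = function(e) NULL)
    if (is.null(mix) || mix$K == 1L) {
      use_rule <- TRUE
    } else {
      lab <- posterior_assign(mix, pts)$label
      water_comp <- which.max(mix$means[, "alpha"])
      labels[sig] <- ifelse(lab == water_comp, "water_like", "flake_like")
    }
  }
  if (use_rule)
    labels[sig] <- ifelse(alpha[sig] >= 0.5, "water_like", "flake_like")
  attr(labels, "mixture") <- mix
  labels
}

#' Derived classifier table
#'
#' Augments a list of fitted classifiers with the unit-normalized scales
#' and coarse labels: `Delta` (MSD at 1 s), `Dtilde`, `log10 tan(delta)`
#' and the coarse three-way label.
#'
#' @param fits List of `fbm_classifier` objects.
#' @param ctx A [material_context()].
#' @param ... Passed to [coarse_classify()].
#' @return A data frame, one row per bead.
#' @export
classifier_table <- function(fits, ctx, ...) {
  alpha <- vapply(fits, `[[`, numeric(1L), "alpha")
  lt <- rep(Inf, length(alpha))
  lt[alpha < 1] <- log10(tanpi(alpha[alpha < 1] / 2))
  data.frame(
    bead_id = vapply(fits, `[[`, character(1L), "bead_id"),
    alpha = alpha,
    D_alpha = vapply(fits, `[[`, numeric(1L), "D_alpha"),
    sigma2_static = vapply(fits, `[[`, numeric(1L), "sigma2_static"),
    delta = vapply(fits, delta_at, numeric(1L)),
    d_tilde = vapply(fits, dtilde, numeric(1L), ctx = ctx),
    log10_loss_tan = lt,
    var_alpha = vapply(fits, function(f) f$cov_alpha_logD[1L, 1L], numeric(1L)),
    var_logD = vapply(fits, function(f) f$cov_alpha_logD[2L, 2L], numeric(1L)),
    cov_alpha_logD = vapply(fits, function(f) f$cov_alpha_logD[1L, 2L], numeric(1L)),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"), character(1L)),
    coarse_label = as.character(coarse_classify(fits, ...)))
}
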