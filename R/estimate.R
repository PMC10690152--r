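## LS-predictor / fARMAs-corrector estimation of the denoised fBm classifier.
##
## Observation model for each coordinate's increment series:
##   Y_n = (1 - b) dX_n + b dX_{n-1} + e_n - e_{n-1} + mu
## where dX is fBm (fGn) increments with MSD prefactor D_alpha and exponent
## alpha, b is a single moving-average camera-blur coefficient, e are iid
## N(0, sigma2) static localization errors and mu is a constant drift mean.
## Coordinates are exchangeable: they share (alpha, D_alpha, b, sigma2) and
## contribute independent likelihood terms; drift means are per-coordinate.
## The exact stationary Gaussian likelihood is evaluated by the
## Durbin-Levinson recursion on the Toeplitz increment autocovariance, with
## the overall scale s = D_alpha tau^alpha profiled out analytically and the
## drift means profiled by GLS.

## Unit-scale model autocovariance shape over lags 0..n-1:
## rho_blur(k) + lambda * nu(k), nu = (2, -1, 0, ...) from differenced
## static noise, lambda = sigma2 / (D_alpha tau^alpha).
.model_acf_shape <- function(n, alpha, b, lambda) {
  rho <- fgn_autocov(0:n, alpha)               # rho(0..n)
  k <- seq_len(n)                              # lags 0..n-1 are rho[k]
  rho_m1 <- c(rho[2L], rho[k[-n]])             # rho(|k-1|), rho(-1)=rho(1)
  g <- ((1 - b)^2 + b^2) * rho[k] + b * (1 - b) * (rho[k + 1L] + rho_m1)
  g[1L] <- g[1L] + 2 * lambda
  if (n > 1L) g[2L] <- g[2L] - lambda
  g
}

.BIG <- 1e10

## Profiled negative log-likelihood: par = (alpha, b, eta = log lambda).
.nll_profile <- function(par, Y, tau, estimate_drift = TRUE) {
  alpha <- par[1L]; b <- par[2L]; lambda <- exp(par[3L])
  n <- nrow(Y); d <- ncol(Y)
  g <- .model_acf_shape(n, alpha, b, lambda)
  q <- dl_quad(g, Y)
  if (!isTRUE(q$ok)) return(.BIG)
  Qres <- if (estimate_drift) q$Qyy - q$Qy1^2 / q$Q11 else q$Qyy
  s_hat <- sum(Qres) / (n * d)
  if (!is.finite(s_hat) || s_hat <= 0) return(.BIG)
  0.5 * (d * q$logdet + n * d * (log(2 * pi) + 1 + log(s_hat)))
}

## Full (non-profiled) negative log-likelihood in the reporting
## parameterization theta = (alpha, log D_alpha, b, log sigma2); used for the
## observed-information covariance of the classifier.
.nll_full <- function(theta, Y, tau, estimate_drift = TRUE,
                      fix_b = NULL, fix_lsig2 = NULL) {
  alpha <- theta[1L]
  if (alpha <= 0 || alpha >= 2) return(.BIG)
  D_alpha <- exp(theta[2L])
  i <- 3L
  if (is.null(fix_b)) { b <- theta[i]; i <- i + 1L } else b <- fix_b
  sig2 <- if (is.null(fix_lsig2)) exp(theta[i]) else exp(fix_lsig2)
  if (b < 0 || b > 0.5) return(.BIG)
  n <- nrow(Y); d <- ncol(Y)
  s <- D_alpha * tau^alpha
  g <- s * .model_acf_shape(n, alpha, b, sig2 / s)
  q <- dl_quad(g, Y)
  if (!isTRUE(q$ok)) return(.BIG)
  Qres <- if (estimate_drift) q$Qyy - q$Qy1^2 / q$Q11 else q$Qyy
  0.5 * (d * q$logdet + sum(Qres) + n * d * log(2 * pi))
}

## Central-difference Hessian of f at x.
.num_hessian <- function(f, x, h = pmax(abs(x), 0.1) * 1e-3) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

## Project a symmetric matrix to the nearest PSD matrix (eigenvalue clamp).
.nearest_psd <- function(S, floor_frac = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, floor_frac * max(abs(e$values), 1))
  e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
}

#' Least-squares predictor fit of the MSD power law
#'
#' Ordinary least squares of `log MSD` on `log t` over a lag-time bandwidth,
#' estimating the exponent from the slope and the prefactor from the
#' intercept (`log 2 d D_alpha`). This is the classical estimator; it fits
#' signal-plus-noise, so it is used here as the *predictor* (initial value)
#' for the fARMAs corrector, and as a comparison method.
#'
#' @param msd An [empirical_msd()] (or any data frame with `time` and `msd`
#'   columns).
#' @param bandwidth Length-2 numeric `(t_min, t_max)` in seconds, or `NULL`
#'   for the full available lag range.
#' @param d Spatial dimension used to unpack the intercept; defaults to the
#'   dimension recorded on `msd` (else 2).
#'
#' @return An object of class `ls_fit` with fields `alpha`, `D_alpha`,
#'   `bandwidth`, `residual_sse`, `n_lags`, `d`.
#' @export
ls_fit <- function(msd, bandwidth = NULL, d = NULL) {
  if (is.null(d)) d <- attr(msd, "d") %||% 2
  tt <- msd$time; vv <- msd$msd
  if (is.null(bandwidth)) bandwidth <- range(tt)
  keep <- tt >= bandwidth[1L] & tt <= bandwidth[2L]
  if (sum(keep) < 3L)
    stop("bandwidth must contain at least 3 lags")
  if (any(vv[keep] <= 0))
    stop("MSD values in the bandwidth must be positive")
  fit <- lm(log(vv[keep]) ~ log(tt[keep]))
  cf <- coef(fit)
  structure(
    list(alpha = unname(cf[2L]),
         D_alpha = exp(unname(cf[1L])) / (2 * d),
         bandwidth = bandwidth,
         residual_sse = sum(fit$residuals^2),
         n_lags = sum(keep), d = d),
    class = "ls_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ls_fit <- function(x, ...) {
  cat(sprintf("<ls_fit: alpha = %.4f, D_alpha = %.4g, band = [%.3g, %.3g] s>\n",
              x$alpha, x$D_alpha, x$bandwidth[1L], x$bandwidth[2L]))
  invisible(x)
}

#' fARMAs corrector: denoised maximum-likelihood classifier fit
#'
#' Maximizes the exact stationary Gaussian likelihood of a trajectory's
#' increment series under the fBm-plus-noise model: fBm increments passed
#' through a one-coefficient moving-average camera-blur filter, plus
#' differenced static localization noise, plus a constant per-coordinate
#' drift mean. Coordinates are treated as independent replicates sharing
#' parameters. The optimizer is started at the least-squares predictor
#' (the nonlinear fit is sensitive to its initial condition); the overall
#' scale `D_alpha tau^alpha` is profiled analytically, reducing the search
#' to (alpha, blur, noise ratio), with jittered restarts on non-convergence.
#'
#' @param traj A [trajectory_record()] with contiguous frames (N >= 100
#'   recommended).
#' @param init Optional [ls_fit()] predictor; computed from the full lag
#'   band when missing.
#' @param estimate_blur Estimate the moving-average blur coefficient
#'   (default `TRUE`); when `FALSE` it is fixed at 0.
#' @param estimate_drift Profile a constant increment mean per coordinate
#'   (default `TRUE`).
#' @param alpha_max Upper bound for alpha (default 1; raise for
#'   super-diffusive diagnostics).
#' @param n_restart Number of jittered restarts tried after a failed
#'   optimization.
#' @param compute_cov Compute the observed-information covariance of
#'   `(alpha, log D_alpha)` (default `TRUE`).
#'
#' @return An object of class `fbm_classifier`: fields `alpha`, `D_alpha`
#'   (um^2/s^alpha), `sigma2_static` (um^2), `blur_coef`, `drift` (um/s per
#'   coordinate), `cov_alpha_logD`, `loglik`, `method = "fARMAs"`, and
#'   `flags` (character; e.g. boundary or convergence annotations).
#' @export
farmas_fit <- function(traj, init = NULL, estimate_blur = TRUE,
                       estimate_drift = TRUE, alpha_max = 1,
                       n_restart = 3L, compute_cov = TRUE) {
  stopifnot(inherits(traj, "trajectory_record"))
  if (any(diff(traj$frame_index) != 1L))
    stop("trajectory has missing frames; apply uniformity_filter() first")
  Y <- apply(traj$positions, 2L, diff)
  n <- nrow(Y); d <- ncol(Y); tau <- traj$tau
  if (is.null(init)) init <- ls_fit(empirical_msd(traj), d = d)
  a0 <- min(max(init$alpha, 0.02), alpha_max - 1e-3)
  D0 <- max(init$D_alpha, 1e-12)
  s0 <- D0 * tau^a0
  ## The likelihood can be bimodal in (alpha, sigma2): a spurious basin
  ## trades the noise floor for a smaller exponent (antipersistent fGn has
  ## the same high-frequency signature as differenced noise). Predict the
  ## noise level by extrapolating a mid-band LS signal fit down to lag 1,
  ## where the excess over the signal is the noise floor; the corrector is
  ## then started in both basins and the higher-likelihood fit kept.
  msd1 <- mean(rowSums((traj$positions[-1L, , drop = FALSE] -
                        traj$positions[-(n + 1L), , drop = FALSE])^2))
  band <- c(min(6 * tau, n * tau / 4), min(2, n * tau / 2))
  sig2_A <- tryCatch({
    mid <- ls_fit(empirical_msd(traj), bandwidth = band, d = d)
    max((msd1 - 2 * d * mid$D_alpha * tau^mid$alpha) / (2 * d), 1e-4 * s0)
  }, error = function(e) 1e-4 * s0)
  eta_A <- min(max(log(sig2_A / s0), -20), 6)
  eta_B <- log(1e-4)

  if (estimate_blur) {
    lower <- c(0.01, 0, -25); upper <- c(alpha_max, 0.49, 8)
    nll <- function(p) .nll_profile(p, Y, tau, estimate_drift)
    starts <- list(c(a0, 0.02, eta_A), c(a0, 0.02, eta_B))
    jit <- function() c(rnorm(1L, 0, 0.1), rnorm(1L, 0, 0.05), rnorm(1L, 0, 1))
  } else {
    lower <- c(0.01, -25); upper <- c(alpha_max, 8)
    nll <- function(p) .nll_profile(c(p[1L], 0, p[2L]), Y, tau, estimate_drift)
    starts <- list(c(a0, eta_A), c(a0, eta_B))
    jit <- function() c(rnorm(1L, 0, 0.1), rnorm(1L, 0, 1))
  }
  run_one <- function(st) tryCatch(
    optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200L, factr = 1e7)),
    error = function(e) NULL)
  best <- NULL; converged <- FALSE
  for (st in starts) {   # both noise-basin starts are always explored
    opt <- run_one(st)
    if (is.null(opt) || opt$value > .BIG / 2) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0L
    }
  }
  r <- 0L
  while (!converged && r < n_restart) {   # jittered fallback restarts
    r <- r + 1L
    opt <- run_one(pmin(pmax(starts[[1L]] + jit(), lower), upper))
    if (!is.null(opt) && opt$value < .BIG / 2 &&
        (is.null(best) || opt$value < best$value)) {
      best <- opt
      converged <- opt$convergence == 0L
    }
  }
  if (is.null(best)) stop("fARMAs likelihood optimization failed at every start")
  flags <- character(0L)
  if (!converged) flags <- c(flags, "nonconvergence")
  alpha <- best$par[1L]
  b <- if (estimate_blur) best$par[2L] else 0
  eta_hat <- best$par[length(best$par)]
  lambda <- exp(eta_hat)

  ## recover the profiled quantities at the optimum
  g <- .model_acf_shape(n, alpha, b, lambda)
  q <- dl_quad(g, Y)
  Qres <- if (estimate_drift) q$Qyy - q$Qy1^2 / q$Q11 else q$Qyy
  s_hat <- sum(Qres) / (n * d)
  D_alpha <- s_hat / tau^alpha
  sigma2 <- lambda * s_hat
  drift <- if (estimate_drift) as.numeric(q$Qy1 / q$Q11) / tau else rep(0, d)
  loglik <- -best$value

  if (alpha >= alpha_max - 1e-4 || alpha <= 0.01 + 1e-4)
    flags <- c(flags, "alpha_boundary")
  if (estimate_blur && b >= 0.49 - 1e-4) flags <- c(flags, "blur_boundary")
  noise_floor_hit <- eta_hat <= -25 + 1e-3

  cov2 <- matrix(NA_real_, 2L, 2L)
  if (compute_cov) {
    fix_b <- if (!estimate_blur || b < 1e-5) b else NULL
    fix_ls <- if (noise_floor_hit || sigma2 < 1e-12) log(sigma2 + 1e-300) else NULL
    theta <- c(alpha, log(D_alpha))
    if (is.null(fix_b)) theta <- c(theta, b)
    if (is.null(fix_ls)) theta <- c(theta, log(sigma2))
    f <- function(th) .nll_full(th, Y, tau, estimate_drift,
                                fix_b = fix_b, fix_lsig2 = fix_ls)
    H <- tryCatch(.num_hessian(f, theta), error = function(e) NULL)
    ok <- !is.null(H) && all(is.finite(H))
    if (ok) {
      Vfull <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(Vfull) || any(!is.finite(Vfull)) ||
          any(diag(Vfull)[1:2] <= 0)) {
        Vfull <- tryCatch(solve(.nearest_psd(H, 1e-8)),
                          error = function(e) NULL)
        flags <- c(flags, "cov_regularized")
      }
      ok <- !is.null(Vfull) && all(is.finite(Vfull))
    }
    if (ok) {
      cov2 <- Vfull[1:2, 1:2, drop = FALSE]
      ev <- eigen((cov2 + t(cov2)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 0)) {
        cov2 <- .nearest_psd((cov2 + t(cov2)) / 2)
        flags <- c(flags, "cov_regularized")
      }
      cov2 <- (cov2 + t(cov2)) / 2
    } else {
      flags <- c(flags, "cov_failed")
    }
  }
  dimnames(cov2) <- list(c("alpha", "logD"), c("alpha", "logD"))

  structure(
    list(bead_id = traj$bead_id, alpha = alpha, D_alpha = D_alpha,
         sigma2_static = sigma2, blur_coef = b, drift = drift,
         cov_alpha_logD = cov2, loglik = loglik, method = "fARMAs",
         flags = flags, tau = tau, d = d, N = n, ls_init = init),
    class = "fbm_classifier")
}

#' @export
print.fbm_classifier <- function(x, ...) {
  cat(sprintf(
    "<fbm_classifier '%s' (%s): alpha = %.4f, D_alpha = %.4g, sigma2 = %.3g%s>\n",
    x$bead_id, x$method, x$alpha, x$D_alpha, x$sigma2_static,
    if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Construct a classifier object directly from known parameters
#'
#' Convenience constructor used for closed-form work (moduli curves,
#' synthetic classifier ensembles) where no trajectory fit is involved.
#'
#' @inheritParams fbm_msd
#' @param bead_id Identifier.
#' @param cov Optional 2x2 covariance of `(alpha, log D_alpha)`.
#' @return An `fbm_classifier` object (method `"known"`).
#' @export
fbm_classifier <- function(alpha, D_alpha, d = 2, bead_id = "bead",
                           cov = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  if (D_alpha <= 0) stop("D_alpha must be positive")
  cov2 <- if (is.null(cov)) matrix(NA_real_, 2L, 2L) else cov
  structure(
    list(bead_id = bead_id, alpha = alpha, D_alpha = D_alpha,
         sigma2_static = 0, blur_coef = 0, drift = rep(0, d),
         cov_alpha_logD = cov2, loglik = NA_real_, method = "known",
         flags = character(0L), tau = NA_real_, d = d, N = NA_integer_),
    class = "fbm_classifier")
}

#' Covariance of the fitted classifier
#'
#' The 2x2 covariance of `(alpha, log D_alpha)`, the inverse of the
#' numerically differentiated observed information at the maximum-likelihood
#' estimate (nuisance parameters at boundaries are held fixed). This is the
#' per-bead variance `V_i` consumed by the homogeneity test. Because
#' `log Delta(t = 1 s) = log(2 d) + log D_alpha`, the same matrix is the
#' covariance of `(alpha, log Delta)` at the 1-second reference time.
#'
#' @param fit An `fbm_classifier` from [farmas_fit()].
#' @return Symmetric positive semi-definite 2x2 matrix.
#' @export
classifier_covariance <- function(fit) {
  stopifnot(inherits(fit, "fbm_classifier"))
  fit$cov_alpha_logD
}

#' Remove a linear drift trend from a trajectory
#'
#' Subtracts the per-coordinate ordinary-least-squares linear trend in time.
#' Drift is normally handled inside the likelihood as a constant increment
#' mean; explicit detrending is offered for diagnostics.
#'
#' @param traj A `trajectory_record`.
#' @return A list with `trajectory` (detrended record) and `velocity`
#'   (fitted slope per coordinate, um/s).
#' @export
remove_drift <- function(traj) {
  stopifnot(inherits(traj, "trajectory_record"))
  tgrid <- traj$frame_index * traj$tau
  v <- numeric(traj$d)
  for (j in seq_len(traj$d)) {
    fit <- lm(traj$positions[, j] ~ tgrid)
    v[j] <- coef(fit)[2L]
    traj$positions[, j] <- fit$residuals
  }
  list(trajectory = traj, velocity = v)
}

#' Model-implied MSD of a fitted classifier
#'
#' The denoised power law `2 d D_alpha t^alpha`, optionally with the fitted
#' static-noise offset added back, for comparison against the empirical MSD.
#'
#' @param fit An `fbm_classifier`.
#' @param t Times (s).
#' @param include_noise Add the `2 d sigma2` noise-floor offset.
#' @return MSD values (um^2).
#' @export
implied_msd <- function(fit, t, include_noise = FALSE) {
  stopifnot(inherits(fit, "fbm_classifier"))
  out <- 2 * fit$d * fit$D_alpha * t^fit$alpha
  if (include_noise) out <- out + 2 * fit$d * fit$sigma2_static
  out
}
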