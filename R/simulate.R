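## Synthetic trajectory generators: exact fractional Gaussian paths plus the
## experimental contaminations the estimator must undo (static localization
## noise, motion blur, drift) and stuck-bead noise-floor controls.

## Autocovariance of fGn increments at integer lags `k` for unit frame
## interval: scale * (|k+1|^a - 2|k|^a + |k-1|^a), scale = D_alpha * tau^alpha.
fgn_autocov <- function(k, alpha, scale = 1) {
  scale * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

## One exact sample path of fGn (n increments) by Davies-Harte circulant
## embedding, falling back to Cholesky factorization of the Toeplitz
## covariance if the embedding is not non-negative definite.
## Returns increments; attr "method" records which path was taken.
fgn_sample <- function(n, alpha, scale, ncol = 1L) {
  g <- fgn_autocov(0:n, alpha, scale)
  m <- 2L * n
  ## circular embedding vector (gamma_0 .. gamma_n, gamma_{n-1} .. gamma_1)
  lam <- Re(fft(c(g[seq_len(n)], g[n + 1L], g[n:2])))
  method <- "circulant"
  if (min(lam) < -1e-8 * max(lam)) {
    ## exact fallback: factor the n x n Toeplitz covariance directly
    method <- "cholesky"
    L <- chol(stats::toeplitz(g[seq_len(n)]))
    out <- crossprod(L, matrix(rnorm(n * ncol), n, ncol))
    attr(out, "method") <- method
    return(out)
  }
  lam <- pmax(lam, 0)
  out <- matrix(0, n, ncol)
  for (j in seq_len(ncol)) {
    z <- complex(m)
    z[1L] <- sqrt(lam[1L]) * rnorm(1L)
    z[n + 1L] <- sqrt(lam[n + 1L]) * rnorm(1L)
    if (n > 1L) {
      a <- rnorm(n - 1L); b <- rnorm(n - 1L)
      z[2L:n] <- sqrt(lam[2L:n] / 2) * complex(real = a, imaginary = b)
      z[m:(n + 2L)] <- Conj(z[2L:n])
    }
    x <- Re(fft(z)) / sqrt(m)
    out[, j] <- x[seq_len(n)]
  }
  attr(out, "method") <- method
  out
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Generates an exact d-dimensional fBm path whose per-coordinate increment
#' autocovariance at lag k is `D_alpha tau^alpha (|k+1|^a - 2|k|^a +
#' |k-1|^a)`, so the d-dimensional MSD is `2 d D_alpha t^alpha`. Sampling is
#' exact via circulant embedding of the increment covariance (Davies-Harte),
#' with a Cholesky fallback when the embedding fails; the method used is
#' recorded in the `sim_method` attribute.
#'
#' @param alpha Subdiffusion exponent in (0, 1].
#' @param D_alpha MSD prefactor (um^2 / s^alpha).
#' @param N Number of increments (N + 1 positions are returned).
#' @param tau Frame interval (s).
#' @param d Spatial dimension (default 2).
#' @param seed Optional integer seed for reproducibility.
#' @param bead_id Identifier for the returned record.
#'
#' @return A [trajectory_record()] starting at the origin.
#' @export
simulate_fbm <- function(alpha, D_alpha, N, tau = 1 / 60, d = 2,
                         seed = NULL, bead_id = "fbm") {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (D_alpha <= 0) stop("D_alpha must be positive")
  if (!is.null(seed)) set.seed(seed)
  inc <- fgn_sample(N, alpha, D_alpha * tau^alpha, ncol = d)
  pos <- rbind(0, apply(inc, 2L, cumsum))
  out <- trajectory_record(pos, tau, bead_id = bead_id)
  attr(out, "sim_method") <- attr(inc, "method")
  out
}

#' Add static localization noise to a trajectory
#'
#' Adds independent zero-mean Gaussian localization error of standard
#' deviation `sigma` per coordinate per frame, the "static" camera error
#' that raises the MSD by a constant `2 d sigma^2`.
#'
#' @param traj A `trajectory_record`.
#' @param sigma Noise SD (um), >= 0.
#' @param seed Optional integer seed.
#' @return A `trajectory_record` with perturbed positions.
#' @export
add_static_noise <- function(traj, sigma, seed = NULL) {
  stopifnot(inherits(traj, "trajectory_record"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(traj)
  if (!is.null(seed)) set.seed(seed)
  traj$positions <- traj$positions +
    matrix(rnorm(length(traj$positions), 0, sigma), nrow(traj$positions))
  traj
}

#' Apply camera motion blur to a finely sampled trajectory
#'
#' Emulates dynamic localization error: each reported frame position is the
#' average of the substep positions falling inside the open-shutter window
#' at the start of the frame interval. The input must be sampled on a
#' substep grid commensurate with the output frame interval; blur is
#' computed by brute-force averaging so it can serve as an independent check
#' of the estimator's moving-average blur model.
#'
#' @param traj_substeps A `trajectory_record` sampled at `tau / substeps`.
#' @param substeps Substeps per output frame (>= 10).
#' @param shutter_fraction Fraction of the frame interval the shutter is
#'   open, in (0, 1]. As it approaches 0 the output reduces to point
#'   sampling.
#' @return A `trajectory_record` at the coarse frame interval.
#' @export
add_dynamic_blur <- function(traj_substeps, substeps, shutter_fraction) {
  stopifnot(inherits(traj_substeps, "trajectory_record"))
  if (substeps < 10L) stop("need at least 10 substeps per frame")
  if (shutter_fraction <= 0 || shutter_fraction > 1)
    stop("shutter_fraction must lie in (0, 1]")
  n_sub <- nrow(traj_substeps$positions) - 1L
  if (n_sub %% substeps != 0L)
    stop("substep grid is not commensurate with the output frame interval")
  K <- max(1L, round(shutter_fraction * substeps))
  N_frames <- (n_sub - (K - 1L)) %/% substeps
  if (N_frames < 2L) stop("too few substeps for the requested blur window")
  X <- traj_substeps$positions
  pos <- matrix(0, N_frames + 1L, ncol(X))
  for (j in 0:N_frames) {
    idx <- j * substeps + seq_len(K)
    pos[j + 1L, ] <- colMeans(X[idx, , drop = FALSE])
  }
  trajectory_record(pos, traj_substeps$tau * substeps,
                    bead_id = traj_substeps$bead_id)
}

#' Add deterministic linear drift
#'
#' Superposes slow transport `v * t` on each coordinate.
#'
#' @param traj A `trajectory_record`.
#' @param velocity Drift velocity per coordinate (um/s); recycled to d.
#' @return A `trajectory_record`.
#' @export
add_drift <- function(traj, velocity) {
  stopifnot(inherits(traj, "trajectory_record"))
  velocity <- rep_len(velocity, traj$d)
  tgrid <- traj$frame_index * traj$tau
  traj$positions <- traj$positions + outer(tgrid, velocity)
  traj
}

#' Simulate a stuck (noise-floor) bead
#'
#' Pure static localization noise about a fixed location, with no mobility
#' signal: the control that defines the instrument's noise floor, as
#' obtained experimentally by tracking beads glued to a slide. Its MSD is
#' flat at `2 d sigma^2`.
#'
#' @inheritParams simulate_fbm
#' @param sigma Localization noise SD (um), > 0 for a realistic control
#'   (0 returns a constant trajectory).
#' @return A [trajectory_record()].
#' @export
simulate_stuck_bead <- function(sigma, N, tau = 1 / 60, d = 2, seed = NULL,
                                bead_id = "stuck") {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(rnorm((N + 1L) * d, 0, sigma), N + 1L, d)
  trajectory_record(pos, tau, bead_id = bead_id)
}

#' Specification of a normal classifier cluster
#'
#' One mixture component of the classifier plane: per-bead `(alpha,
#' D_alpha)` are drawn as independent normals (independence reflects absence
#' of knowledge about their correlation) truncated by resampling to
#' `alpha` in (0, 1] and `D_alpha > 0`.
#'
#' @param weight Mixing proportion.
#' @param mean Length-2 vector: mean `(alpha, D_alpha)`.
#' @param sd Length-2 vector of standard deviations, >= 0.
#' @param label Cluster label.
#' @return A `cluster_spec` object.
#' @export
cluster_spec <- function(weight, mean, sd, label) {
  stopifnot(length(mean) == 2L, length(sd) == 2L, all(sd >= 0), weight >= 0)
  structure(list(weight = weight, mean = mean, sd = sd, label = label),
            class = "cluster_spec")
}

#' @rdname cluster_spec
#' @details `water_like_spec()` and `flake_like_spec()` carry the reference
#'   study conditions for dilute (water-like) and flake-like mucus signals:
#'   means (0.85, 0.35) with SDs (0.03, 0.02), and means (0.3, 0.05) with
#'   SDs (0.07, 0.02) respectively.
#' @export
water_like_spec <- function(weight = 0.5)
  cluster_spec(weight, c(0.85, 0.35), c(0.03, 0.02), "water_like")

#' @rdname cluster_spec
#' @export
flake_like_spec <- function(weight = 0.5)
  cluster_spec(weight, c(0.3, 0.05), c(0.07, 0.02), "flake_like")

## Draw one (alpha, D_alpha) pair from a cluster spec, resampling out-of-range
## values (alpha outside (0,1] causes anomalous moduli; D_alpha must be > 0).
draw_classifier <- function(spec) {
  repeat {
    a <- rnorm(1L, spec$mean[1L], spec$sd[1L])
    if (a > 0 && a <= 1) break
  }
  repeat {
    D <- rnorm(1L, spec$mean[2L], spec$sd[2L])
    if (D > 0) break
  }
  c(alpha = a, D_alpha = D)
}

#' Simulate a heterogeneous bead ensemble
#'
#' Draws, for each bead, a cluster by the mixing weights, a true classifier
#' `(alpha, D_alpha)` from that cluster's truncated normal law, simulates an
#' exact fBm path, and applies the requested contaminations. Optionally a
#' fraction of beads are stuck-bead (noise-floor) controls carrying no
#' signal. The ground truth used for generation is returned alongside the
#' trajectories.
#'
#' @param specs List of [cluster_spec()] objects; weights are normalized and
#'   must not all be zero.
#' @param M Number of signal beads.
#' @param N Increments per trajectory.
#' @param tau Frame interval (s); default 1/60 (camera-limited).
#' @param d Spatial dimension.
#' @param sigma_static Static localization noise SD (um) applied to every
#'   signal bead (0 = none).
#' @param drift Optional per-coordinate drift velocity (um/s).
#' @param n_stuck Number of additional stuck beads appended to the ensemble.
#' @param stuck_sigma Noise SD of the stuck beads (um).
#' @param field_of_view Side length (um) of the square imaging field over
#'   which initial bead positions are scattered uniformly (so that
#'   proximity filtering is meaningful); 0 starts every bead at the origin.
#' @param seed Optional integer seed governing all draws.
#'
#' @return A list with `trajectories` (list of `trajectory_record`) and
#'   `truth` (data frame: bead_id, label, alpha, D_alpha; stuck beads have
#'   `NA` classifiers).
#' @export
simulate_ensemble <- function(specs, M, N, tau = 1 / 60, d = 2,
                              sigma_static = 0, drift = NULL,
                              n_stuck = 0L, stuck_sigma = 0.05,
                              field_of_view = 200, seed = NULL) {
  if (inherits(specs, "cluster_spec")) specs <- list(specs)
  w <- vapply(specs, function(s) s$weight, numeric(1L))
  if (all(w == 0)) stop("all cluster weights are zero")
  w <- w / sum(w)
  if (!is.null(seed)) set.seed(seed)
  trajs <- vector("list", M + n_stuck)
  truth <- data.frame(bead_id = character(M + n_stuck),
                      label = character(M + n_stuck),
                      alpha = NA_real_, D_alpha = NA_real_)
  scatter <- function(tr) {
    if (field_of_view > 0)
      tr$positions <- sweep(tr$positions, 2L,
                            stats::runif(d, 0, field_of_view), `+`)
    tr
  }
  for (i in seq_len(M)) {
    k <- sample.int(length(specs), 1L, prob = w)
    th <- draw_classifier(specs[[k]])
    id <- sprintf("bead%03d", i)
    tr <- simulate_fbm(th[1L], th[2L], N = N, tau = tau, d = d, bead_id = id)
    if (!is.null(drift)) tr <- add_drift(tr, drift)
    if (sigma_static > 0) tr <- add_static_noise(tr, sigma_static)
    trajs[[i]] <- scatter(tr)
    truth[i, ] <- list(id, specs[[k]]$label, th[1L], th[2L])
  }
  for (i in seq_len(n_stuck)) {
    id <- sprintf("stuck%03d", i)
    trajs[[M + i]] <- scatter(
      simulate_stuck_bead(stuck_sigma, N = N, tau = tau, d = d,
                          bead_id = id))
    truth[M + i, c("bead_id", "label")] <- list(id, "noise_floor")
  }
  list(trajectories = trajs, truth = truth)
}
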