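#' Tracked-bead trajectory record
#'
#' Container for one bead's uniformly sampled position time series. Positions
#' are in micrometres; `tau` is the frame interval in seconds. With `N + 1`
#' recorded positions the series supports lags `1..N`.
#'
#' @param positions Numeric matrix with one row per frame and one column per
#'   spatial coordinate (micrometres). A vector is treated as one coordinate.
#' @param tau Frame interval in seconds (> 0).
#' @param bead_id Identifier for the bead.
#' @param frame_index Integer frame indices aligned with `positions`
#'   (default `0:N`). Must be strictly increasing.
#'
#' @return An object of class `trajectory_record` with fields `bead_id`,
#'   `positions`, `tau`, `d`, `frame_index`.
#' @export
trajectory_record <- function(positions, tau, bead_id = "bead",
                              frame_index = NULL) {
  if (is.vector(positions)) positions <- matrix(positions, ncol = 1)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) < 3L)
    stop("a trajectory needs at least 3 positions (N >= 2)")
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  if (is.null(frame_index)) frame_index <- seq_len(nrow(positions)) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nrow(positions))
    stop("frame_index must align with positions")
  if (any(diff(frame_index) <= 0L))
    stop("frame_index must be strictly increasing")
  structure(
    list(bead_id = bead_id, positions = positions, tau = tau,
         d = ncol(positions), frame_index = frame_index),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record '%s': N = %d, d = %d, tau = %.5g s>\n",
              x$bead_id, nrow(x$positions) - 1L, x$d, x$tau))
  invisible(x)
}

#' Number of increments of a trajectory
#' @param traj A `trajectory_record`.
#' @return Integer N such that the record holds N + 1 positions.
#' @export
n_increments <- function(traj) nrow(traj$positions) - 1L

#' Material and imaging context
#'
#' Physical constants of the experiment needed to convert mean-squared
#' displacements to dynamic moduli and to non-dimensionalize classifiers:
#' bead radius, absolute temperature and the viscosity of the reference
#' (solvent) fluid, typically water.
#'
#' @param radius Bead radius in metres.
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Solvent dynamic viscosity in pascal-seconds
#'   (water at 20 C: 1.002e-3).
#'
#' @return An object of class `material_context`.
#' @export
material_context <- function(radius = 0.5e-6, temperature = 293.15,
                             viscosity = 1.002e-3) {
  if (radius <= 0 || temperature <= 0 || viscosity <= 0)
    stop("radius, temperature and viscosity must all be positive")
  structure(list(radius = radius, temperature = temperature,
                 viscosity = viscosity, kB = .kB),
            class = "material_context")
}

#' Time-averaged mean-squared displacement
#'
#' Computes the overlapping-window time average of squared Euclidean
#' displacements of a single trajectory,
#' `MSD(n tau) = mean_j || X_{j+n} - X_j ||^2`, averaging over the
#' `N - n + 1` available start frames at each lag.
#'
#' @param traj A `trajectory_record` with contiguous frames.
#' @param max_lag Largest lag (in frames) to compute. Defaults to
#'   `floor(N / 2)`: long-lag averages rest on very few displacement pairs
#'   and are statistically unreliable.
#'
#' @return An object of class `empirical_msd`: a data frame with columns
#'   `lag` (frames), `time` (seconds), `msd` (square micrometres) and
#'   `n_pairs`.
#' @export
empirical_msd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory_record"))
  if (any(diff(traj$frame_index) != 1L))
    stop("trajectory has missing frames; apply uniformity_filter() first")
  N <- n_increments(traj)
  if (is.null(max_lag)) max_lag <- max(1L, N %/% 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag > N)
    stop("max_lag must be between 1 and N")
  X <- traj$positions
  vals <- numeric(max_lag)
  npairs <- integer(max_lag)
  n1 <- nrow(X)
  for (n in seq_len(max_lag)) {
    dx <- X[(n + 1L):n1, , drop = FALSE] - X[1L:(n1 - n), , drop = FALSE]
    vals[n] <- mean(rowSums(dx^2))
    npairs[n] <- n1 - n
  }
  out <- data.frame(lag = seq_len(max_lag), time = seq_len(max_lag) * traj$tau,
                    msd = vals, n_pairs = npairs)
  class(out) <- c("empirical_msd", "data.frame")
  attr(out, "bead_id") <- traj$bead_id
  attr(out, "d") <- traj$d
  out
}

#' Power-law MSD of fractional Brownian motion
#'
#' `MSD(t) = 2 d D_alpha t^alpha`, the mean-squared displacement of
#' d-dimensional fBm with subdiffusion exponent `alpha` and prefactor
#' `D_alpha` (units um^2 / s^alpha). Reduces to ordinary diffusion
#' `2 d D t` at `alpha = 1`.
#'
#' @param alpha Power-law exponent in (0, 1] (values above 1 allowed only
#'   with `allow_super = TRUE`, for diagnostics).
#' @param D_alpha MSD prefactor (um^2 / s^alpha), positive.
#' @param t Time (s), positive; vectorized.
#' @param d Spatial dimension (default 2: beads tracked in a focal plane).
#' @param allow_super Permit `alpha > 1` (super-diffusive diagnostics).
#'
#' @return MSD values in square micrometres.
#' @export
fbm_msd <- function(alpha, D_alpha, t, d = 2, allow_super = FALSE) {
  amax <- if (allow_super) 2 else 1
  if (alpha <= 0 || alpha > amax)
    stop("alpha must lie in (0, ", amax, "]")
  if (D_alpha <= 0) stop("D_alpha must be positive")
  if (any(t <= 0)) stop("t must be positive")
  2 * d * D_alpha * t^alpha
}

#' Power-law MSD contaminated by a static noise floor
#'
#' Static localization error of standard deviation `sigma` per coordinate
#' adds a constant offset `2 d sigma^2` to the MSD (for d = 2 the familiar
#' `+ 4 sigma^2`): `MSD(t) = 2 d D_alpha t^alpha + 2 d sigma^2`.
#'
#' @inheritParams fbm_msd
#' @param sigma Static localization noise SD per coordinate (um), >= 0.
#' @return MSD values in square micrometres.
#' @export
noisy_fbm_msd <- function(alpha, D_alpha, sigma, t, d = 2,
                          allow_super = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative")
  fbm_msd(alpha, D_alpha, t, d = d, allow_super = allow_super) +
    2 * d * sigma^2
}

#' Stokes-Einstein diffusivity of the reference fluid
#'
#' `Dw = kB T / (6 pi eta r)`, the diffusivity of a bead of the context's
#' radius in the context's solvent, returned in um^2/s.
#'
#' @param ctx A [material_context()].
#' @return Diffusivity in square micrometres per second.
#' @export
water_diffusivity <- function(ctx) {
  stopifnot(inherits(ctx, "material_context"))
  D_si <- ctx$kB * ctx$temperature / (6 * pi * ctx$viscosity * ctx$radius)
  D_si * 1e12
}
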