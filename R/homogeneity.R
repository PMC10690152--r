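## Cochran's Q test of classifier homogeneity across beads, using each
## bead's estimated classifier covariance.

## Symmetric (eigendecomposition) inverse square root of an SPD matrix.
.inv_sqrt <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) return(NULL)
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Cochran's Q homogeneity test
#'
#' Tests whether M per-bead classifier estimates share a common true value,
#' given each estimate's covariance. The default (`form = "weighted"`) is
#' the classical inverse-variance-weighted statistic
#' `Q = sum_i (theta_i - theta_w)' V_i^{-1} (theta_i - theta_w)` about the
#' precision-weighted mean `theta_w`; under homogeneity it is exactly
#' chi-squared with `p (M - 1)` degrees of freedom, and it is invariant
#' under any affine reparameterization of the classifier (so the test
#' gives identical results on `(alpha, log Delta)` and
#' `(alpha, log Dtilde)`). The compact whitened form
#' (`form = "whitened"`), `Q = sum_i ||Z_i - Zbar||^2` with
#' `Z_i = V_i^{-1/2} theta_i` using the symmetric eigendecomposition
#' square root, coincides with the weighted form whenever all covariances
#' are equal, but with heterogeneous covariances its null distribution is
#' a noncentral chi-squared that depends on the common classifier value
#' (the whitening maps a shared mean to different `Z` means); it is
#' retained for sensitivity analysis only.
#'
#' @param estimates M x p matrix (or list of length-p vectors) of per-bead
#'   classifier estimates, e.g. `(alpha, log Delta)`.
#' @param covariances List of M symmetric positive-definite p x p matrices.
#' @param epsilon Test level (default 0.05).
#' @param form `"weighted"` (default, chi-squared calibrated and affine
#'   invariant) or `"whitened"` (the compact mean-of-whitened-estimates
#'   form).
#'
#' @return An object of class `cochran_q`: `Q`, `df = p (M - 1)`,
#'   `p_value`, `M`, `p`, `epsilon`, `reject`, and `low_power` (`TRUE` for
#'   clusters of fewer than 4 beads, reported but flagged).
#' @export
cochran_q <- function(estimates, covariances, epsilon = 0.05,
                      form = c("weighted", "whitened")) {
  form <- match.arg(form)
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  th <- as.matrix(estimates)
  M <- nrow(th); p <- ncol(th)
  if (M < 2L) stop("need at least 2 beads to test homogeneity")
  if (length(covariances) != M)
    stop("need one covariance per bead")
  if (form == "whitened") {
    Z <- matrix(0, M, p)
    for (i in seq_len(M)) {
      W <- .inv_sqrt(covariances[[i]])
      if (is.null(W))
        stop(sprintf("covariance of bead %d is not positive definite", i))
      Z[i, ] <- W %*% th[i, ]
    }
    Zbar <- colMeans(Z)
    Q <- sum(sweep(Z, 2L, Zbar)^2)
  } else {
    Vinv <- vector("list", M)
    for (i in seq_len(M)) {
      V <- (covariances[[i]] + t(covariances[[i]])) / 2
      if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values <= 0))
        stop(sprintf("covariance of bead %d is not positive definite", i))
      Vinv[[i]] <- solve(V)
    }
    P <- Reduce(`+`, Vinv)
    b <- Reduce(`+`, lapply(seq_len(M), function(i) Vinv[[i]] %*% th[i, ]))
    thw <- solve(P, b)
    Q <- sum(vapply(seq_len(M), function(i) {
      r <- th[i, ] - as.numeric(thw)
      as.numeric(t(r) %*% Vinv[[i]] %*% r)
    }, numeric(1L)))
  }
  df <- p * (M - 1L)
  structure(
    list(Q = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE),
         M = M, p = p, epsilon = epsilon,
         reject = Q > qchisq(1 - epsilon, df),
         low_power = M < 4L, form = form),
    class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf(
    "Cochran's Q homogeneity test%s\n  Q = %.3f, df = %d, p-value = %.3g\n  %s at level %.3g (M = %d beads%s)\n",
    if (x$form == "whitened") " (whitened form)" else "",
    x$Q, x$df, x$p_value,
    if (x$reject) "homogeneity REJECTED" else "homogeneity not rejected",
    x$epsilon, x$M, if (x$low_power) "; low power, M < 4" else ""))
  invisible(x)
}
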