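## Finite normal-mixture clustering of bead classifiers with BIC model
## selection, backed by the mclust EM machinery. Six covariance-constraint
## families are exposed (spherical/diagonal/full x equal/varying), the
## subset of mclust's fourteen that covers the constrained-vs-unconstrained
## behaviors relevant to classifier-plane clustering without
## orientation-only families.

.constraint_models <- c(
  "spherical-equal"   = "EII",
  "spherical-varying" = "VII",
  "diagonal-equal"    = "EEI",
  "diagonal-varying"  = "VVI",
  "full-equal"        = "EEE",
  "full-varying"      = "VVV")

#' Constraint families available for mixture clustering
#' @return Character vector of the six covariance-constraint family names.
#' @export
mixture_constraints <- function() names(.constraint_models)

.as_points <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L) stop("points must be M x 2")
  if (!all(is.finite(pts))) stop("points must be finite")
  pts
}

#' Fit a K-component normal mixture under a covariance constraint
#'
#' EM fit of a bivariate normal mixture to classifier points (e.g.
#' `(alpha, log Delta)`), under one of six covariance-constraint families.
#' Initialization is mclust's deterministic model-based hierarchical
#' agglomeration, so fits are reproducible without a seed.
#'
#' @param points M x 2 matrix of classifier points.
#' @param K Number of components (M >= K).
#' @param constraint One of [mixture_constraints()] (default
#'   `"full-varying"`, the unconstrained family).
#'
#' @return An object of class `pptm_mixture`: `K`, `weights`, `means`
#'   (K x 2), `covariances` (2 x 2 x K array), `constraint`, `loglik`,
#'   `n_params`, and `bic` in the minimized convention
#'   `-2 loglik + n_params log M`.
#' @export
fit_mixture <- function(points, K, constraint = "full-varying") {
  pts <- .as_points(points)
  constraint <- match.arg(constraint, names(.constraint_models))
  if (nrow(pts) < K) stop("need at least K points to fit K components")
  model <- .constraint_models[[constraint]]
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
  fit <- tryCatch(
    mclust::Mclust(pts, G = K, modelNames = model, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    stop(sprintf("mixture fit failed for K = %d, constraint '%s'", K, constraint))
  pars <- fit$parameters
  means <- t(pars$mean)
  if (K == 1L) means <- matrix(pars$mean, 1L, 2L)
  colnames(means) <- colnames(pts) %||% c("x1", "x2")
  covs <- pars$variance$sigma
  if (length(dim(covs)) == 2L) covs <- array(covs, c(2L, 2L, K))
  npar <- mclust::nMclustParams(model, d = 2L, G = K)
  structure(
    list(K = K, weights = as.numeric(pars$pro), means = means,
         covariances = covs, constraint = constraint,
         loglik = fit$loglik, n_params = npar,
         bic = -2 * fit$loglik + npar * log(nrow(pts)),
         model_name = model, mclust = fit),
    class = "pptm_mixture")
}

#' @export
print.pptm_mixture <- function(x, ...) {
  cat(sprintf("<pptm_mixture: K = %d, constraint = %s, BIC = %.2f>\n",
              x$K, x$constraint, x$bic))
  invisible(x)
}

#' BIC model selection over component counts and constraint families
#'
#' Fits every combination of `K = 1..Kmax` and the requested constraint
#' families, and returns the fit minimizing `BIC = -2 loglik +
#' n_params log M`. Ties are broken toward smaller `K`, then toward the
#' simpler constraint (in the order of [mixture_constraints()]).
#'
#' @inheritParams fit_mixture
#' @param Kmax Largest component count considered (>= 1).
#' @param constraints Subset of [mixture_constraints()] (default all six).
#'
#' @return The selected `pptm_mixture`, with the full candidate table in
#'   `$bic_table` and any failed fits in `$failures`.
#' @export
select_model <- function(points, Kmax, constraints = mixture_constraints()) {
  pts <- .as_points(points)
  if (Kmax < 1L) stop("Kmax must be at least 1")
  constraints <- match.arg(constraints, names(.constraint_models),
                           several.ok = TRUE)
  ## keep canonical simple-to-complex order for tie-breaking
  constraints <- names(.constraint_models)[names(.constraint_models) %in% constraints]
  grid <- expand.grid(constraint = constraints, K = seq_len(Kmax),
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  bics <- rep(Inf, nrow(grid))
  fails <- character(0L)
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(fit_mixture(pts, grid$K[i], grid$constraint[i]),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) { fails <- c(fails, f); next }
    fits[[i]] <- f
    bics[i] <- f$bic
  }
  if (all(is.infinite(bics)))
    stop("all mixture fits failed:\n", paste(unique(fails), collapse = "\n"))
  ## ties toward smaller K, then simpler constraint: order the grid that way
  ord <- order(grid$K, match(grid$constraint, names(.constraint_models)))
  best <- ord[which.min(bics[ord])]
  out <- fits[[best]]
  out$bic_table <- data.frame(grid, bic = bics)[order(bics), ]
  out$failures <- fails
  out
}

#' Posterior component membership
#'
#' Posterior probabilities of each point under each mixture component, and
#' the maximum-a-posteriori hard label. Exact ties are broken toward the
#' lowest component index.
#'
#' @param model A `pptm_mixture`.
#' @param points M x 2 matrix of points to assign.
#' @return A list with `label` (integer vector) and `prob` (M x K matrix of
#'   posterior probabilities, rows summing to 1).
#' @export
posterior_assign <- function(model, points) {
  stopifnot(inherits(model, "pptm_mixture"))
  pts <- .as_points(points)
  logd <- vapply(seq_len(model$K), function(k) {
    mu <- model$means[k, ]
    S <- model$covariances[, , k]
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), 2L) %*%
      t(e$vectors)
    z2 <- rowSums((sweep(pts, 2L, mu) %*% W)^2)
    -0.5 * (z2 + sum(log(pmax(e$values, 1e-300))) + 2 * log(2 * pi)) +
      log(model$weights[k])
  }, numeric(nrow(pts)))
  logd <- matrix(logd, nrow = nrow(pts))
  z <- exp(logd - apply(logd, 1L, max))
  z <- z / rowSums(z)
  list(label = max.col(z, ties.method = "first"), prob = z)
}
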