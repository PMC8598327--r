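# Gaussian-mixture fusion of the final cascade layer's component classifiers.
# Component score vectors are first unified by a per-column batch
# standardization (the 1x1-convolution + batch-norm analog: an affine map per
# score column, no cross-column mixing, statistics frozen after fitting).
# A scalar summary per component — the standardized score the component
# assigns to a sample's true class — is then modeled as a mixture over
# components, with per-(component, class) Gaussians and shared component
# weights, fitted by expectation-maximization. The learned weights fuse the
# components' class-probability vectors at prediction time.

#' Gaussian probability density
#'
#' `N(y; mu, var) = exp(-(y - mu)^2 / (2 var)) / sqrt(2 pi var)`.
#'
#' @param y Numeric vector of evaluation points.
#' @param mean Mean.
#' @param var Variance (> 0).
#' @return Density values.
#' @export
gaussian_density <- function(y, mean, var) {
  if (any(var <= 0)) stop_dsn("variance must be positive")
  exp(-(y - mean)^2 / (2 * var)) / sqrt(2 * pi * var)
}

# Batch statistics: consecutive chunks of `batch_size` rows contribute their
# per-column mean and population variance, averaged with chunk-size weights
# (the batch-normalization running-statistics convention; equal to full-batch
# statistics for the mean, and to the mean within-batch variance otherwise).
batch_stats <- function(X, batch_size) {
  n <- nrow(X)
  starts <- seq.int(1L, n, by = batch_size)
  mu <- matrix(0, length(starts), ncol(X))
  vr <- matrix(0, length(starts), ncol(X))
  wt <- numeric(length(starts))
  for (b in seq_along(starts)) {
    rows <- starts[b]:min(starts[b] + batch_size - 1L, n)
    Xb <- X[rows, , drop = FALSE]
    mu[b, ] <- colMeans(Xb)
    vr[b, ] <- colMeans(Xb^2) - mu[b, ]^2
    wt[b] <- length(rows)
  }
  wt <- wt / sum(wt)
  list(mean = colSums(mu * wt), var = pmax(colSums(vr * wt), 0))
}

#' Unify component score vectors by batch standardization
#'
#' Affinely maps every score column of every component to zero mean and unit
#' variance over the fitting batches (population convention), freezing the
#' statistics for later inference. Zero-variance columns keep unit scale (so a
#' constant column maps to all zeros) with a warning.
#'
#' @param scores List of `m x P` component score matrices (rows sum to 1).
#' @param batch_size Rows per statistics batch; statistics are the
#'   size-weighted average of per-batch moments.
#' @param unifier Optional frozen statistics from a previous call, to
#'   standardize new scores for inference.
#' @return List with `scores` (standardized matrices) and `unifier` (the
#'   frozen per-component means/standard deviations).
#' @export
unify_scores <- function(scores, batch_size = 64L, unifier = NULL) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  m <- nrow(scores[[1L]])
  if (!all(vapply(scores, nrow, 0L) == m)) {
    stop_dsn("component score matrices have differing row counts")
  }
  if (is.null(unifier)) {
    unifier <- lapply(scores, function(S) {
      st <- batch_stats(S, batch_size)
      sd <- sqrt(st$var)
      if (any(sd <= 1e-12)) {
        warn_dsn("zero-variance score column(s); keeping unit scale")
        sd[sd <= 1e-12] <- 1
      }
      list(mean = st$mean, sd = sd)
    })
  }
  std <- lapply(seq_along(scores), function(i) {
    u <- unifier[[i]]
    sweep(sweep(scores[[i]], 2L, u$mean, "-"), 2L, u$sd, "/")
  })
  list(scores = std, unifier = unifier)
}

#' Expectation-maximization for a Gaussian mixture over components
#'
#' The EM engine behind [fit_fusion()]. Column `i` of `Y` holds the scalar
#' observation attributed to mixture component `i` for each sample; `classes`
#' optionally indexes per-class Gaussian parameters within each component
#' (a single shared class when `NULL`). The E-step computes responsibilities
#' `gamma[j, i]` proportional to `w[i] * N(Y[j, i]; mu[i, c_j], var[i, c_j])`,
#' normalized to sum to 1 over components; the M-step re-estimates component
#' weights as mean responsibilities and the per-(component, class) means and
#' variances as responsibility-weighted moments. Iterations continue until the
#' change in the mixture log-likelihood `sum_j log sum_i w_i N(y_ji)` falls
#' below `tol` or `max_iter` is reached; the log-likelihood trace is
#' non-decreasing. Collapsing variances are floored at `var_floor`.
#'
#' @param Y `m x n` matrix of per-component scalar observations.
#' @param classes Optional integer vector (length `m`) of 1-based class
#'   indices.
#' @param weights,mu,var Optional initial values: `weights` length `n`;
#'   `mu`, `var` are `n x C` matrices (`C` = number of classes). Defaults:
#'   uniform weights, per-(component, class) sample moments.
#' @param max_iter Iteration cap.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param var_floor Lower bound applied to variances.
#' @return List with `weights`, `mu`, `var`, `gamma` (final responsibilities),
#'   `loglik` (trace) and `iterations`.
#' @export
em_mixture <- function(Y, classes = NULL, weights = NULL, mu = NULL,
                       var = NULL, max_iter = 100L, tol = 1e-6,
                       var_floor = 1e-6) {
  Y <- as.matrix(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (m < 1L || n < 1L) stop_dsn("Y must be a non-empty matrix")
  if (is.null(classes)) classes <- rep(1L, m)
  classes <- as.integer(classes)
  C <- max(classes)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (is.null(mu) || is.null(var)) {
    mu0 <- matrix(0, n, C); var0 <- matrix(1, n, C)
    for (cc in seq_len(C)) {
      rows <- classes == cc
      if (any(rows)) {
        mu0[, cc] <- colMeans(Y[rows, , drop = FALSE])
        var0[, cc] <- pmax(colMeans(Y[rows, , drop = FALSE]^2) - mu0[, cc]^2,
                           var_floor)
      }
    }
    if (is.null(mu)) mu <- mu0
    if (is.null(var)) var <- var0
  }
  mu <- matrix(mu, n, C); var <- pmax(matrix(var, n, C), var_floor)
  weights <- weights / sum(weights)

  loglik <- numeric(0)
  gamma <- matrix(1 / n, m, n)
  for (iter in seq_len(max_iter)) {
    # E-step
    dens <- matrix(0, m, n)
    for (i in seq_len(n)) {
      dens[, i] <- gaussian_density(Y[, i], mu[i, classes], var[i, classes])
    }
    wd <- sweep(dens, 2L, weights, "*")
    rs <- rowSums(wd)
    rs[rs <= 0 | !is.finite(rs)] <- .Machine$double.xmin
    ll <- sum(log(rs))
    gamma <- wd / rs
    loglik <- c(loglik, ll)
    if (length(loglik) > 1L &&
        abs(loglik[length(loglik)] - loglik[length(loglik) - 1L]) < tol) {
      break
    }
    # M-step
    weights <- colMeans(gamma)
    weights <- weights / sum(weights)
    for (cc in seq_len(C)) {
      rows <- which(classes == cc)
      if (length(rows) == 0L) next
      g <- gamma[rows, , drop = FALSE]
      yc <- Y[rows, , drop = FALSE]
      tot <- colSums(g)
      upd <- tot > 1e-12
      mu_new <- colSums(g * yc) / pmax(tot, 1e-12)
      mu[upd, cc] <- mu_new[upd]
      var_new <- colSums(g * sweep(yc, 2L, mu[, cc], "-")^2) / pmax(tot, 1e-12)
      var[upd, cc] <- pmax(var_new[upd], var_floor)
    }
  }
  list(weights = weights, mu = mu, var = var, gamma = gamma,
       loglik = loglik, iterations = length(loglik))
}

#' Fit Gaussian-mixture fusion parameters on component classifier scores
#'
#' Standardizes each component's class-score columns with [unify_scores()],
#' extracts per sample the standardized score each component assigns to the
#' sample's true class, and fits the component mixture by [em_mixture()]:
#' per-(component, class) Gaussian means/variances and shared component
#' weights on the simplex.
#'
#' @param scores List of `m x P` class-probability matrices, one per component
#'   classifier (rows sum to 1).
#' @param labels Label factor of length `m` (true classes).
#' @param max_iter EM iteration cap (the "epochs" hyperparameter; default
#'   100).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param batch_size Batch size for the unifying standardization (default 64).
#' @return Object of class `dsn_fusion`: weights, per-(component, class)
#'   Gaussians, final responsibilities, log-likelihood trace and the frozen
#'   unifier.
#' @export
fit_fusion <- function(scores, labels, max_iter = 100L, tol = 1e-6,
                       batch_size = 64L) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  labels <- as.factor(labels)
  m <- length(labels)
  if (nrow(scores[[1L]]) != m) stop_dsn("scores and labels disagree on m")
  uni <- unify_scores(scores, batch_size = batch_size)
  cls <- as.integer(labels)
  Y <- vapply(uni$scores, function(S) S[cbind(seq_len(m), cls)], numeric(m))
  Y <- matrix(Y, nrow = m)
  em <- em_mixture(Y, classes = cls, max_iter = max_iter, tol = tol)
  structure(list(weights = em$weights, mu = em$mu, var = em$var,
                 gamma = em$gamma, loglik = em$loglik,
                 iterations = em$iterations,
                 unifier = uni$unifier,
                 class_levels = levels(labels),
                 n_components = length(scores),
                 batch_size = as.integer(batch_size)),
            class = "dsn_fusion")
}

#' @export
print.dsn_fusion <- function(x, ...) {
  cat(sprintf("dsn_fusion: %d components, %d classes, %d EM iterations\n",
              x$n_components, length(x$class_levels), x$iterations))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Fuse component class probabilities with learned mixture weights
#'
#' The fused probability of class `c` is the weight-averaged component
#' probability `sum_i w_i p_ic`, renormalized to sum to 1 per row.
#'
#' @param scores List of `m x P` class-probability matrices (raw, not
#'   standardized), in the component order used at fit time.
#' @param params A `dsn_fusion` from [fit_fusion()].
#' @return `m x P` matrix of fused class probabilities.
#' @export
fuse_predict <- function(scores, params) {
  stopifnot(inherits(params, "dsn_fusion"))
  if (length(scores) != params$n_components) {
    stop_dsn("component count mismatch: params have %d, scores %d",
             params$n_components, length(scores))
  }
  fused <- Reduce(`+`, Map(function(S, w) S * w, scores,
                           as.list(params$weights)))
  fused <- normalize_rows(pmax(fused, 0))
  colnames(fused) <- params$class_levels
  fused
}
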