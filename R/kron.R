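#' Scalable linear algebra for factored covariances
#'
#' All artifact-model operations (solves, log-determinants, posterior means,
#' sampling) reduce to per-factor eigendecompositions plus tensor
#' mode-products, so their cost is cubic in the largest factor dimension
#' rather than in the total dimension. No dense matrix of the total size is
#' ever allocated by these routines.
#'
#' @name kron
NULL

# Mode-k tensor-times-matrix product: applies M (m x d_k) along dimension
# `mode` of array X, returning an array with that dimension of size m.
.mode_prod <- function(X, M, mode) {
  d <- dim(X)
  if (is.null(d)) d <- length(X)
  k <- length(d)
  if (ncol(M) != d[mode]) stop("mode-product size mismatch")
  if (k == 1L) return(as.vector(M %*% as.vector(X)))
  perm <- c(mode, seq_len(k)[-mode])
  Xp <- aperm(X, perm)
  dim(Xp) <- c(d[mode], prod(d[-mode]))
  Y <- M %*% Xp
  dim(Y) <- c(nrow(M), d[-mode])
  aperm(Y, order(perm))
}

# Array of Kronecker eigenvalue products kappa_m, laid out to match the
# column-major vectorization of [time, electrode, stimulus] arrays.
.kappa <- function(eig) {
  Reduce(function(a, b) outer(a, b), lapply(eig, function(e) e$values))
}

# Transform an array to / from the joint factor eigenbasis.
.to_eigbasis <- function(X, eig) {
  for (k in seq_along(eig)) X <- .mode_prod(X, t(eig[[k]]$vectors), k)
  X
}
.from_eigbasis <- function(X, eig) {
  for (k in seq_along(eig)) X <- .mode_prod(X, eig[[k]]$vectors, k)
  X
}

.as_factor_array <- function(v, dims) {
  if (length(v) != prod(dims)) stop("vector length must equal product of factor sizes")
  array(as.numeric(v), dim = dims)
}

#' Kronecker-product matrix-vector product
#'
#' Computes `(K_last %x% ... %x% K_1) %*% v` without forming the product
#' matrix, where `v` is the column-major vectorization of an array whose
#' k-th dimension matches the k-th factor.
#'
#' @param factors list of matrices, axis order (time, electrode, stimulus).
#' @param v numeric vector of length `prod(sizes)`.
#' @return numeric vector.
#' @export
kron_matvec <- function(factors, v) {
  dims <- vapply(factors, ncol, integer(1))
  X <- .as_factor_array(v, dims)
  for (k in seq_along(factors)) X <- .mode_prod(X, factors[[k]], k)
  as.vector(X)
}

#' Shifted factored operator
#'
#' Represents `rho * (K_s %x% ... %x% K_t) + c * I` where the diagonal shift
#' `c` collects the kernel jitter `phi2` plus any observation-noise term
#' (e.g. `sigma2 / n_j`).
#'
#' @param kernel a [kron_kernel()].
#' @param extra_shift additional diagonal variance added to `kernel$phi2`
#'   (uV^2, >= 0).
#' @return object of class `kron_op`.
#' @export
kron_op <- function(kernel, extra_shift = 0) {
  stopifnot(inherits(kernel, "kron_kernel"))
  if (!is.finite(extra_shift) || extra_shift < 0)
    stop("'extra_shift' must be nonnegative")
  structure(list(kernel = kernel, shift = kernel$phi2 + extra_shift),
            class = "kron_op")
}

#' Solve a shifted Kronecker system
#'
#' Returns `(rho * kron + c I)^{-1} v` via per-factor eigendecompositions:
#' the operator is diagonal in the joint eigenbasis with entries
#' `rho * kappa_m + c`.
#'
#' @param op a [kron_op()].
#' @param v right-hand side vector (length = product of factor sizes) or an
#'   array of matching dimensions.
#' @return solution with the same shape as `v`.
#' @export
kron_solve_shifted <- function(op, v) {
  stopifnot(inherits(op, "kron_op"))
  k <- op$kernel
  shp <- dim(v)
  X <- .as_factor_array(v, k$dims)
  kap <- k$rho * .kappa(k$eig) + op$shift
  if (any(kap <= 0)) stop("operator is singular: nonpositive eigenvalue")
  W <- .to_eigbasis(X, k$eig)
  X <- .from_eigbasis(W / kap, k$eig)
  if (is.null(shp)) as.vector(X) else array(as.vector(X), dim = shp)
}

#' Log-determinant of a shifted Kronecker operator
#'
#' `sum(log(rho * kappa_m + c))` over the products `kappa_m` of factor
#' eigenvalues.
#'
#' @param op a [kron_op()].
#' @return scalar log-determinant.
#' @export
kron_logdet_shifted <- function(op) {
  stopifnot(inherits(op, "kron_op"))
  k <- op$kernel
  ev <- k$rho * .kappa(k$eig) + op$shift
  if (any(ev <= 0)) stop("nonpositive eigenvalue: log-determinant undefined")
  sum(log(ev))
}

#' Sample from a factored Gaussian
#'
#' Draws a zero-mean Gaussian array with covariance `rho * kron + c I` by
#' filling an array with independent standard normals and applying the
#' symmetric square root of each factor along its own dimension, then adding
#' independent `sqrt(c)` noise.
#'
#' @param op a [kron_op()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the draw is reproducible.
#' @return array with one dimension per factor.
#' @export
kron_sample <- function(op, seed = NULL) {
  stopifnot(inherits(op, "kron_op"))
  if (!is.null(seed)) set.seed(seed)
  k <- op$kernel
  z <- array(stats::rnorm(prod(k$dims)), dim = k$dims)
  if (k$rho > 0) {
    for (m in seq_along(k$factors)) {
      e <- k$eig[[m]]
      L <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
      z <- .mode_prod(z, L, m)
    }
    z <- sqrt(k$rho) * z
  } else {
    z <- array(0, dim = k$dims)
  }
  if (op$shift > 0)
    z <- z + sqrt(op$shift) * array(stats::rnorm(prod(k$dims)), dim = k$dims)
  z
}

#' Gaussian-process conditional mean across stimulus slices
#'
#' Conditions the factored GP on values observed at a subset of stimulus
#' indices and predicts the mean at target indices:
#' `K_(target,obs) (K_(obs,obs) + noise I)^{-1} obs_values`, where only the
#' last (stimulus) factor is sliced and the remaining factors apply in full.
#'
#' @param kernel a [kron_kernel()]; the last factor is the stimulus axis.
#' @param obs_idx integer indices (into the stimulus axis) of observed
#'   slices; must be nonempty.
#' @param target_idx integer indices of target slices.
#' @param obs array of observed values whose last dimension has length
#'   `length(obs_idx)` (other dimensions match the kernel factors).
#' @param noise observation-noise variance added to the diagonal (uV^2).
#' @return array of predicted values with last dimension
#'   `length(target_idx)`.
#' @export
kron_conditional_mean <- function(kernel, obs_idx, target_idx, obs,
                                  noise = 0) {
  stopifnot(inherits(kernel, "kron_kernel"))
  if (length(obs_idx) == 0L) stop("observed index set must be nonempty")
  nf <- length(kernel$factors)
  Ks <- kernel$factors[[nf]]
  dims_obs <- c(kernel$dims[-nf], length(obs_idx))
  X <- .as_factor_array(obs, dims_obs)
  eig_obs <- c(kernel$eig[-nf],
               list(.eig_psd(Ks[obs_idx, obs_idx, drop = FALSE])))
  kap <- kernel$rho * .kappa(eig_obs) + noise
  W <- .to_eigbasis(X, eig_obs)
  # pseudo-inverse in the eigenbasis: zero modes contribute nothing
  ok <- kap > 1e-12 * max(kap, 1)
  W <- ifelse(ok, W / kap, 0)
  X <- .from_eigbasis(W, eig_obs)
  # cross-covariance: full factors on the kept axes, sliced stimulus factor
  for (k in seq_len(nf - 1L)) X <- .mode_prod(X, kernel$factors[[k]], k)
  X <- .mode_prod(X, Ks[target_idx, obs_idx, drop = FALSE], nf)
  kernel$rho * X
}

#' Eigenbasis shrinkage filter
#'
#' Applies `rho K (rho K + c I)^{-1}` to an array: each joint eigencomponent
#' is multiplied by `kappa / (kappa + c)`, the Wiener shrinkage behind the
#' artifact filtering step. With `c = 0` the input is returned unchanged.
#'
#' @param x array matching the kernel factor dimensions.
#' @param kernel a [kron_kernel()] (its `phi2` is ignored here; pass the
#'   full shift via `c`).
#' @param c diagonal noise variance `sigma2 / n_j + phi2` (uV^2, >= 0).
#' @return filtered array, same shape as `x`.
#' @export
kron_shrink <- function(x, kernel, c = 0) {
  stopifnot(inherits(kernel, "kron_kernel"))
  if (c < 0) stop("'c' must be nonnegative")
  if (c == 0) return(x)
  shp <- dim(x)
  X <- .as_factor_array(x, kernel$dims)
  kap <- kernel$rho * .kappa(kernel$eig)
  W <- .to_eigbasis(X, kernel$eig)
  X <- .from_eigbasis(W * kap / (kap + c), kernel$eig)
  if (is.null(shp)) as.vector(X) else array(as.vector(X), dim = shp)
}
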