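#' Non-stationary axis kernels and factored artifact covariances
#'
#' The stimulation artifact is modelled as a zero-mean Gaussian process whose
#' covariance factorizes over the time, electrode (space) and stimulus
#' amplitude axes. Each axis kernel is a stationary Matern(3/2) correlation
#' modulated by an unnormalized gamma-density variance envelope, which places
#' "bumps" of variability where the artifact is strong (e.g. around 0.5 ms
#' after pulse onset, or near the stimulating electrode).
#'
#' Conventions used throughout the package:
#' * artifact arrays are indexed `[time, electrode, stimulus]` and vectorized
#'   column-major (time fastest);
#' * kernel factors are stored in the order (time, electrode, stimulus), so
#'   the dense covariance on the vectorized array is
#'   `rho * (K_s %x% K_e %x% K_t) + phi2 * I`;
#' * covariate units are milliseconds (time), micrometres (space) and
#'   microamperes (stimulus amplitude); inverse length-scales `lam` are per
#'   unit of that covariate.
#'
#' @name kernels
NULL

#' Matern(3/2) correlation
#'
#' Stationary correlation `(1 + sqrt(3)*delta*lam) * exp(-sqrt(3)*delta*lam)`,
#' the continuous analogue of an AR(2) process. Used as the smoothness
#' primitive on every axis.
#'
#' @param delta nonnegative distance(s) in covariate units.
#' @param lam inverse length-scale (> 0), per covariate unit.
#' @return correlation value(s) in (0, 1]; 1 exactly at `delta = 0`.
#' @examples
#' matern32(0, 2)      # 1
#' matern32(1, 1)      # (1 + sqrt(3)) * exp(-sqrt(3))
#' @export
matern32 <- function(delta, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("'lam' must be a single positive number")
  if (any(delta < 0)) stop("'delta' must be nonnegative")
  u <- sqrt(3) * delta * lam
  (1 + u) * exp(-u)
}

#' Gamma variance envelope
#'
#' Unnormalized gamma density `d(x) = x^alpha * exp(-x*beta)` used to modulate
#' the amplitude of a stationary process, creating non-stationary variance
#' bumps. The convention `0^0 = 1` makes `alpha = beta = 0` an exactly flat
#' envelope (stationary kernel).
#'
#' @param x nonnegative covariate value(s).
#' @param alpha envelope shape (>= 0, dimensionless).
#' @param beta envelope rate (>= 0, per covariate unit).
#' @return nonnegative envelope value(s); the maximum over `x` sits at
#'   `alpha/beta` when both are positive.
#' @export
gamma_envelope <- function(x, alpha = 0, beta = 0) {
  if (any(x < 0)) stop("'x' must be nonnegative")
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be nonnegative")
  if (alpha == 0) return(exp(-x * beta))   # 0^0 := 1
  x^alpha * exp(-x * beta)
}

#' Axis kernel parameters
#'
#' @param lam inverse length-scale (> 0).
#' @param alpha,beta gamma-envelope shape and rate (>= 0); both zero gives a
#'   stationary kernel.
#' @return an object of class `axis_params`.
#' @export
axis_params <- function(lam, alpha = 0, beta = 0) {
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be positive")
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be nonnegative")
  structure(list(lam = lam, alpha = alpha, beta = beta),
            class = "axis_params")
}

#' Axis covariate grid
#'
#' Pairs the covariate entering the stationary Matern distance `delta` with
#' the covariate entering the variance envelope. For the time axis both are
#' time since stimulus onset (ms); for the electrode axis `smooth` holds the
#' electrode coordinates (a matrix of x,y positions in um, pairwise Euclidean
#' distances giving `delta`) while `envelope` holds the distance from each
#' recording electrode to the stimulating electrode; for the stimulus axis
#' `smooth` is the amplitude in uA and the envelope is flat.
#'
#' @param smooth numeric vector, or a matrix with one row per grid point
#'   whose rows are coordinates (pairwise Euclidean distances are used).
#' @param envelope nonnegative numeric vector, same number of points as
#'   `smooth`; defaults to `smooth` when that is a vector.
#' @return an object of class `axis_grid`.
#' @export
axis_grid <- function(smooth, envelope = NULL) {
  n <- if (is.matrix(smooth)) nrow(smooth) else length(smooth)
  if (n < 1L) stop("axis grid must be nonempty")
  if (is.null(envelope)) {
    if (is.matrix(smooth))
      stop("'envelope' is required when 'smooth' is a coordinate matrix")
    envelope <- smooth
  }
  if (length(envelope) != n)
    stop("'smooth' and 'envelope' must have the same number of points")
  if (any(envelope < 0)) stop("envelope covariate must be nonnegative")
  # pairwise distances are cached here so repeated kernel builds on the
  # same grid (hyperparameter optimization) do not recompute them
  structure(list(smooth = smooth, envelope = envelope, n = n,
                 distmat = .pairwise_dist(smooth)),
            class = "axis_grid")
}

.pairwise_dist <- function(smooth) {
  if (is.matrix(smooth)) {
    as.matrix(stats::dist(smooth))
  } else {
    abs(outer(smooth, smooth, "-"))
  }
}

#' Build one axis kernel matrix
#'
#' Entry (i, k) is `d(x_i) * matern32(|delta_i - delta_k|, lam) * d(x_k)`:
#' a stationary Matern(3/2) correlation sandwiched by the gamma envelope
#' evaluated at the envelope covariate.
#'
#' @param grid an [axis_grid()].
#' @param params an [axis_params()].
#' @return symmetric positive semidefinite matrix of size `grid$n`.
#' @export
build_axis_kernel <- function(grid, params) {
  stopifnot(inherits(grid, "axis_grid"), inherits(params, "axis_params"))
  d <- gamma_envelope(grid$envelope, params$alpha, params$beta)
  dm <- if (is.null(grid$distmat)) .pairwise_dist(grid$smooth) else
    grid$distmat
  K <- matern32(dm, params$lam)
  K <- K * tcrossprod(d)
  (K + t(K)) / 2
}

# Symmetric eigendecomposition with negative eigenvalues clipped at zero.
# Errors if any eigenvalue is below -tol * max(eigenvalue) (non-PSD factor).
.eig_psd <- function(K, tol = 1e-8, what = "kernel factor") {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  top <- max(e$values, 0)
  if (any(e$values < -tol * max(top, 1)))
    stop(sprintf("%s is not positive semidefinite", what))
  e$values <- pmax(e$values, 0)
  e
}

#' Factored (Kronecker) artifact covariance
#'
#' Holds an ordered list of symmetric PSD axis kernel matrices, an overall
#' scale `rho` and a jitter `phi2`, representing the covariance
#' `rho * (K_s %x% ... %x% K_t) + phi2 * I` without materializing it. Factor
#' eigendecompositions are computed once at construction and cached; the
#' eigenvalues of the Kronecker product are the products of factor
#' eigenvalues.
#'
#' @param factors list of symmetric PSD matrices in axis order
#'   (time, electrode, stimulus) or (time, stimulus).
#' @param rho overall scale (>= 0, dimensionless).
#' @param phi2 additive jitter variance (uV^2, >= 0).
#' @return an object of class `kron_kernel` with cached `eig` per factor.
#' @export
kron_kernel <- function(factors, rho, phi2 = 0) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  if (!is.finite(rho) || rho < 0) stop("'rho' must be nonnegative")
  if (!is.finite(phi2) || phi2 < 0) stop("'phi2' must be nonnegative")
  factors <- lapply(factors, function(K) {
    K <- as.matrix(K)
    if (nrow(K) != ncol(K)) stop("kernel factors must be square")
    if (max(abs(K - t(K))) > 1e-6 * max(abs(K), 1))
      stop("kernel factor is not symmetric")
    (K + t(K)) / 2
  })
  eig <- lapply(factors, .eig_psd)
  structure(list(factors = factors, rho = rho, phi2 = phi2, eig = eig,
                 dims = vapply(factors, nrow, integer(1))),
            class = "kron_kernel")
}

#' @export
dim.kron_kernel <- function(x) x$dims

#' @export
print.kron_kernel <- function(x, ...) {
  cat(sprintf("<kron_kernel> factors %s, rho = %.4g, phi2 = %.4g\n",
              paste(x$dims, collapse = " x "), x$rho, x$phi2))
  invisible(x)
}

#' Assemble the non-stimulating-electrode covariance
#'
#' Three-factor Kronecker covariance over (time, electrode, stimulus). The
#' stimulus axis models smoothness only (its envelope must be flat,
#' `alpha = beta = 0`), since artifact growth with amplitude is carried by
#' the data rather than a prescribed variance profile.
#'
#' @param t_grid,e_grid,s_grid [axis_grid()]s for time (ms), electrodes (um)
#'   and stimulus amplitude (uA).
#' @param params named list with elements `time`, `electrode`, `stimulus`,
#'   each an [axis_params()]; `params$stimulus` must have
#'   `alpha = beta = 0`.
#' @param rho overall scale.
#' @param phi2 jitter variance (uV^2).
#' @return a three-factor [kron_kernel()].
#' @export
assemble_nonstim_kernel <- function(t_grid, e_grid, s_grid, params,
                                    rho, phi2) {
  stopifnot(all(c("time", "electrode", "stimulus") %in% names(params)))
  ps <- params$stimulus
  if (ps$alpha != 0 || ps$beta != 0)
    stop("stimulus axis must be stationary (alpha = beta = 0)")
  kron_kernel(list(time = build_axis_kernel(t_grid, params$time),
                   electrode = build_axis_kernel(e_grid, params$electrode),
                   stimulus = build_axis_kernel(s_grid, ps)),
              rho = rho, phi2 = phi2)
}

#' Assemble the stimulating-electrode covariance
#'
#' The stimulating electrode's artifact is a piecewise-smooth function of
#' amplitude: hardware gain changes at known breakpoint amplitudes make the
#' artifact discontinuous there, so no covariance is shared across
#' breakpoints. The kernel is block diagonal in the stimulus dimension: one
#' independent two-factor (time, stimulus) Kronecker block per range between
#' consecutive breakpoints, each with its own scale and axis parameters.
#'
#' An amplitude equal to a breakpoint belongs to the upper range (the gain
#' change applies from that amplitude on).
#'
#' @param t_grid time [axis_grid()] (ms).
#' @param amplitudes increasing stimulus amplitudes (uA).
#' @param breakpoints breakpoint amplitudes strictly inside
#'   `range(amplitudes)`; may be empty.
#' @param params_per_range list with one element per range, each a list with
#'   elements `time` ([axis_params()]), `stimulus` ([axis_params()], flat
#'   envelope) and `rho`.
#' @param phi2p jitter variance phi'^2 (uV^2).
#' @return object of class `stim_kernel`: per-range [kron_kernel()] blocks
#'   plus the amplitude-index partition.
#' @export
assemble_stim_kernel <- function(t_grid, amplitudes, breakpoints,
                                 params_per_range, phi2p) {
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("'amplitudes' must be strictly increasing")
  breakpoints <- sort(breakpoints)
  if (length(breakpoints) &&
      (min(breakpoints) <= min(amplitudes) ||
       max(breakpoints) > max(amplitudes)))
    stop("breakpoints must lie strictly inside the amplitude range")
  range_id <- findInterval(amplitudes, breakpoints) + 1L
  R <- length(breakpoints) + 1L
  ranges <- lapply(seq_len(R), function(r) which(range_id == r))
  if (any(vapply(ranges, length, integer(1)) == 0L))
    stop("every breakpoint range must contain at least one amplitude")
  if (length(params_per_range) != R)
    stop(sprintf("need %d parameter sets, got %d", R,
                 length(params_per_range)))
  blocks <- lapply(seq_len(R), function(r) {
    p <- params_per_range[[r]]
    # amplitude doubles as the envelope covariate, so per-range stimulus
    # kernels may carry a variance envelope (unlike the non-stimulating
    # stimulus axis, which is restricted to pure smoothness)
    s_grid <- axis_grid(amplitudes[ranges[[r]]],
                        envelope = amplitudes[ranges[[r]]])
    Ks <- build_axis_kernel(s_grid, p$stimulus)
    if (!is.null(p$scale_profile)) {
      if (length(p$scale_profile) != nrow(Ks))
        stop("scale_profile length must match the range size")
      Ks <- Ks * tcrossprod(p$scale_profile)
    }
    kron_kernel(list(time = build_axis_kernel(t_grid, p$time),
                     stimulus = Ks),
                rho = p$rho, phi2 = phi2p)
  })
  structure(list(blocks = blocks, ranges = ranges, amplitudes = amplitudes,
                 breakpoints = breakpoints, phi2 = phi2p),
            class = "stim_kernel")
}

#' @export
print.stim_kernel <- function(x, ...) {
  cat(sprintf("<stim_kernel> %d range(s), %d amplitudes, phi2' = %.4g\n",
              length(x$blocks), length(x$amplitudes), x$phi2))
  invisible(x)
}

#' Dense reconstruction of a factored covariance
#'
#' Materializes the full covariance matrix. Intended for small problems and
#' for checking the factored algebra against dense linear algebra; guarded by
#' a size cap.
#'
#' @param kernel a [kron_kernel()] or `stim_kernel`.
#' @param max_dim refuse to materialize above this total dimension.
#' @return dense covariance matrix.
#' @export
dense_covariance <- function(kernel, max_dim = 4096) {
  if (inherits(kernel, "stim_kernel")) {
    Tn <- nrow(kernel$blocks[[1]]$factors[[1]])
    J <- length(kernel$amplitudes)
    n <- Tn * J
    if (n > max_dim) stop("total dimension exceeds 'max_dim'")
    K <- matrix(0, n, n)
    for (r in seq_along(kernel$blocks)) {
      b <- kernel$blocks[[r]]
      idx <- as.vector(outer(seq_len(Tn), (kernel$ranges[[r]] - 1L) * Tn,
                             "+"))
      K[idx, idx] <- b$rho * (b$factors[[2]] %x% b$factors[[1]])
    }
    return(K + diag(kernel$phi2, n))
  }
  n <- prod(kernel$dims)
  if (n > max_dim) stop("total dimension exceeds 'max_dim'")
  K <- Reduce(`%x%`, rev(kernel$factors))
  kernel$rho * K + diag(kernel$phi2, n)
}
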