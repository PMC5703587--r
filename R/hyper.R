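#' Proxy artifacts, noise estimation and hyperparameter fitting
#'
#' The artifact GP hyperparameters cannot be estimated by exact marginal
#' likelihood (that would require summing over all spike configurations), so
#' a cheap proxy artifact is built first -- trial means, pooled over
#' stimulating electrodes after translating each onto the array center for
#' the non-stimulating kernel -- and the Gaussian likelihood of that proxy is
#' optimized instead. The jitter `phi2` is estimated directly from the
#' proxy's background (it is held fixed, never optimized jointly), and the
#' observation noise `sigma2` from across-trial variability at the lowest
#' amplitude far from the stimulation site.
#'
#' @name hyper
NULL

#' Subtract the switching artifact
#'
#' The baseline ("switching") artifact present even at the smallest
#' amplitude is estimated as the mean over trials at the lowest amplitude,
#' per (time, electrode), and subtracted from every trace. Adding it back
#' reproduces the raw traces exactly.
#'
#' @param raw a [trace_series()].
#' @return object of class `centered_traces`: the centered series plus the
#'   `(T, E)` switching-mean matrix (uV).
#' @export
subtract_switching_mean <- function(raw) {
  stopifnot(inherits(raw, "trace_series"))
  if (dim(raw$Y[[1]])[3] < 1L)
    stop("no trials at the lowest amplitude")
  mu <- apply(raw$Y[[1]], c(1, 2), mean)
  centered <- raw
  centered$Y <- lapply(raw$Y, function(y) y - as.vector(mu))
  structure(list(traces = centered, switching_mean = mu),
            class = "centered_traces")
}

#' Restore raw traces from centered ones
#' @param centered a `centered_traces` object.
#' @return the original [trace_series()].
#' @export
add_switching_mean <- function(centered) {
  stopifnot(inherits(centered, "centered_traces"))
  raw <- centered$traces
  raw$Y <- lapply(raw$Y, function(y) y + as.vector(centered$switching_mean))
  raw
}

.proxy_artifact <- function(values, kind, time_ms, amplitudes,
                            coords = NULL, distances = NULL,
                            kept_electrodes = NULL, provenance = list()) {
  structure(list(values = values, kind = kind, time_ms = time_ms,
                 amplitudes = amplitudes, coords = coords,
                 distances = distances, kept_electrodes = kept_electrodes,
                 provenance = provenance),
            class = "proxy_artifact")
}

#' @export
print.proxy_artifact <- function(x, ...) {
  cat(sprintf("<proxy_artifact> %s, values %s\n", x$kind,
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

#' Non-stimulating-electrode proxy artifact
#'
#' Pools trial-mean traces from one or more stimulating-electrode datasets:
#' each dataset's electrodes are translated on the grid so its stimulating
#' electrode sits at the array center, and the translated means are averaged
#' per (electrode, time, amplitude). Averaging across stimulating electrodes
#' cancels electrode-specific neural activity, leaving a cheap but stable
#' artifact estimate. Only electrodes closest to the center are retained
#' (distant electrodes contribute mostly noise); the center electrode itself
#' (the stimulating electrode after translation) is excluded.
#'
#' @param datasets list of `centered_traces`, one per stimulating electrode;
#'   each must carry a layout.
#' @param layout the common [make_layout()].
#' @param keep_frac fraction of (non-center) electrodes retained, closest to
#'   the center first; default 0.25.
#' @return a `proxy_artifact` with values `(T, E_kept, J)`, the kept
#'   electrodes' coordinates and their distances to the center.
#' @export
build_proxy_nonstim <- function(datasets, layout, keep_frac = 0.25) {
  if (inherits(datasets, "centered_traces")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  ts1 <- datasets[[1]]$traces
  Tn <- dim(ts1$Y[[1]])[1]
  E <- dim(ts1$Y[[1]])[2]
  J <- length(ts1$Y)
  acc <- array(0, dim = c(Tn, E, J))
  cnt <- integer(E)
  dropped <- integer(0)
  for (d in datasets) {
    ts <- d$traces
    stopifnot(length(ts$Y) == J, dim(ts$Y[[1]])[1] == Tn)
    trial_mean <- vapply(ts$Y, function(y) apply(y, c(1, 2), mean),
                         matrix(0, Tn, E))           # (T, E, J)
    src <- translate_electrodes(layout, from = layout$center,
                                to = ts$stim_electrode)
    ok <- which(!is.na(src))
    dropped <- union(dropped, which(is.na(src)))
    acc[, ok, ] <- acc[, ok, ] + trial_mean[, src[ok], , drop = FALSE]
    cnt[ok] <- cnt[ok] + 1L
  }
  keep <- which(cnt > 0L & seq_len(E) != layout$center)
  vals <- sweep(acc[, keep, , drop = FALSE], 2, cnt[keep], "/")
  dist_c <- sqrt(colSums((t(layout$positions) -
                            layout$positions[layout$center, ])^2))[keep]
  n_keep <- max(1L, ceiling(keep_frac * length(keep)))
  sel <- order(dist_c)[seq_len(n_keep)]
  .proxy_artifact(vals[, sel, , drop = FALSE], kind = "nonstim",
                  time_ms = time_ms(ts1), amplitudes = ts1$amplitudes,
                  coords = layout$positions[keep[sel], , drop = FALSE],
                  distances = dist_c[sel],
                  kept_electrodes = keep[sel],
                  provenance = list(
                    stim_electrodes = vapply(datasets, function(d)
                      d$traces$stim_electrode, integer(1)),
                    excluded = dropped, keep_frac = keep_frac))
}

#' Stimulating-electrode proxy artifact
#'
#' The stimulating electrode's artifact dwarfs any spike contribution there,
#' so the per-amplitude mean (or, for robustness, median) across trials is a
#' serviceable proxy.
#'
#' @param centered a `centered_traces` object.
#' @param stat `"mean"` (default) or `"median"`.
#' @return a `proxy_artifact` with values `(T, J)`.
#' @export
build_proxy_stim <- function(centered, stat = c("mean", "median")) {
  stopifnot(inherits(centered, "centered_traces"))
  stat <- match.arg(stat)
  ts <- centered$traces
  f <- if (stat == "mean") mean else stats::median
  vals <- vapply(ts$Y, function(y)
    apply(y[, ts$stim_electrode, , drop = FALSE], 1, f),
    numeric(dim(ts$Y[[1]])[1]))                       # (T, J)
  .proxy_artifact(vals, kind = "stim", time_ms = time_ms(ts),
                  amplitudes = ts$amplitudes,
                  provenance = list(stat = stat))
}

#' Estimate the artifact jitter phi^2
#'
#' Sample variance of the proxy over a background window where the artifact
#' is essentially absent: the last fraction of the time samples, at the
#' lowest amplitude and (for the pooled non-stimulating proxy) on the
#' electrodes in the farthest distance quartile. When the proxy is built
#' from a single stimulating-electrode dataset, the switching-mean
#' subtraction makes the lowest-amplitude proxy identically zero; the
#' background then falls back to the lowest amplitude whose window carries
#' nonzero variance.
#'
#' @param proxy a `proxy_artifact`.
#' @param time_frac trailing fraction of time samples used (default 0.25).
#' @param dist_frac fraction of farthest electrodes used (default 0.25;
#'   ignored for stimulating-electrode proxies).
#' @return background variance (uV^2).
#' @export
estimate_phi2 <- function(proxy, time_frac = 0.25, dist_frac = 0.25) {
  stopifnot(inherits(proxy, "proxy_artifact"))
  Tn <- length(proxy$time_ms)
  nt <- ceiling(time_frac * Tn)
  if (nt < 1L) stop("empty background time window")
  t_idx <- seq.int(Tn - nt + 1L, Tn)
  bg_at <- function(j) {
    if (proxy$kind == "nonstim") {
      thr <- stats::quantile(proxy$distances, 1 - dist_frac)
      e_idx <- which(proxy$distances >= thr)
      if (!length(e_idx)) stop("empty background electrode set")
      as.vector(proxy$values[t_idx, e_idx, j])
    } else {
      as.vector(proxy$values[t_idx, j])
    }
  }
  tiny <- 1e-10 * max(stats::var(as.vector(proxy$values)), 1e-12)
  for (j in seq_along(proxy$amplitudes)) {
    bg <- bg_at(j)
    if (length(bg) < 2L) stop("background window too small")
    v <- stats::var(bg)
    if (v > tiny) return(v)
  }
  0
}

#' Estimate the observation-noise variance sigma^2
#'
#' Pooled across-trial sample variance of low-amplitude traces on electrodes
#' far from the stimulation site, where neither artifact nor evoked spikes
#' contribute: any structure common to all trials (the artifact) cancels in
#' the across-trial variance.
#'
#' @param centered a `centered_traces` object.
#' @param dist_frac fraction of farthest electrodes used (default 0.25).
#' @return observation-noise variance (uV^2).
#' @export
estimate_sigma2 <- function(centered, dist_frac = 0.25) {
  stopifnot(inherits(centered, "centered_traces"))
  ts <- centered$traces
  Y1 <- ts$Y[[1]]
  if (dim(Y1)[3] < 2L)
    stop("need at least two trials at the lowest amplitude")
  d <- stim_distances(ts)
  thr <- stats::quantile(d, 1 - dist_frac)
  e_idx <- which(d >= thr)
  v <- apply(Y1[, e_idx, , drop = FALSE], c(1, 2), stats::var)
  mean(v)
}

#' Negative log marginal likelihood of a proxy artifact
#'
#' `0.5 * v' K^{-1} v + 0.5 * log|K|` for the zero-mean Gaussian with
#' covariance `rho * kron + phi2 * I`, computed entirely with the factored
#' algebra. The additive `0.5 * n * log(2*pi)` constant is omitted.
#'
#' @param values proxy values (vector or array matching the kernel).
#' @param kernel a [kron_kernel()] with positive `phi2`.
#' @return scalar negative log likelihood (up to the constant).
#' @export
neg_log_marglik <- function(values, kernel) {
  op <- kron_op(kernel)
  v <- as.vector(values)
  0.5 * sum(v * kron_solve_shifted(op, v)) + 0.5 * kron_logdet_shifted(op)
}

# ---- hyperparameter optimization ------------------------------------------

.hp_bounds <- function() {
  list(log_rho = c(-20, 40), log_lam = log(c(1e-3, 1e3)),
       alpha = c(0, 20), log_beta = log(c(1e-4, 1e2)))
}

.clip <- function(x, b) pmin(pmax(x, b[1]), b[2])

# Crude envelope regression: log sd(x) ~ alpha * log(x) - beta * x.
.envelope_init <- function(x, s) {
  ok <- x > 0 & s > 0
  if (sum(ok) < 3L) return(c(alpha = 0, beta = 1e-3))
  A <- cbind(1, log(x[ok]), -x[ok])
  cf <- tryCatch(qr.solve(A, log(s[ok])), error = function(e) c(0, 0, 1e-3))
  b <- .hp_bounds()
  c(alpha = .clip(cf[2], b$alpha),
    beta = exp(.clip(log(max(cf[3], 1e-4)), b$log_beta)))
}

.nonstim_grids <- function(proxy) {
  list(time = axis_grid(proxy$time_ms),
       electrode = axis_grid(proxy$coords, envelope = proxy$distances),
       stimulus = axis_grid(proxy$amplitudes,
                            envelope = rep(0, length(proxy$amplitudes))))
}

.nonstim_kernel_from_par <- function(p, grids, phi2) {
  params <- list(time = axis_params(exp(p[2]), p[3], exp(p[4])),
                 electrode = axis_params(exp(p[5]), p[6], exp(p[7])),
                 stimulus = axis_params(exp(p[8])))
  assemble_nonstim_kernel(grids$time, grids$electrode, grids$stimulus,
                          params, rho = exp(p[1]), phi2 = phi2)
}

.stim_kernel_from_par <- function(p, grids, phi2) {
  kron_kernel(list(
    time = build_axis_kernel(grids$time,
                             axis_params(exp(p[2]), p[3], exp(p[4]))),
    stimulus = build_axis_kernel(grids$stimulus, axis_params(exp(p[5])))),
    rho = exp(p[1]), phi2 = phi2)
}

.hp_nll_factory <- function(values, grids, phi2, builder) {
  function(p) {
    k <- tryCatch(builder(p, grids, phi2), error = function(e) NULL)
    if (is.null(k)) return(1e10)
    # degeneracy guard: envelopes must not underflow the kernel variance
    dvar <- lapply(k$factors, diag)
    if (any(vapply(dvar, function(d)
      min(d) < 1e-12 * max(d, 1e-300), logical(1))))
      return(1e10)
    out <- tryCatch(neg_log_marglik(values, k), error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
}

.hp_optimize <- function(nll, starts, lower, upper, maxit) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) list(par = p0, value = nll(p0), convergence = 52L))
    if (is.null(best) || fit$value < best$value) best <- fit
    # the unoptimized start itself also competes (guards optimizer failures)
    v0 <- nll(p0)
    if (v0 < best$value) best <- list(par = p0, value = v0, convergence = 0L)
  }
  # only the winning start's convergence matters
  best$warned <- best$convergence != 0L
  best
}

.hp_init_nonstim <- function(proxy, phi2) {
  b <- .hp_bounds()
  v <- proxy$values
  sd_t <- apply(v, 1, stats::sd)
  sd_e <- apply(v, 2, stats::sd)
  env_t <- .envelope_init(proxy$time_ms, sd_t)
  env_e <- .envelope_init(proxy$distances, sd_e)
  lam_t <- 4 / diff(range(proxy$time_ms))
  lam_e <- 4 / max(stats::dist(proxy$coords))
  lam_s <- 4 / diff(range(proxy$amplitudes))
  dt <- gamma_envelope(proxy$time_ms, env_t["alpha"], env_t["beta"])
  de <- gamma_envelope(proxy$distances, env_e["alpha"], env_e["beta"])
  env2 <- mean(outer(dt^2, de^2))
  rho0 <- max(mean(v^2) - phi2, 1e-6) / max(env2, 1e-12)
  p0 <- c(log(rho0),
          .clip(log(lam_t), b$log_lam), env_t["alpha"],
          .clip(log(env_t["beta"]), b$log_beta),
          .clip(log(lam_e), b$log_lam), env_e["alpha"],
          .clip(log(env_e["beta"]), b$log_beta),
          .clip(log(lam_s), b$log_lam))
  unname(p0)
}

.hp_init_stim <- function(values, time_ms, amplitudes, phi2) {
  b <- .hp_bounds()
  sd_t <- apply(values, 1, stats::sd)
  env_t <- .envelope_init(time_ms, sd_t)
  lam_t <- 4 / diff(range(time_ms))
  lam_s <- if (length(amplitudes) > 1L) 4 / diff(range(amplitudes)) else 1
  dt <- gamma_envelope(time_ms, env_t["alpha"], env_t["beta"])
  rho0 <- max(mean(values^2) - phi2, 1e-6) / max(mean(dt^2), 1e-12)
  unname(c(log(rho0), .clip(log(lam_t), b$log_lam), env_t["alpha"],
           .clip(log(env_t["beta"]), b$log_beta),
           .clip(log(lam_s), b$log_lam)))
}

.par_to_nonstim <- function(p, phi2, nll) {
  structure(list(kind = "nonstim",
                 params = list(time = axis_params(exp(p[2]), p[3], exp(p[4])),
                               electrode = axis_params(exp(p[5]), p[6],
                                                       exp(p[7])),
                               stimulus = axis_params(exp(p[8]))),
                 rho = exp(p[1]), phi2 = phi2, nll = nll, par = p),
            class = "artifact_hyperparams")
}

.nonstim_to_par <- function(hp) {
  with(hp, c(log(rho), log(params$time$lam), params$time$alpha,
             log(max(params$time$beta, 1e-4)),
             log(params$electrode$lam), params$electrode$alpha,
             log(max(params$electrode$beta, 1e-4)),
             log(params$stimulus$lam)))
}

#' Fit artifact-kernel hyperparameters to a proxy
#'
#' Minimizes the Gaussian negative log likelihood of the proxy over the
#' kernel hyperparameters, with `phi2` held fixed (it is estimated
#' beforehand from the proxy background and never optimized jointly, which
#' avoids numerical instabilities). `rho`, the length-scales and the
#' envelope rates are optimized on the log scale; envelope shapes `alpha`
#' are box-constrained at `[0, 20]`. A seeded multistart (data-driven
#' initialization plus jittered restarts) guards against the multimodal
#' likelihood; the reported fit is the best over all starts and never worse
#' than the supplied initialization.
#'
#' @param proxy a `proxy_artifact` from [build_proxy_nonstim()] (the
#'   three-axis kernel) or one range of a stimulating-electrode proxy.
#' @param phi2 fixed jitter variance (uV^2, > 0), from [estimate_phi2()].
#' @param init optional `artifact_hyperparams` used as an additional start.
#' @param n_starts number of multistart initializations (default 5).
#' @param seed integer seed for the multistart jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return an `artifact_hyperparams` object: fitted [axis_params()] per
#'   axis, `rho`, the fixed `phi2`, the achieved negative log likelihood
#'   and an optimizer report.
#' @export
fit_hyperparameters <- function(proxy, phi2, init = NULL, n_starts = 5,
                                seed = 1, maxit = 100) {
  stopifnot(inherits(proxy, "proxy_artifact"), phi2 > 0)
  if (proxy$kind != "nonstim")
    stop("use fit_stim_hyperparameters() for stimulating-electrode proxies")
  grids <- .nonstim_grids(proxy)
  nll <- .hp_nll_factory(proxy$values, grids, phi2, .nonstim_kernel_from_par)
  b <- .hp_bounds()
  lower <- c(b$log_rho[1], b$log_lam[1], b$alpha[1], b$log_beta[1],
             b$log_lam[1], b$alpha[1], b$log_beta[1], b$log_lam[1])
  upper <- c(b$log_rho[2], b$log_lam[2], b$alpha[2], b$log_beta[2],
             b$log_lam[2], b$alpha[2], b$log_beta[2], b$log_lam[2])
  p0 <- .hp_init_nonstim(proxy, phi2)
  set.seed(seed)
  starts <- c(list(p0),
              lapply(seq_len(max(n_starts - 1L, 0L)), function(s)
                p0 + stats::rnorm(length(p0), sd = 0.6)))
  if (!is.null(init)) starts <- c(list(.nonstim_to_par(init)), starts)
  best <- .hp_optimize(nll, starts, lower, upper, maxit)
  out <- .par_to_nonstim(best$par, phi2, best$value)
  out$convergence <- best$convergence
  out$warned <- isTRUE(best$warned)
  if (out$warned)
    warning("hyperparameter optimizer did not fully converge; ",
            "returning best parameters found")
  out
}

#' Fit stimulating-electrode hyperparameters per breakpoint range
#'
#' The stimulating electrode gets its own (time x stimulus) kernel, fitted
#' independently on each range between consecutive breakpoints since no
#' artifact information is shared across a breakpoint.
#'
#' @param proxy a `proxy_artifact` from [build_proxy_stim()].
#' @param breakpoints breakpoint amplitudes (uA), possibly empty.
#' @param phi2 fixed jitter variance phi'^2 (uV^2, > 0).
#' @inheritParams fit_hyperparameters
#' @return object of class `stim_hyperparams`: one fit per range plus the
#'   amplitude partition.
#' @export
fit_stim_hyperparameters <- function(proxy, breakpoints, phi2,
                                     n_starts = 5, seed = 1, maxit = 100) {
  stopifnot(inherits(proxy, "proxy_artifact"), proxy$kind == "stim",
            phi2 > 0)
  amps <- proxy$amplitudes
  range_id <- findInterval(amps, sort(breakpoints)) + 1L
  R <- length(breakpoints) + 1L
  b <- .hp_bounds()
  lower <- c(b$log_rho[1], b$log_lam[1], b$alpha[1], b$log_beta[1],
             b$log_lam[1])
  upper <- c(b$log_rho[2], b$log_lam[2], b$alpha[2], b$log_beta[2],
             b$log_lam[2])
  fits <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- which(range_id == r)
    if (!length(idx)) stop("empty breakpoint range")
    vals <- proxy$values[, idx, drop = FALSE]
    grids <- list(time = axis_grid(proxy$time_ms),
                  stimulus = axis_grid(amps[idx], envelope = amps[idx]))
    nll <- .hp_nll_factory(vals, grids, phi2, .stim_kernel_from_par)
    p0 <- .hp_init_stim(vals, proxy$time_ms, amps[idx], phi2)
    set.seed(seed + 1000L * r)
    starts <- c(list(p0),
                lapply(seq_len(max(n_starts - 1L, 0L)), function(s)
                  p0 + stats::rnorm(length(p0), sd = 0.6)))
    best <- .hp_optimize(nll, starts, lower, upper, maxit)
    p <- best$par
    # moment-matched per-amplitude scale profile: the stationary fit
    # spreads variance evenly over the range, but the stimulating
    # electrode's artifact energy grows with amplitude; rescaling the
    # stimulus factor to the realized per-amplitude mean square keeps the
    # filter's shrinkage honest at the top of the range
    ms <- pmax(colMeans(vals^2) - phi2, 1e-8)
    prof <- sqrt(ms / mean(ms))
    fits[[r]] <- list(
      time = axis_params(exp(p[2]), p[3], exp(p[4])),
      stimulus = axis_params(exp(p[5])),
      rho = exp(p[1]), scale_profile = prof, nll = best$value, idx = idx,
      convergence = best$convergence)
  }
  structure(list(ranges = fits, breakpoints = sort(breakpoints),
                 amplitudes = amps, phi2 = phi2),
            class = "stim_hyperparams")
}

#' Noise estimates bundle
#' @param sigma2 observation-noise variance (uV^2).
#' @param phi2 non-stimulating artifact jitter (uV^2).
#' @param phi2_stim stimulating-electrode jitter (uV^2).
#' @return object of class `noise_estimates`.
#' @export
noise_estimates <- function(sigma2, phi2, phi2_stim = phi2) {
  stopifnot(sigma2 >= 0, phi2 >= 0, phi2_stim >= 0)
  structure(list(sigma2 = sigma2, phi2 = phi2, phi2_stim = phi2_stim),
            class = "noise_estimates")
}

#' Full initialization for one amplitude series
#'
#' Convenience wrapper running the whole initialization stage on a single
#' series: switching-mean subtraction, proxy construction, `phi2` /
#' `sigma2` estimation, and hyperparameter fits for both the
#' non-stimulating-electrode kernel and the per-range stimulating-electrode
#' kernels.
#'
#' @param raw a [trace_series()] with a layout attached.
#' @param n_starts,seed,maxit passed to the optimizers.
#' @param proxy_stat `"mean"` or `"median"` for the stimulating-electrode
#'   proxy.
#' @return object of class `series_model` with elements `nonstim`, `stim`,
#'   `noise` and the centered traces.
#' @export
fit_series_model <- function(raw, n_starts = 5, seed = 1, maxit = 100,
                             proxy_stat = "mean") {
  stopifnot(inherits(raw, "trace_series"))
  if (is.null(raw$layout))
    stop("trace series must carry a layout for proxy construction")
  centered <- subtract_switching_mean(raw)
  proxy_ns <- build_proxy_nonstim(list(centered), raw$layout)
  proxy_st <- build_proxy_stim(centered, stat = proxy_stat)
  sigma2 <- estimate_sigma2(centered)
  # the proxy is a trial mean, so its background variance is
  # phi2 + sigma2 / n_j; remove the known trial-mean noise part
  nbar <- mean(n_trials(raw))
  phi2 <- max(estimate_phi2(proxy_ns) - sigma2 / nbar, 1e-2)
  phi2_stim <- max(estimate_phi2(proxy_st) - sigma2 / nbar, 1e-2)
  nonstim <- fit_hyperparameters(proxy_ns, phi2 = phi2, n_starts = n_starts,
                                 seed = seed, maxit = maxit)
  stim <- fit_stim_hyperparameters(proxy_st, raw$breakpoints,
                                   phi2 = phi2_stim, n_starts = n_starts,
                                   seed = seed, maxit = maxit)
  structure(list(nonstim = nonstim, stim = stim,
                 noise = noise_estimates(sigma2, phi2, phi2_stim),
                 centered = centered),
            class = "series_model")
}
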