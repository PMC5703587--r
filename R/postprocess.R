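#' Activation curves, thresholds and failure diagnostics
#'
#' Inferred spikes are summarized per neuron as an activation curve: the
#' proportion of trials with a spike as a function of stimulus amplitude,
#' fitted with the CDF of a normal distribution. A neuron is called
#' activated when the fitted curve exceeds 0.5 within the stimulated
#' range; the activation threshold is then the amplitude giving 0.5 spike
#' probability, which for the normal CDF is exactly the fitted mean.
#'
#' @name postprocess
NULL

#' Empirical activation proportions
#'
#' @param spikes spike table (`series_fit$spikes` or the ground-truth
#'   table).
#' @param amplitudes stimulus amplitudes (uA).
#' @param n_trials trials per amplitude.
#' @param neuron_ids neurons to summarize; defaults to those present in
#'   the spike table. Ids absent from `neuron_ids` raise an error.
#' @return data.frame with one row per (neuron, amplitude):
#'   `neuron_id`, `amplitude_index`, `amplitude_uA`, `n`, `k`, `p_hat`.
#' @export
empirical_activation <- function(spikes, amplitudes, n_trials,
                                 neuron_ids = NULL) {
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  if (nrow(spikes) && !all(spikes$neuron_id %in% neuron_ids))
    stop("spike table contains unknown neuron ids")
  out <- expand.grid(amplitude_index = seq_along(amplitudes),
                     neuron_id = neuron_ids)
  out$amplitude_uA <- amplitudes[out$amplitude_index]
  out$n <- n_trials[out$amplitude_index]
  out$k <- mapply(function(j, n) {
    s <- spikes[spikes$amplitude_index == j & spikes$neuron_id == n, ,
                drop = FALSE]
    length(unique(s$trial))
  }, out$amplitude_index, out$neuron_id)
  out$p_hat <- out$k / out$n
  out[order(out$neuron_id, out$amplitude_index),
      c("neuron_id", "amplitude_index", "amplitude_uA", "n", "k", "p_hat")]
}

# Bernoulli negative log likelihood of the probit activation model.
.act_nll <- function(par, a, k, n) {
  p <- stats::pnorm((a - par[1]) / exp(par[2]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit a normal-CDF activation curve
#'
#' Bernoulli maximum likelihood for `p(a) = pnorm((a - mu_a) / s_a)` on
#' per-amplitude spike counts, optimized over `(mu_a, log s_a)` from an
#' initialization at the empirical 50% crossing. A neuron is `activated`
#' when the fitted probability reaches 0.5 at the maximum stimulated
#' amplitude; the threshold (current for 0.5 spiking probability) is then
#' exactly `mu_a`. Degenerate data (no spikes anywhere, or spikes on every
#' trial everywhere) decide activation directly and flag the fit.
#'
#' @param proportions data.frame for one neuron as returned by
#'   [empirical_activation()] (columns `amplitude_uA`, `n`, `k`), or the
#'   full frame plus `neuron_id` to select.
#' @param neuron_id neuron to fit when `proportions` covers several.
#' @return object of class `activation_curve`: `mu_a`, `s_a`,
#'   `activated`, `threshold_uA` (NA unless activated), `degenerate`,
#'   `loglik`, and the empirical curve.
#' @export
fit_activation_cdf <- function(proportions, neuron_id = NULL) {
  d <- proportions
  if (!is.null(neuron_id)) d <- d[d$neuron_id == neuron_id, , drop = FALSE]
  if (length(unique(d$amplitude_uA)) < 2L)
    stop("need at least two distinct amplitudes")
  a <- d$amplitude_uA
  k <- d$k
  n <- d$n
  if (sum(k) == 0L) {
    return(structure(list(mu_a = NA_real_, s_a = NA_real_,
                          activated = FALSE, threshold_uA = NA_real_,
                          degenerate = TRUE, loglik = 0,
                          empirical = d), class = "activation_curve"))
  }
  if (all(k == n)) {
    return(structure(list(mu_a = NA_real_, s_a = NA_real_,
                          activated = TRUE, threshold_uA = NA_real_,
                          degenerate = TRUE, loglik = 0,
                          empirical = d), class = "activation_curve"))
  }
  p_hat <- k / n
  above <- which(p_hat >= 0.5)
  mu0 <- if (length(above)) {
    j <- min(above)
    if (j > 1L) (a[j - 1L] + a[j]) / 2 else a[1L]
  } else max(a)
  s0 <- max(diff(range(a)) / 4, 1e-2)
  init <- c(mu0, log(s0))
  fit <- stats::optim(init, .act_nll, a = a, k = k, n = n,
                      method = "L-BFGS-B",
                      lower = c(min(a) - 5 * diff(range(a)), log(1e-3)),
                      upper = c(max(a) + 5 * diff(range(a)), log(1e3)))
  # guard: keep whichever of {init, fit} has the better likelihood
  if (.act_nll(init, a, k, n) < fit$value)
    fit <- list(par = init, value = .act_nll(init, a, k, n))
  mu_a <- fit$par[1]
  s_a <- exp(fit$par[2])
  p_max <- stats::pnorm((max(a) - mu_a) / s_a)
  activated <- p_max >= 0.5
  structure(list(mu_a = mu_a, s_a = s_a, activated = activated,
                 threshold_uA = if (activated) mu_a else NA_real_,
                 degenerate = FALSE, loglik = -fit$value,
                 empirical = d), class = "activation_curve")
}

#' @export
print.activation_curve <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<activation_curve> degenerate (%s)\n",
                if (x$activated) "always spiking" else "never spiking"))
  } else {
    cat(sprintf("<activation_curve> mu_a = %.3f uA, s_a = %.3f uA, activated = %s%s\n",
                x$mu_a, x$s_a, x$activated,
                if (x$activated) sprintf(", threshold = %.3f uA",
                                         x$threshold_uA) else ""))
  }
  invisible(x)
}

#' Fit activation curves for all neurons in a series fit
#'
#' @param fit a `series_fit`.
#' @param neuron_ids neurons to summarize (default: all in the fit's
#'   bank).
#' @return named list of `activation_curve` objects.
#' @export
activation_curves <- function(fit, neuron_ids = NULL) {
  if (is.null(neuron_ids)) neuron_ids <- fit$neuron_ids
  emp <- empirical_activation(fit$spikes, fit$amplitudes, fit$n_trials,
                              neuron_ids = neuron_ids)
  out <- lapply(neuron_ids, function(n) fit_activation_cdf(emp, n))
  names(out) <- as.character(neuron_ids)
  out
}

#' Flag non-smooth activation curves
#'
#' Sudden jumps or drops in the empirical spiking probability between
#' consecutive amplitudes usually indicate sorting failures (e.g. an
#' artifact discontinuity absorbed as spikes). Flags any step larger than
#' `jump_tol`, and any decrease larger than `jump_tol` after the curve has
#' exceeded 0.5.
#'
#' @param curve an `activation_curve`, or a data.frame with `p_hat`
#'   ordered by amplitude.
#' @param jump_tol step tolerance (default 0.5).
#' @return list: `flagged`, plus the offending transition indices.
#' @export
flag_activation_jump <- function(curve, jump_tol = 0.5) {
  p <- if (inherits(curve, "activation_curve")) curve$empirical$p_hat
  else curve$p_hat
  d <- diff(p)
  jumps <- which(abs(d) > jump_tol)
  crossed <- cumsum(p >= 0.5) > 0
  drops <- which(d < -jump_tol & crossed[-length(p)])
  list(flagged = length(jumps) > 0L || length(drops) > 0L,
       jump_at = jumps, drop_at = drops)
}

#' Flag trials with unexplained residuals
#'
#' After subtracting the estimated artifact and the inferred spikes, the
#' residual of a well-explained trial is white noise at variance
#' `sigma2`. Trials whose residual mean square exceeds `sigma2 * z_tol`
#' harbour structure the model did not capture (e.g. an unmodelled neuron)
#' and are flagged for review.
#'
#' @param traces a [trace_series()] (raw; the fit's switching mean is
#'   subtracted).
#' @param fit a `series_fit`.
#' @param eis the [ei_set()] used for the fit.
#' @param sigma2 observation-noise variance (uV^2).
#' @param z_tol residual mean-square multiplier (default 4).
#' @return data.frame per (amplitude, trial): residual mean square and
#'   `flagged`.
#' @export
flag_residuals <- function(traces, fit, eis, sigma2, z_tol = 4) {
  centered <- subtract_switching_mean(traces)
  ts <- centered$traces
  Tn <- dim(ts$Y[[1]])[1]
  bank <- make_template_bank(eis, n_samples = Tn,
                             sampling_rate_hz = ts$sampling_rate_hz,
                             window_ms = fit$config$window_ms,
                             strength_threshold = fit$config$ei_threshold_uv)
  rows <- list()
  for (j in seq_along(ts$Y)) {
    n_j <- dim(ts$Y[[j]])[3]
    for (i in seq_len(n_j)) {
      sp <- fit$spikes[fit$spikes$amplitude_index == j &
                         fit$spikes$trial == i, , drop = FALSE]
      s <- matrix(0, Tn, dim(ts$Y[[j]])[2])
      if (nrow(sp)) {
        internal <- data.frame(neuron = match(sp$neuron_id,
                                              bank$neuron_ids),
                               onset = sp$onset_sample)
        s <- .spike_matrix(bank, internal)
      }
      rms <- mean((ts$Y[[j]][, , i] - fit$artifact[, , j] - s)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude_index = j, trial = i, residual_ms = rms,
        flagged = rms > sigma2 * z_tol)
    }
  }
  do.call(rbind, rows)
}

#' Plot an activation curve
#'
#' Draws the fitted normal-CDF activation curve with the empirical
#' per-amplitude spike proportions, and marks the 0.5-probability
#' threshold.
#'
#' @param x an `activation_curve`.
#' @param ... further arguments passed to [plot()].
#' @export
plot.activation_curve <- function(x, ...) {
  d <- x$empirical
  plot(d$amplitude_uA, d$p_hat, ylim = c(0, 1), pch = 19,
       xlab = "stimulus amplitude (uA)", ylab = "spike probability", ...)
  if (!x$degenerate) {
    a <- seq(min(d$amplitude_uA), max(d$amplitude_uA), length.out = 200)
    graphics::lines(a, stats::pnorm((a - x$mu_a) / x$s_a))
    if (x$activated) {
      graphics::abline(v = x$threshold_uA, lty = 2)
      graphics::abline(h = 0.5, lty = 3)
    }
  }
  invisible(x)
}
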