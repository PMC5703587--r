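# Shared fixtures: small random kernels, dense oracles, and a reduced
# simulation scenario for fast integration tests.

# Random axis grid + params, sized for dense cross-checks.
random_axis <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis_grid(sort(runif(n, 0, 3)), envelope = runif(n, 0, 2))
}

random_axis_params <- function() {
  axis_params(lam = exp(runif(1, -1, 1.5)),
              alpha = runif(1, 0, 2),
              beta = runif(1, 0.1, 2))
}

# Random 2- or 3-factor kron_kernel with total dimension <= dim_cap.
random_kron_kernel <- function(n_factors = 3, dim_cap = 500,
                               phi2 = NULL) {
  sizes <- sample(2:8, n_factors, replace = TRUE)
  while (prod(sizes) > dim_cap)
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  factors <- lapply(sizes, function(n)
    build_axis_kernel(random_axis(n), random_axis_params()))
  if (is.null(phi2)) phi2 <- runif(1, 0.05, 0.5)
  kron_kernel(factors, rho = exp(runif(1, -1, 1)), phi2 = phi2)
}

# Dense counterpart of the pure Kronecker part (no jitter).
dense_kron <- function(kernel) {
  kernel$rho * Reduce(`%x%`, rev(kernel$factors))
}

# Reduced desk scenario: 4x4 array, 6 amplitudes, 2 neurons; runs the full
# pipeline in a couple of seconds.
tiny_sim_config <- function(...) {
  sim_config(
    rows = 4, cols = 4, pitch = 60,
    amplitudes = seq(0.5, 3, length.out = 6),
    breakpoints = numeric(0),
    n_j = 5,
    n_samples = 30,
    artifact_sd_peak = 25,
    stim_artifact_sd_peak = 120,
    roster = data.frame(
      soma_row_offset = c(0, 1),
      soma_col_offset = c(1, -1),
      ei_peak = c(120, 90),
      mu_a = c(1.0, 1.8),
      s_a = c(0.25, 0.25),
      trough_width = c(1.2, 1.6),
      rebound = c(0.3, 0.4),
      rebound_lag = c(4, 6)),
    ...)
}

# series_model built from generator-truth hyperparameters: used where the
# test isolates the inference machinery from hyperparameter fitting.
oracle_model <- function(ds) {
  cfg <- ds$config
  tk <- cfg$true_kernels
  tms <- seq_len(cfg$n_samples) * 1000 / cfg$sampling_rate_hz
  amps <- cfg$amplitudes
  d <- stim_distances(ds$traces)
  d_ns <- d[d > 0]
  peak_t <- min(max(tk$time$alpha / max(tk$time$beta, 1e-9), min(tms)),
                max(tms))
  ref <- gamma_envelope(peak_t, tk$time$alpha, tk$time$beta) *
    gamma_envelope(min(d_ns), tk$electrode$alpha, tk$electrode$beta) *
    gamma_envelope(max(amps), tk$stimulus$alpha, tk$stimulus$beta)
  rho_gen <- (cfg$magnification * cfg$artifact_sd_peak / ref)^2
  # the inference model's stimulus axis is flat; absorb the generator's
  # amplitude envelope into an average scale
  s_env2 <- mean(gamma_envelope(amps, tk$stimulus$alpha,
                                tk$stimulus$beta)^2)
  nonstim <- structure(
    list(kind = "nonstim",
         params = list(time = tk$time, electrode = tk$electrode,
                       stimulus = axis_params(tk$stimulus$lam)),
         rho = rho_gen * s_env2, phi2 = max(cfg$phi_true^2, 1e-2)),
    class = "artifact_hyperparams")
  rid <- findInterval(amps, sort(cfg$breakpoints)) + 1L
  peak_ts <- min(max(tk$stim_time$alpha / max(tk$stim_time$beta, 1e-9),
                     min(tms)), max(tms))
  ranges <- lapply(sort(unique(rid)), function(r) {
    idx <- which(rid == r)
    ref_r <- gamma_envelope(peak_ts, tk$stim_time$alpha,
                            tk$stim_time$beta) *
      gamma_envelope(max(amps[idx]), tk$stim_stimulus$alpha,
                     tk$stim_stimulus$beta)
    rho_r <- (cfg$magnification * cfg$stim_artifact_sd_peak / ref_r)^2
    s2 <- mean(gamma_envelope(amps[idx], tk$stim_stimulus$alpha,
                              tk$stim_stimulus$beta)^2)
    list(time = tk$stim_time, stimulus = axis_params(tk$stim_stimulus$lam),
         rho = rho_r * s2, idx = idx)
  })
  stim <- structure(list(ranges = ranges,
                         breakpoints = sort(cfg$breakpoints),
                         amplitudes = amps,
                         phi2 = max(cfg$phi_true^2, 1e-2)),
                    class = "stim_hyperparams")
  structure(list(nonstim = nonstim, stim = stim,
                 noise = noise_estimates(cfg$sigma^2,
                                         max(cfg$phi_true^2, 1e-2))),
            class = "series_model")
}
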