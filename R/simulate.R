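#' Synthetic amplitude-series generator
#'
#' Generates data from the additive observation model: traces are the sum
#' of a GP-sampled stimulation artifact, spike waveforms placed by a
#' probabilistic activation model, and white Gaussian noise. The artifact
#' is drawn from the same structured Kronecker GP family the inference
#' assumes, with default hyperparameters chosen to reproduce the
#' qualitative artifact structure seen in stimulation experiments: a
#' temporal variance bump near 0.5 ms, spatial decay that makes the
#' artifact negligible beyond about 700 um from the stimulating electrode,
#' smooth growth with stimulus amplitude, and an independent, much larger,
#' piecewise (per breakpoint range) artifact on the stimulating electrode.
#' Spiking probability follows a normal CDF of amplitude per neuron, and
#' spike latency variability shrinks as spiking probability approaches one.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Defaults define a desk-scale scenario that preserves every structural
#' feature of a large-array experiment at reduced electrode count:
#' 8 x 8 = 64 electrodes at 60 um pitch, 2 ms records at 20 kHz (T = 40),
#' J = 20 amplitudes from 0.1 to 4 uA with one breakpoint at 2 uA, 20
#' trials per amplitude, 4 neurons and 6 uV observation noise.
#'
#' @param ... overrides of the defaults listed in Details.
#' @details Configurable fields: `rows`, `cols`, `pitch` (layout);
#'   `amplitudes`, `breakpoints`, `n_j`, `sampling_rate_hz`, `n_samples`
#'   (protocol); `sigma` (noise sd, uV); `magnification` (artifact scale
#'   factor, default 1); `artifact_sd_peak` (target artifact sd at the
#'   most-affected non-stimulating coordinate, uV),
#'   `stim_artifact_sd_peak` (same for the stimulating electrode);
#'   `true_kernels` (axis hyperparameters of the generating GP);
#'   `roster` (per-neuron soma electrode, EI peak uV, activation mean
#'   `mu_a` and sd `s_a` in uA); `latency` (endpoints `L_hi`, `L_lo`,
#'   `sd_hi`, `sd_lo` in ms of the latency-vs-probability model);
#'   `window_ms` (spike window); `ei_t_prime`, `ei_decay_um` (EI shape).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    rows = 8, cols = 8, pitch = 60,
    amplitudes = seq(0.1, 4, length.out = 20),
    breakpoints = 2,
    n_j = 20,
    sampling_rate_hz = 20000,
    n_samples = 40,
    sigma = 6,
    magnification = 1,
    artifact_sd_peak = 40,
    stim_artifact_sd_peak = 300,
    phi_true = 1,
    true_kernels = list(
      time = axis_params(lam = 2, alpha = 2, beta = 4),
      electrode = axis_params(lam = 0.005, alpha = 0, beta = 0.005),
      stimulus = axis_params(lam = 0.4, alpha = 1, beta = 0),
      stim_time = axis_params(lam = 1.5, alpha = 0.5, beta = 0.5),
      stim_stimulus = axis_params(lam = 0.4, alpha = 1, beta = 0)),
    roster = data.frame(
      soma_row_offset = c(0, 1, -1, 0),
      soma_col_offset = c(1, 0, -1, -2),
      ei_peak = c(120, 90, 150, 60),
      mu_a = c(0.8, 1.6, 2.4, 3.2),
      s_a = c(0.3, 0.3, 0.3, 0.3),
      trough_width = c(1.2, 1.6, 1.4, 1.8),
      rebound = c(0.30, 0.40, 0.25, 0.35),
      rebound_lag = c(4, 6, 5, 7)),
    latency = list(L_hi = 1.0, L_lo = 0.4, sd_hi = 0.25, sd_lo = 0.03),
    window_ms = c(0.25, 1.5),
    ei_t_prime = 20,
    ei_decay_um = 100)
  mod <- list(...)
  cfg[names(mod)] <- mod
  structure(cfg, class = "sim_config")
}

# Envelope value of an axis_params at covariate x.
.env_at <- function(p, x) gamma_envelope(x, p$alpha, p$beta)

#' Sample a ground-truth artifact stack
#'
#' Draws the non-stimulating-electrode artifact from the three-factor
#' (time, electrode, stimulus) GP and, independently per breakpoint range,
#' the stimulating-electrode artifact from its own (time, stimulus) GP.
#' The GP scales `rho` are calibrated so the marginal artifact sd at the
#' most-affected coordinate (temporal envelope peak, nearest electrode,
#' top amplitude) equals the configured targets; the whole stack is then
#' multiplied by the magnification factor.
#'
#' @param config a [sim_config()].
#' @param layout the [make_layout()] for `config` (built if omitted).
#' @return `(T, E, J)` artifact array (uV); the stimulating electrode's
#'   column holds its own independent artifact.
#' @export
sample_artifact <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- make_layout(config$rows, config$cols,
                                             config$pitch)
  tk <- config$true_kernels
  tms <- seq_len(config$n_samples) * 1000 / config$sampling_rate_hz
  amps <- config$amplitudes
  e_stim <- layout$center
  e_ns <- setdiff(seq_len(nrow(layout$positions)), e_stim)
  d_stim <- sqrt(colSums((t(layout$positions) -
                            layout$positions[e_stim, ])^2))[e_ns]
  t_grid <- axis_grid(tms)
  e_grid <- axis_grid(layout$positions[e_ns, , drop = FALSE],
                      envelope = d_stim)
  s_grid <- axis_grid(amps, envelope = amps)
  # calibrate rho: sd at (peak-t, nearest electrode, top amplitude) target
  peak_t <- if (tk$time$beta > 0 && tk$time$alpha > 0)
    tk$time$alpha / tk$time$beta else max(tms)
  peak_t <- min(max(peak_t, min(tms)), max(tms))
  ref <- .env_at(tk$time, peak_t) * .env_at(tk$electrode, min(d_stim)) *
    .env_at(tk$stimulus, max(amps))
  rho <- (config$artifact_sd_peak / ref)^2
  Kt <- build_axis_kernel(t_grid, tk$time)
  Ke <- build_axis_kernel(e_grid, tk$electrode)
  Ks <- build_axis_kernel(s_grid, tk$stimulus)
  k_ns <- kron_kernel(list(Kt, Ke, Ks), rho = rho,
                      phi2 = config$phi_true^2)
  A <- array(0, dim = c(config$n_samples, nrow(layout$positions),
                        length(amps)))
  A[, e_ns, ] <- kron_sample(kron_op(k_ns))
  # stimulating electrode: independent draw per breakpoint range
  rid <- findInterval(amps, sort(config$breakpoints)) + 1L
  Kt_s <- build_axis_kernel(t_grid, tk$stim_time)
  peak_ts <- if (tk$stim_time$beta > 0 && tk$stim_time$alpha > 0)
    tk$stim_time$alpha / tk$stim_time$beta else max(tms)
  peak_ts <- min(max(peak_ts, min(tms)), max(tms))
  for (r in unique(rid)) {
    idx <- which(rid == r)
    sg <- axis_grid(amps[idx], envelope = amps[idx])
    Ks_r <- build_axis_kernel(sg, tk$stim_stimulus)
    ref_r <- .env_at(tk$stim_time, peak_ts) *
      .env_at(tk$stim_stimulus, max(amps[idx]))
    rho_r <- (config$stim_artifact_sd_peak / ref_r)^2
    k_r <- kron_kernel(list(Kt_s, Ks_r), rho = rho_r,
                       phi2 = config$phi_true^2)
    A[, e_stim, idx] <- kron_sample(kron_op(k_r))
  }
  config$magnification * A
}

#' Build synthetic electrical images
#'
#' Each neuron gets a biphasic spike waveform (sharp negative trough
#' followed by a slower positive rebound) centred on its soma electrode,
#' with amplitude decaying exponentially with electrode distance and the
#' peak absolute voltage equal to the roster's EI peak strength. Real
#' electrical images are distinguishable across cells -- waveform width,
#' rebound size and timing differ per neuron, and the spike propagates
#' outward so distal electrodes see a delayed copy -- so the waveform
#' parameters are per-neuron (roster columns `trough_width`, `rebound`,
#' `rebound_lag`, in samples) and the waveform shifts with distance at a
#' conduction speed of `velocity_um_per_sample`.
#'
#' @param layout a [make_layout()].
#' @param roster data.frame with columns `soma_row_offset`,
#'   `soma_col_offset` (grid offsets of the soma from the center
#'   electrode), `ei_peak` (uV), and optionally `trough_width`,
#'   `rebound`, `rebound_lag`.
#' @param sampling_rate_hz sampling rate.
#' @param t_prime template length in samples.
#' @param decay_um spatial decay length (um).
#' @param velocity_um_per_sample propagation speed (um per sample;
#'   default 100, i.e. 2 m/s at 20 kHz).
#' @return an [ei_set()]; templates are `(T', E)` matrices.
#' @export
make_eis <- function(layout, roster, sampling_rate_hz, t_prime = 20,
                     decay_um = 100, velocity_um_per_sample = 100) {
  stopifnot(nrow(roster) >= 1L)
  E <- nrow(layout$positions)
  rc <- ceiling(layout$rows / 2)
  cc <- ceiling(layout$cols / 2)
  k <- seq_len(t_prime)
  k0 <- max(3, round(0.25 * t_prime))
  if (is.null(roster$trough_width))
    roster$trough_width <- 1.2 + 0.2 * ((seq_len(nrow(roster)) - 1L) %% 4L)
  if (is.null(roster$rebound))
    roster$rebound <- 0.25 + 0.05 * ((seq_len(nrow(roster)) - 1L) %% 4L)
  if (is.null(roster$rebound_lag))
    roster$rebound_lag <- 4 + (seq_len(nrow(roster)) - 1L) %% 4L
  templates <- lapply(seq_len(nrow(roster)), function(n) {
    r <- rc + roster$soma_row_offset[n]
    c <- cc + roster$soma_col_offset[n]
    if (r < 1 || r > layout$rows || c < 1 || c > layout$cols)
      stop("soma offset places neuron outside the array")
    soma_e <- layout$index[r, c]
    d <- sqrt(colSums((t(layout$positions) -
                         layout$positions[soma_e, ])^2))
    w <- roster$trough_width[n]
    rb <- roster$rebound[n]
    lag <- roster$rebound_lag[n]
    tpl <- vapply(seq_len(E), function(e) {
      ks <- k - d[e] / velocity_um_per_sample   # propagation delay
      v <- -exp(-(ks - k0)^2 / (2 * w^2)) +
        rb * exp(-(ks - k0 - lag)^2 / (2 * (2 * w)^2))
      v * exp(-d[e] / decay_um)
    }, numeric(t_prime))
    tpl * (roster$ei_peak[n] / max(abs(tpl)))
  })
  ei_set(templates)
}

# Soma electrode index for each roster entry.
.soma_electrodes <- function(layout, roster) {
  rc <- ceiling(layout$rows / 2)
  cc <- ceiling(layout$cols / 2)
  vapply(seq_len(nrow(roster)), function(n)
    layout$index[rc + roster$soma_row_offset[n],
                 cc + roster$soma_col_offset[n]], integer(1))
}

#' Sample ground-truth spikes
#'
#' Per trial and neuron, a spike occurs with probability
#' `pnorm((a_j - mu_a) / s_a)`; its latency is normal with mean
#' interpolating from `L_hi` down to `L_lo` and sd from `sd_hi` down to
#' `sd_lo` as the spike probability goes from 0 to 1 (latency variability
#' shrinks as activation becomes reliable), truncated to the spike window
#' and rounded to the sample grid. At most one spike per neuron per trial.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `amplitude_index`, `amplitude_uA`,
#'   `trial`, `neuron_id`, `onset_sample`, `latency_ms` plus the spike
#'   probability used.
#' @export
sample_spikes <- function(config) {
  amps <- config$amplitudes
  rate <- config$sampling_rate_hz
  lat <- config$latency
  o_min <- max(1L, as.integer(ceiling(config$window_ms[1] * rate / 1000 - 1e-9)))
  o_max <- min(config$n_samples,
               as.integer(floor(config$window_ms[2] * rate / 1000 + 1e-9)))
  rows <- list()
  for (j in seq_along(amps)) {
    for (n in seq_len(nrow(config$roster))) {
      p <- stats::pnorm((amps[j] - config$roster$mu_a[n]) /
                          config$roster$s_a[n])
      fire <- stats::runif(config$n_j) < p
      if (!any(fire)) next
      mu_l <- lat$L_hi + (lat$L_lo - lat$L_hi) * p
      sd_l <- lat$sd_hi + (lat$sd_lo - lat$sd_hi) * p
      lms <- stats::rnorm(sum(fire), mu_l, sd_l)
      onset <- pmin(pmax(as.integer(round(lms * rate / 1000)), o_min), o_max)
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude_index = j, amplitude_uA = amps[j],
        trial = which(fire), neuron_id = n, onset_sample = onset,
        latency_ms = onset * 1000 / rate, p_spike = p)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(amplitude_index = integer(0),
                      amplitude_uA = numeric(0), trial = integer(0),
                      neuron_id = integer(0), onset_sample = integer(0),
                      latency_ms = numeric(0), p_spike = numeric(0))
  out
}

#' Assemble traces from artifact, spikes and noise
#'
#' `Y = A + sum_n M^n b^n + eps` with `eps` i.i.d. `N(0, sigma^2)`.
#'
#' @param artifact `(T, E, J)` artifact stack (uV).
#' @param spikes ground-truth spike table from [sample_spikes()].
#' @param eis an [ei_set()].
#' @param config a [sim_config()].
#' @param layout a [make_layout()].
#' @return a [trace_series()].
#' @export
assemble_traces <- function(artifact, spikes, eis, config, layout) {
  Tn <- dim(artifact)[1]
  E <- dim(artifact)[2]
  J <- dim(artifact)[3]
  bank_like <- lapply(eis$templates, identity)
  Y <- vector("list", J)
  for (j in seq_len(J)) {
    Yj <- array(stats::rnorm(Tn * E * config$n_j, sd = config$sigma),
                dim = c(Tn, E, config$n_j))
    Yj <- Yj + as.vector(artifact[, , j])
    sj <- spikes[spikes$amplitude_index == j, , drop = FALSE]
    if (nrow(sj)) {
      for (k in seq_len(nrow(sj))) {
        tpl <- bank_like[[sj$neuron_id[k]]]
        o <- sj$onset_sample[k]
        kmax <- min(nrow(tpl), Tn - o + 1L)
        Yj[o:(o + kmax - 1L), , sj$trial[k]] <-
          Yj[o:(o + kmax - 1L), , sj$trial[k]] + tpl[seq_len(kmax), ]
      }
    }
    Y[[j]] <- Yj
  }
  trace_series(Y, amplitudes = config$amplitudes,
               sampling_rate_hz = config$sampling_rate_hz,
               positions = layout$positions,
               stim_electrode = layout$center,
               breakpoints = config$breakpoints, layout = layout)
}

#' Simulate a full amplitude series with ground truth
#'
#' One-stop generator: layout, GP-sampled artifact, EIs, activation-model
#' spikes and white noise, returned together with the ground truth needed
#' for scoring.
#'
#' @param config a [sim_config()].
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return list of class `sim_dataset`: `traces` ([trace_series()]),
#'   `eis`, `truth` (spike table, artifact stack, activation parameters,
#'   soma electrodes), `config`, `layout`, `seed`.
#' @export
simulate_series <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  layout <- make_layout(config$rows, config$cols, config$pitch)
  artifact <- sample_artifact(config, layout)
  eis <- make_eis(layout, config$roster, config$sampling_rate_hz,
                  t_prime = config$ei_t_prime,
                  decay_um = config$ei_decay_um)
  spikes <- sample_spikes(config)
  traces <- assemble_traces(artifact, spikes, eis, config, layout)
  structure(list(traces = traces, eis = eis,
                 truth = list(spikes = spikes, artifact = artifact,
                              activation = config$roster,
                              soma_electrodes = .soma_electrodes(layout,
                                                                 config$roster)),
                 config = config, layout = layout, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> seed %d, %d true spikes\n", x$seed,
              nrow(x$truth$spikes)))
  print(x$traces)
  invisible(x)
}

#' Perturb a simulated dataset
#'
#' The robustness perturbations used for validation: cap the number of
#' trials per amplitude, keep only every k-th amplitude, or add extra
#' white noise to all traces. Ground truth is subset accordingly.
#'
#' @param dataset a `sim_dataset`.
#' @param mode one of `"trial_subsample"`, `"amplitude_subsample"`,
#'   `"noise_inject"`.
#' @param params list: `k` (trial cap) for trial subsampling; `step`
#'   (default 2, keep every `step`-th amplitude) for amplitude
#'   subsampling; `sigma` (injected noise sd, uV) for noise injection.
#' @param seed seed for the injected noise (required for
#'   `"noise_inject"`).
#' @return a modified `sim_dataset`.
#' @export
perturb <- function(dataset, mode, params = list(), seed = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  out <- dataset
  ts <- dataset$traces
  tr <- dataset$truth$spikes
  if (mode == "trial_subsample") {
    k <- params$k
    if (is.null(k) || k < 1) stop("trial_subsample needs params$k >= 1")
    out$traces$Y <- lapply(ts$Y, function(y)
      y[, , seq_len(min(k, dim(y)[3])), drop = FALSE])
    out$truth$spikes <- tr[tr$trial <= k, , drop = FALSE]
    out$config$n_j <- min(k, out$config$n_j)
  } else if (mode == "amplitude_subsample") {
    step <- if (is.null(params$step)) 2L else as.integer(params$step)
    keep <- seq(1L, length(ts$amplitudes), by = step)
    out$traces$Y <- ts$Y[keep]
    out$traces$amplitudes <- ts$amplitudes[keep]
    out$config$amplitudes <- ts$amplitudes[keep]
    out$truth$artifact <- dataset$truth$artifact[, , keep, drop = FALSE]
    tr <- tr[tr$amplitude_index %in% keep, , drop = FALSE]
    tr$amplitude_index <- match(tr$amplitude_index, keep)
    out$truth$spikes <- tr
  } else if (mode == "noise_inject") {
    s <- params$sigma
    if (is.null(s) || s < 0) stop("noise_inject needs params$sigma >= 0")
    if (!is.null(seed)) set.seed(seed)
    out$traces$Y <- lapply(ts$Y, function(y)
      y + array(stats::rnorm(length(y), sd = s), dim = dim(y)))
  } else {
    stop("unknown perturbation mode: ", mode)
  }
  out
}

#' Baseline artifact estimate: mean of raw traces
#'
#' The reference estimator that ignores spikes entirely: the artifact at
#' each amplitude is the plain across-trial mean of the traces. When
#' spiking is near-deterministic the mean contains the very neural
#' activity being sought, which is the failure mode this baseline is used
#' to demonstrate.
#'
#' @param traces a [trace_series()] (centered or raw).
#' @return `(T, E, J)` array of across-trial means.
#' @export
baseline_mean_of_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_series"))
  Tn <- dim(traces$Y[[1]])[1]
  E <- dim(traces$Y[[1]])[2]
  vapply(traces$Y, function(y) apply(y, c(1, 2), mean),
         matrix(0, Tn, E)) |>
    array(dim = c(Tn, E, length(traces$Y)))
}

#' Run the mean-of-traces baseline detector
#'
#' Subtracts the switching mean, freezes the per-amplitude mean of traces
#' as the artifact, and runs one matching-pursuit pass per trial against
#' it.
#'
#' @inheritParams run_simplified
#' @return a `series_fit` with `method = "baseline"`.
#' @export
run_baseline <- function(traces, eis, config = infer_config()) {
  centered <- subtract_switching_mean(traces)
  ts <- centered$traces
  Tn <- dim(ts$Y[[1]])[1]
  A <- baseline_mean_of_traces(ts)
  bank <- make_template_bank(eis, n_samples = Tn,
                             sampling_rate_hz = ts$sampling_rate_hz,
                             window_ms = config$window_ms,
                             strength_threshold = config$ei_threshold_uv)
  spike_rows <- vector("list", length(ts$Y))
  for (j in seq_along(ts$Y)) {
    n_j <- dim(ts$Y[[j]])[3]
    sp <- do.call(rbind, lapply(seq_len(n_j), function(i) {
      s <- matching_pursuit(ts$Y[[j]][, , i] - A[, , j], bank,
                            penalty = config$penalty,
                            refine = config$refine)$spikes
      if (nrow(s)) cbind(trial = i, s) else NULL
    }))
    if (!is.null(sp) && nrow(sp))
      spike_rows[[j]] <- data.frame(
        amplitude_index = j, amplitude_uA = ts$amplitudes[j],
        trial = sp$trial, neuron_id = bank$neuron_ids[sp$neuron],
        onset_sample = sp$onset,
        latency_ms = sp$onset * 1000 / ts$sampling_rate_hz)
  }
  spikes <- do.call(rbind, spike_rows)
  if (is.null(spikes))
    spikes <- data.frame(amplitude_index = integer(0),
                         amplitude_uA = numeric(0), trial = integer(0),
                         neuron_id = integer(0), onset_sample = integer(0),
                         latency_ms = numeric(0))
  structure(list(artifact = A, spikes = spikes,
                 sweeps = rep(1L, length(ts$Y)),
                 converged = rep(TRUE, length(ts$Y)),
                 switching_mean = centered$switching_mean,
                 method = "baseline", config = config,
                 amplitudes = ts$amplitudes, n_trials = n_trials(ts),
                 neuron_ids = bank$neuron_ids,
                 excluded_neurons = bank$excluded, warnings = NULL),
            class = "series_fit")
}

#' Score inferred spikes against ground truth
#'
#' Trial-by-trial comparison per (amplitude, trial, neuron): a true
#' positive requires the same neuron in the same trial with latency within
#' `latency_tol_ms`; a latency mismatch counts as both a false positive
#' and a false negative. Reports false discovery rate `FP / (FP + TP)`,
#' false omission rate `FN / (FN + TP)`, the overall per-decision error
#' rate `(FP + FN) / #decisions`, and the latency differences of matched
#' spikes.
#'
#' @param inferred spike table (`series_fit$spikes` or compatible).
#' @param truth ground-truth spike table from [sample_spikes()].
#' @param n_trials integer vector of trials per amplitude.
#' @param n_neurons total neurons considered.
#' @param latency_tol_ms latency agreement tolerance (default 0.1 ms).
#' @param amplitude_subset optional amplitude indices to restrict scoring.
#' @return list of class `spike_score` with counts and rates.
#' @export
score_spikes <- function(inferred, truth, n_trials, n_neurons,
                         latency_tol_ms = 0.1, amplitude_subset = NULL) {
  key <- function(d) paste(d$amplitude_index, d$trial, d$neuron_id)
  if (!is.null(amplitude_subset)) {
    inferred <- inferred[inferred$amplitude_index %in% amplitude_subset, ,
                         drop = FALSE]
    truth <- truth[truth$amplitude_index %in% amplitude_subset, ,
                   drop = FALSE]
    n_decisions <- sum(n_trials[amplitude_subset]) * n_neurons
  } else {
    n_decisions <- sum(n_trials) * n_neurons
  }
  ki <- key(inferred)
  kt <- key(truth)
  common <- intersect(ki, kt)
  lat_i <- inferred$latency_ms[match(common, ki)]
  lat_t <- truth$latency_ms[match(common, kt)]
  dlat <- lat_i - lat_t
  matched <- abs(dlat) <= latency_tol_ms + 1e-9
  TP <- sum(matched)
  mism <- sum(!matched)
  FP <- length(setdiff(ki, kt)) + mism
  FN <- length(setdiff(kt, ki)) + mism
  TN <- n_decisions - length(union(ki, kt))
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    FDR = if (FP + TP > 0) FP / (FP + TP) else 0,
    FOR = if (FN + TP > 0) FN / (FN + TP) else 0,
    error_rate = (FP + FN) / n_decisions,
    n_decisions = n_decisions,
    latency_diff_ms = dlat[matched]),
    class = "spike_score")
}

#' @export
print.spike_score <- function(x, ...) {
  cat(sprintf("<spike_score> TP %d FP %d FN %d TN %d | FDR %.4f FOR %.4f error %.4f%%\n",
              x$TP, x$FP, x$FN, x$TN, x$FDR, x$FOR, 100 * x$error_rate))
  invisible(x)
}
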