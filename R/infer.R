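#' Joint artifact and spike inference
#'
#' The core algorithm: for each stimulus amplitude in increasing order, the
#' artifact estimate is initialized by Gaussian-process extrapolation from
#' all lower amplitudes, then refined by coordinate ascent that alternates
#' greedy template matching pursuit over trials with GP posterior-mean
#' filtering of the spike-subtracted trial mean. A simplified variant
#' replaces filtering by the plain spike-subtracted mean and extrapolation
#' by copying the previous amplitude's artifact, and needs no
#' hyperparameters.
#'
#' @name infer
NULL

#' Template bank for matching pursuit
#'
#' Expands each neuron's electrical image into one vectorized `(T, E)`
#' spike contribution per allowed onset sample. Onsets are restricted to a
#' spike window (default 0.25-1.5 ms after stimulus onset, within which
#' each neuron fires at most once per trial); templates whose EI extends
#' past the end of the recording are truncated, with squared norms computed
#' on the truncated support. Neurons whose peak EI strength falls below the
#' threshold carry too little signal to be matched reliably and are
#' excluded; the same criterion applies per onset, so late onsets whose
#' truncation cuts away the spike's peak (leaving a near-zero template any
#' noise would "match") are dropped as well.
#'
#' @param eis an [ei_set()].
#' @param n_samples recording window length `T` (samples).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param window_ms allowed spike-onset window, ms after stimulus onset
#'   (inclusive on both ends on the sample grid).
#' @param strength_threshold minimum peak |EI| (uV, default 30) for a
#'   neuron to enter the bank.
#' @return object of class `template_bank`: a rows matrix (one vectorized
#'   template per (neuron, onset)), row norms, and the retained/excluded
#'   neuron bookkeeping.
#' @export
make_template_bank <- function(eis, n_samples, sampling_rate_hz,
                               window_ms = c(0.25, 1.5),
                               strength_threshold = 30) {
  stopifnot(inherits(eis, "ei_set"), strength_threshold >= 0)
  E <- eis$E
  rate <- sampling_rate_hz
  o_min <- max(1L, as.integer(ceiling(window_ms[1] * rate / 1000 - 1e-9)))
  o_max <- min(n_samples, as.integer(floor(window_ms[2] * rate / 1000 + 1e-9)))
  if (o_max < o_min) stop("spike window contains no sample")
  onsets <- o_min:o_max
  peak <- ei_peak_strength(eis)
  keep <- which(peak >= strength_threshold)
  if (!length(keep))
    stop("no neuron meets the EI strength threshold; bank would be empty")
  n_rows <- length(keep) * length(onsets)
  rows <- matrix(0, n_rows, n_samples * E)
  neuron <- integer(n_rows)
  onset <- integer(n_rows)
  r <- 0L
  for (n in keep) {
    tpl <- eis$templates[[n]]
    Tp <- nrow(tpl)
    for (o in onsets) {
      kmax <- min(Tp, n_samples - o + 1L)
      m <- matrix(0, n_samples, E)
      m[o:(o + kmax - 1L), ] <- tpl[seq_len(kmax), ]
      if (max(abs(m)) < strength_threshold) next  # truncated peak too weak
      r <- r + 1L
      rows[r, ] <- as.vector(m)
      neuron[r] <- n
      onset[r] <- o
    }
  }
  rows <- rows[seq_len(r), , drop = FALSE]
  neuron <- neuron[seq_len(r)]
  onset <- onset[seq_len(r)]
  if (!r) stop("no (neuron, onset) template survives truncation")
  structure(list(rows = rows, norms = rowSums(rows^2), neuron = neuron,
                 onset = onset, onsets = onsets, n_samples = n_samples,
                 n_electrodes = E, sampling_rate_hz = rate,
                 neuron_ids = eis$neuron_ids, retained = keep,
                 excluded = setdiff(seq_along(eis$templates), keep),
                 strength_threshold = strength_threshold),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d neurons x %d onsets (samples %d-%d), %d excluded below %g uV\n",
              length(x$retained), length(x$onsets), min(x$onsets),
              max(x$onsets), length(x$excluded), x$strength_threshold))
  invisible(x)
}

#' Greedy template matching pursuit on one trial
#'
#' Iteratively selects the (neuron, onset) template whose subtraction most
#' decreases the squared residual: the gain of adding template `m` to the
#' current residual `r` is `delta = 2 <r, m> - ||m||^2`. The best candidate
#' is accepted iff `delta > penalty` (default 0, i.e. pure likelihood
#' improvement), its template subtracted, and the neuron retired for this
#' trial (at most one spike per neuron). Ties break toward the lower neuron
#' index, then the earlier onset. An empty spike set is a valid outcome.
#'
#' After the greedy pass, a backfitting refinement (enabled by default)
#' cycles over neurons, re-fitting each one's onset-or-absent decision
#' given the templates currently assigned to the others, until no move
#' improves the fit. Each move strictly decreases the squared residual, so
#' the refinement terminates; for a single-neuron bank it changes nothing
#' (the greedy pass is already exhaustive there). This resolves
#' decompositions of overlapping spikes that one-shot greedy subtraction
#' gets wrong.
#'
#' @param resid `(T, E)` artifact-subtracted residual trace (uV).
#' @param bank a [make_template_bank()].
#' @param exclude_electrodes electrode indices ignored in the likelihood
#'   (their samples contribute neither to `<r, m>` nor to `||m||^2`); used
#'   for the stimulating electrode right after a breakpoint.
#' @param penalty nonnegative acceptance margin on `delta`.
#' @param refine logical: run the backfitting refinement (default TRUE).
#' @return list with `spikes` (data.frame `neuron`, `onset`) and the final
#'   `residual` matrix after subtracting accepted templates in full.
#' @export
matching_pursuit <- function(resid, bank, exclude_electrodes = integer(0),
                             penalty = 0, refine = TRUE) {
  stopifnot(inherits(bank, "template_bank"))
  Tn <- bank$n_samples
  r <- as.vector(resid)
  if (length(r) != Tn * bank$n_electrodes)
    stop("residual has wrong dimensions for this bank")
  if (length(exclude_electrodes)) {
    mask_cols <- as.vector(outer(seq_len(Tn),
                                 (exclude_electrodes - 1L) * Tn, "+"))
    B <- bank$rows
    B[, mask_cols] <- 0
    norms <- rowSums(B^2)
  } else {
    B <- bank$rows
    norms <- bank$norms
  }
  neurons <- bank$retained
  rows_of <- split(seq_along(bank$neuron), bank$neuron)
  assign_row <- stats::setNames(rep(NA_integer_, length(neurons)), neurons)
  # greedy pass
  repeat {
    live <- is.na(assign_row)[as.character(bank$neuron)]
    if (!any(live)) break
    delta <- 2 * as.vector(B %*% r) - norms
    delta[!live] <- -Inf
    best <- which.max(delta)
    if (delta[best] <= penalty) break
    assign_row[as.character(bank$neuron[best])] <- best
    r <- r - bank$rows[best, ]          # subtract the full template
  }
  # backfitting refinement: cycle neurons, re-fit onset-or-absent given
  # the others; every move strictly decreases the squared residual
  if (refine && length(neurons) > 1L) {
    for (pass in seq_len(10L)) {
      changed <- FALSE
      for (nn in as.character(neurons)) {
        cur <- assign_row[[nn]]
        if (!is.na(cur)) r <- r + bank$rows[cur, ]
        idx <- rows_of[[nn]]
        delta <- 2 * as.vector(B[idx, , drop = FALSE] %*% r) - norms[idx]
        b <- which.max(delta)
        new <- if (delta[b] > penalty) idx[b] else NA_integer_
        if (!is.na(new)) r <- r - bank$rows[new, ]
        same <- (is.na(new) && is.na(cur)) ||
          (!is.na(new) && !is.na(cur) && new == cur)
        if (!same) changed <- TRUE
        assign_row[[nn]] <- new
      }
      if (!changed) break
    }
  }
  sel <- sort(assign_row[!is.na(assign_row)])  # canonical neuron-major order
  list(spikes = data.frame(neuron = bank$neuron[sel],
                           onset = bank$onset[sel]),
       residual = matrix(r, Tn, bank$n_electrodes))
}

# Fixed-amplitude sub-kernel: drops the stimulus (last) factor, folding its
# diagonal entry into the scale; the remaining factor eigendecompositions
# are reused from the cache.
fixed_j_kernel <- function(kernel, j) {
  if (inherits(kernel, "stim_kernel")) return(.stim_fixed_j(kernel, j))
  nf <- length(kernel$factors)
  Ks <- kernel$factors[[nf]]
  out <- kernel
  out$factors <- kernel$factors[-nf]
  out$eig <- kernel$eig[-nf]
  out$dims <- kernel$dims[-nf]
  out$rho <- kernel$rho * Ks[j, j]
  out
}

#' GP artifact filtering at one amplitude
#'
#' Posterior-mean estimate of the artifact given the spike-subtracted trial
#' mean: `K (K + (sigma2/n_j + phi2) I)^{-1} x`, i.e. Wiener shrinkage of
#' every kernel eigencomponent by `kappa / (kappa + sigma2/n_j + phi2)`.
#' When the noise term vanishes the filter is the identity and the estimate
#' equals the spike-subtracted mean.
#'
#' @param x spike-subtracted trial mean: `(T, E)` matrix (non-stimulating
#'   kernel) or length-`T` vector (stimulating-electrode kernel).
#' @param kernel_j the fixed-amplitude sub-kernel (a [kron_kernel()] whose
#'   scale already includes the stimulus-diagonal entry).
#' @param sigma2 observation-noise variance (uV^2).
#' @param n_j number of trials averaged.
#' @param phi2 artifact jitter variance (uV^2).
#' @return filtered artifact, same shape as `x`.
#' @export
filter_artifact <- function(x, kernel_j, sigma2, n_j, phi2) {
  stopifnot(n_j >= 1)
  kron_shrink(x, kernel_j, c = sigma2 / n_j + phi2)
}

#' GP artifact extrapolation to the next amplitude
#'
#' Initializes the artifact at a new amplitude as the mean of the
#' noise-free GP posterior given the artifact estimates at all lower
#' amplitudes: `K_(target,obs) (K_(obs,obs) + phi2 I)^{-1} A_hat`.
#'
#' @param A_hat array of artifact estimates at the observed amplitudes,
#'   last dimension = `length(obs_idx)`.
#' @param kernel the full [kron_kernel()] over all amplitudes.
#' @param obs_idx stimulus indices of the estimates in `A_hat`.
#' @param target_idx stimulus index(es) to predict.
#' @param phi2 artifact jitter variance (uV^2).
#' @return predicted artifact at the target amplitude(s).
#' @export
extrapolate_artifact <- function(A_hat, kernel, obs_idx, target_idx, phi2) {
  kron_conditional_mean(kernel, obs_idx, target_idx, A_hat, noise = phi2)
}

# Sum of bank templates for a set of accepted rows, as a (T, E) matrix.
.spike_matrix <- function(bank, spikes) {
  m <- matrix(0, bank$n_samples, bank$n_electrodes)
  if (nrow(spikes) == 0L) return(m)
  for (k in seq_len(nrow(spikes))) {
    row <- which(bank$neuron == spikes$neuron[k] &
                   bank$onset == spikes$onset[k])
    m <- m + matrix(bank$rows[row, ], bank$n_samples, bank$n_electrodes)
  }
  m
}

.assignments_equal <- function(a, b) {
  length(a) == length(b) &&
    all(mapply(function(x, y) identical(x$spikes, y$spikes), a, b))
}

#' Coordinate ascent at one amplitude
#'
#' Alternates matching pursuit over all trials (given the current artifact)
#' with artifact re-estimation from the spike-subtracted trial mean (GP
#' filtering, or the plain mean for the simplified method), until the spike
#' assignments are identical between consecutive sweeps or `max_sweeps` is
#' reached.
#'
#' @param Yj `(T, E, n_j)` centered traces at this amplitude (uV).
#' @param A0 `(T, E)` initial artifact estimate.
#' @param bank a [make_template_bank()].
#' @param sigma2 observation-noise variance (uV^2).
#' @param kernel_j fixed-amplitude non-stimulating sub-kernel, or `NULL`
#'   for the simplified (plain-mean) update.
#' @param kernel_electrodes electrode indices the spatial factor of
#'   `kernel_j` covers (default: all electrodes); other columns keep the
#'   plain-mean update unless handled by the stimulating-electrode kernel.
#' @param phi2 artifact jitter (uV^2; ignored for the simplified update).
#' @param stim_electrode index of the stimulating electrode; its artifact
#'   row is updated with `stim_kernel_j` rather than the spatial kernel.
#' @param stim_kernel_j fixed-amplitude stimulating-electrode time kernel,
#'   or `NULL` for the plain-mean update on that electrode.
#' @param phi2_stim stimulating-electrode jitter (uV^2).
#' @param max_sweeps sweep cap (default 5); hitting it without stable
#'   assignments sets `converged = FALSE`.
#' @param exclude_first_sweep electrode indices excluded from the matching
#'   pursuit likelihood during the first sweep (breakpoint rule).
#' @param penalty matching-pursuit acceptance margin.
#' @param refine enable matching-pursuit backfitting refinement.
#' @return list: artifact `A` (T, E), per-trial `assignments`, `spikes`
#'   data.frame (trial, neuron, onset), `sweeps`, `converged`,
#'   `residual_norm2`.
#' @export
coordinate_ascent <- function(Yj, A0, bank, sigma2, kernel_j = NULL,
                              kernel_electrodes = NULL, phi2 = 0,
                              stim_electrode = NULL,
                              stim_kernel_j = NULL, phi2_stim = phi2,
                              max_sweeps = 5, exclude_first_sweep = integer(0),
                              penalty = 0, refine = TRUE) {
  if (is.null(kernel_electrodes)) kernel_electrodes <- seq_len(dim(Yj)[2])
  n_j <- dim(Yj)[3]
  A <- A0
  prev <- replicate(n_j, list(spikes = data.frame(neuron = integer(0),
                                                  onset = integer(0))),
                    simplify = FALSE)
  Ybar <- apply(Yj, c(1, 2), mean)
  sweeps <- 0L
  converged <- FALSE
  cur <- prev
  repeat {
    sweeps <- sweeps + 1L
    excl <- if (sweeps == 1L) exclude_first_sweep else integer(0)
    cur <- lapply(seq_len(n_j), function(i)
      matching_pursuit(Yj[, , i] - A, bank, exclude_electrodes = excl,
                       penalty = penalty, refine = refine))
    sbar <- Reduce(`+`, lapply(cur, function(x)
      .spike_matrix(bank, x$spikes))) / n_j
    x <- Ybar - sbar
    A <- x
    if (!is.null(kernel_j))
      A[, kernel_electrodes] <-
        filter_artifact(x[, kernel_electrodes, drop = FALSE], kernel_j,
                        sigma2, n_j, phi2)
    if (!is.null(stim_electrode)) {
      A[, stim_electrode] <-
        if (is.null(stim_kernel_j)) x[, stim_electrode]
        else filter_artifact(x[, stim_electrode], stim_kernel_j, sigma2,
                             n_j, phi2_stim)
    }
    if (.assignments_equal(cur, prev)) { converged <- TRUE; break }
    prev <- cur
    if (sweeps >= max_sweeps) break
  }
  spikes <- do.call(rbind, lapply(seq_len(n_j), function(i) {
    s <- cur[[i]]$spikes
    if (nrow(s)) cbind(trial = i, s) else NULL
  }))
  if (is.null(spikes))
    spikes <- data.frame(trial = integer(0), neuron = integer(0),
                         onset = integer(0))
  rn <- sum(vapply(seq_len(n_j), function(i)
    sum((Yj[, , i] - A - .spike_matrix(bank, cur[[i]]$spikes))^2),
    numeric(1)))
  list(A = A, assignments = cur, spikes = spikes, sweeps = sweeps,
       converged = converged, residual_norm2 = rn)
}

.default_config <- function(...) {
  cfg <- list(window_ms = c(0.25, 1.5), ei_threshold_uv = 30,
              max_sweeps = 5, penalty = 0, refine = TRUE,
              trial_budget = Inf,
              extrapolation = "kernel", filtering = "kernel",
              keep_frac = 0.25)
  mod <- list(...)
  if (length(mod) == 1L && is.list(mod[[1]]) && is.null(names(mod)))
    mod <- mod[[1]]
  cfg[names(mod)] <- mod
  cfg
}

#' Inference configuration
#'
#' @param ... overrides of the defaults: `window_ms` (c(0.25, 1.5)),
#'   `ei_threshold_uv` (30), `max_sweeps` (5), `penalty` (0), `refine`
#'   (TRUE: matching-pursuit backfitting), `trial_budget` (Inf),
#'   `extrapolation` ("kernel" or "naive"), `filtering` ("kernel" or
#'   "mean").
#' @return named list of configuration values.
#' @export
infer_config <- function(...) .default_config(...)

# Build inference kernels on the dataset grids from fitted hyperparameters.
.series_kernels <- function(traces, model) {
  e_ns <- setdiff(seq_len(nrow(traces$positions)), traces$stim_electrode)
  d_stim <- stim_distances(traces)[e_ns]
  t_grid <- axis_grid(time_ms(traces))
  e_grid <- axis_grid(traces$positions[e_ns, , drop = FALSE],
                      envelope = d_stim)
  s_grid <- axis_grid(traces$amplitudes,
                      envelope = rep(0, length(traces$amplitudes)))
  hp <- model$nonstim
  nonstim <- assemble_nonstim_kernel(t_grid, e_grid, s_grid, hp$params,
                                     rho = hp$rho, phi2 = hp$phi2)
  stim <- NULL
  if (!is.null(model$stim)) {
    pr <- lapply(model$stim$ranges, function(r)
      list(time = r$time, stimulus = r$stimulus, rho = r$rho,
           scale_profile = r$scale_profile))
    stim <- assemble_stim_kernel(t_grid, traces$amplitudes,
                                 model$stim$breakpoints, pr,
                                 phi2p = model$stim$phi2)
  }
  list(nonstim = nonstim, stim = stim, e_nonstim = e_ns)
}

# Fixed-j stimulating-electrode time kernel from a stim_kernel.
.stim_fixed_j <- function(stim, j) {
  r <- which(vapply(stim$ranges, function(ix) j %in% ix, logical(1)))
  b <- stim$blocks[[r]]
  pos <- match(j, stim$ranges[[r]])
  out <- b
  out$factors <- b$factors[1]
  out$eig <- b$eig[1]
  out$dims <- b$dims[1]
  out$rho <- b$rho * b$factors[[2]][pos, pos]
  out
}

# First amplitude index of each breakpoint range except the first.
.range_starts_after_break <- function(amplitudes, breakpoints) {
  if (!length(breakpoints)) return(integer(0))
  rid <- findInterval(amplitudes, sort(breakpoints)) + 1L
  starts <- vapply(unique(rid), function(r) min(which(rid == r)), integer(1))
  setdiff(starts, 1L)
}

#' Run joint inference over a full amplitude series
#'
#' Processes amplitudes in increasing order. The first amplitude starts
#' from a zero artifact; every later amplitude is initialized by GP
#' extrapolation from all lower amplitudes (or by copying the previous
#' estimate when `extrapolation = "naive"`). At each amplitude, matching
#' pursuit and artifact filtering alternate until the spike assignments
#' stabilize. The stimulating electrode is handled with its own per-range
#' kernel; at the first amplitude after each breakpoint its artifact
#' restarts at zero and the electrode is excluded from the matching-pursuit
#' likelihood during the first sweep, since no information crosses a
#' breakpoint there.
#'
#' With a finite `trial_budget` in the configuration, only the first
#' `budget` trials per amplitude drive the artifact loop; the remaining
#' trials get a single matching-pursuit pass against the frozen artifact.
#'
#' @param traces a [trace_series()] (raw; the switching mean is subtracted
#'   internally).
#' @param model a `series_model` from [fit_series_model()], or a list with
#'   elements `nonstim` (`artifact_hyperparams`), `stim`
#'   (`stim_hyperparams` or `NULL`) and `noise` ([noise_estimates()]).
#' @param eis an [ei_set()].
#' @param config an [infer_config()].
#' @return object of class `series_fit`: the artifact stack
#'   `(T, E, J)` (centered scale), the spike table (columns
#'   `amplitude_index`, `amplitude_uA`, `trial`, `neuron_id`,
#'   `onset_sample`, `latency_ms`), per-amplitude sweep counts and
#'   convergence flags, residual norms, and the switching mean.
#' @export
run_amplitude_series <- function(traces, model, eis,
                                 config = infer_config()) {
  stopifnot(inherits(traces, "trace_series"), inherits(eis, "ei_set"))
  if (eis$E != nrow(traces$positions))
    stop("EI electrode count does not match the trace series")
  centered <- subtract_switching_mean(traces)
  kernels <- .series_kernels(traces, model)
  noise <- model$noise
  .run_series(centered, eis, config, kernels = kernels, noise = noise,
              method = "kernel")
}

#' Run the simplified (kernel-free) estimator
#'
#' Same per-amplitude loop, with GP filtering replaced by the plain
#' across-trial mean of spike-subtracted traces and GP extrapolation
#' replaced by copying the previous amplitude's artifact. Requires no
#' hyperparameters. The breakpoint rule for the stimulating electrode still
#' applies.
#'
#' @inheritParams run_amplitude_series
#' @return a `series_fit`, as for [run_amplitude_series()].
#' @export
run_simplified <- function(traces, eis, config = infer_config()) {
  stopifnot(inherits(traces, "trace_series"), inherits(eis, "ei_set"))
  if (eis$E != nrow(traces$positions))
    stop("EI electrode count does not match the trace series")
  config$filtering <- "mean"
  config$extrapolation <- "naive"
  centered <- subtract_switching_mean(traces)
  .run_series(centered, eis, config, kernels = NULL, noise = NULL,
              method = "simplified")
}

.run_series <- function(centered, eis, config, kernels, noise, method) {
  ts <- centered$traces
  Tn <- dim(ts$Y[[1]])[1]
  E <- dim(ts$Y[[1]])[2]
  J <- length(ts$Y)
  rate <- ts$sampling_rate_hz
  bank <- make_template_bank(eis, n_samples = Tn, sampling_rate_hz = rate,
                             window_ms = config$window_ms,
                             strength_threshold = config$ei_threshold_uv)
  use_kernel_filter <- method == "kernel" && config$filtering == "kernel"
  use_kernel_extrap <- method == "kernel" && config$extrapolation == "kernel"
  e_stim <- ts$stim_electrode
  restart_j <- .range_starts_after_break(ts$amplitudes, ts$breakpoints)
  A_hat <- array(0, dim = c(Tn, E, J))
  sweeps <- integer(J)
  converged <- logical(J)
  resid_norm2 <- numeric(J)
  spike_rows <- vector("list", J)
  budget <- config$trial_budget
  for (j in seq_len(J)) {
    Yj <- ts$Y[[j]]
    n_j <- dim(Yj)[3]
    n_fit <- min(n_j, budget)
    # --- initialization A0 ---
    A0 <- matrix(0, Tn, E)
    if (j > 1L) {
      obs <- seq_len(j - 1L)
      if (use_kernel_extrap) {
        ext <- extrapolate_artifact(
          A_hat[, kernels$e_nonstim, obs, drop = FALSE],
          kernels$nonstim, obs_idx = obs, target_idx = j,
          phi2 = kernels$nonstim$phi2)
        A0[, kernels$e_nonstim] <- ext[, , 1]
        if (!(j %in% restart_j) && !is.null(kernels$stim)) {
          # stimulating electrode: extrapolate within its breakpoint range
          r <- which(vapply(kernels$stim$ranges, function(ix) j %in% ix,
                            logical(1)))
          in_r <- intersect(kernels$stim$ranges[[r]], obs)
          if (length(in_r)) {
            b <- kernels$stim$blocks[[r]]
            pos_obs <- match(in_r, kernels$stim$ranges[[r]])
            pos_tgt <- match(j, kernels$stim$ranges[[r]])
            A0[, e_stim] <- as.vector(extrapolate_artifact(
              A_hat[, e_stim, in_r, drop = TRUE],
              b, obs_idx = pos_obs, target_idx = pos_tgt,
              phi2 = kernels$stim$phi2))
          }
        }
      } else {
        A0 <- A_hat[, , j - 1L]
        if (j %in% restart_j) A0[, e_stim] <- 0
      }
    }
    excl <- if (j %in% restart_j) e_stim else integer(0)
    kj <- if (use_kernel_filter) fixed_j_kernel(kernels$nonstim, j) else NULL
    skj <- if (use_kernel_filter && !is.null(kernels$stim))
      .stim_fixed_j(kernels$stim, j) else NULL
    sigma2 <- if (is.null(noise)) 0 else noise$sigma2
    ca <- coordinate_ascent(
      Yj[, , seq_len(n_fit), drop = FALSE], A0, bank, sigma2 = sigma2,
      kernel_j = kj,
      kernel_electrodes = if (is.null(kj)) NULL else kernels$e_nonstim,
      phi2 = if (is.null(noise)) 0 else noise$phi2,
      stim_electrode = if (use_kernel_filter) e_stim else NULL,
      stim_kernel_j = skj,
      phi2_stim = if (is.null(noise)) 0 else noise$phi2_stim,
      max_sweeps = config$max_sweeps, exclude_first_sweep = excl,
      penalty = config$penalty, refine = config$refine)
    A_hat[, , j] <- ca$A
    sweeps[j] <- ca$sweeps
    converged[j] <- ca$converged
    resid_norm2[j] <- ca$residual_norm2
    sp <- ca$spikes
    # trials beyond the budget: single matching-pursuit pass, frozen artifact
    if (n_fit < n_j) {
      extra <- lapply((n_fit + 1L):n_j, function(i) {
        s <- matching_pursuit(Yj[, , i] - ca$A, bank,
                              penalty = config$penalty,
                              refine = config$refine)$spikes
        if (nrow(s)) cbind(trial = i, s) else NULL
      })
      sp <- rbind(sp, do.call(rbind, extra))
    }
    if (nrow(sp))
      spike_rows[[j]] <- data.frame(
        amplitude_index = j, amplitude_uA = ts$amplitudes[j],
        trial = sp$trial, neuron_id = bank$neuron_ids[sp$neuron],
        onset_sample = sp$onset, latency_ms = sp$onset * 1000 / rate)
  }
  spikes <- do.call(rbind, spike_rows)
  if (is.null(spikes))
    spikes <- data.frame(amplitude_index = integer(0),
                         amplitude_uA = numeric(0), trial = integer(0),
                         neuron_id = integer(0), onset_sample = integer(0),
                         latency_ms = numeric(0))
  warn <- NULL
  if (any(!converged))
    warn <- sprintf("assignments did not stabilize at amplitude index %s",
                    paste(which(!converged), collapse = ", "))
  if (is.finite(budget) && budget < 2)
    warn <- c(warn, "trial budget of 1: artifact estimated from single trials")
  structure(list(artifact = A_hat, spikes = spikes, sweeps = sweeps,
                 converged = converged, residual_norm2 = resid_norm2,
                 switching_mean = centered$switching_mean, method = method,
                 config = config, amplitudes = ts$amplitudes,
                 n_trials = n_trials(ts), neuron_ids = bank$neuron_ids,
                 excluded_neurons = bank$excluded, warnings = warn),
            class = "series_fit")
}

#' @export
print.series_fit <- function(x, ...) {
  cat(sprintf("<series_fit> method = %s, J = %d amplitudes, %d spikes, sweeps %s\n",
              x$method, length(x$sweeps), nrow(x$spikes),
              paste(range(x$sweeps), collapse = "-")))
  if (!is.null(x$warnings)) cat(" warning:", x$warnings, "\n")
  invisible(x)
}

#' Amplitude series inference under a trial budget
#'
#' Artifact estimation cost is fixed per amplitude while matching pursuit is
#' cheap per trial, so for large trial counts the artifact can be estimated
#' from a moderate number of trials and then frozen; the remaining trials
#' receive a single matching-pursuit pass against it.
#'
#' @inheritParams run_amplitude_series
#' @param budget_n trials per amplitude used for artifact estimation
#'   (>= 1); larger than `n_j` simply uses all trials.
#' @return a `series_fit`.
#' @export
apply_trial_budget <- function(traces, model, eis, budget_n,
                               config = infer_config()) {
  stopifnot(budget_n >= 1)
  config$trial_budget <- budget_n
  run_amplitude_series(traces, model, eis, config)
}
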