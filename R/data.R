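#' Trace-series container
#'
#' An amplitude series: repeated-trial voltage recordings in response to one
#' stimulating configuration at a sequence of increasing current amplitudes.
#'
#' @param Y list with one element per stimulus amplitude, each a numeric
#'   array of dimension `(T, E, n_j)` (time sample, electrode, trial) in uV;
#'   `n_j` may differ across amplitudes.
#' @param amplitudes increasing stimulus amplitudes (uA), one per element of
#'   `Y`.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param positions `E x 2` matrix of electrode x,y positions (um).
#' @param stim_electrode index of the stimulating electrode.
#' @param breakpoints amplitudes (uA) at which stimulation-hardware gain
#'   changes make the stimulating-electrode artifact discontinuous; may be
#'   empty.
#' @param layout optional layout object from [make_layout()] (required for
#'   electrode translation when pooling proxies).
#' @return object of class `trace_series`.
#' @export
trace_series <- function(Y, amplitudes, sampling_rate_hz, positions,
                         stim_electrode, breakpoints = numeric(0),
                         layout = NULL) {
  stopifnot(is.list(Y), length(Y) == length(amplitudes))
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("'amplitudes' must be strictly increasing")
  d1 <- dim(Y[[1]])
  for (j in seq_along(Y)) {
    dj <- dim(Y[[j]])
    if (length(dj) != 3L || any(dj[1:2] != d1[1:2]))
      stop("all trace arrays must be (T, E, n_j) with common T and E")
  }
  E <- d1[2]
  positions <- as.matrix(positions)
  if (nrow(positions) != E)
    stop("'positions' must have one row per electrode")
  if (stim_electrode < 1L || stim_electrode > E)
    stop("'stim_electrode' out of range")
  structure(list(Y = Y, amplitudes = as.numeric(amplitudes),
                 sampling_rate_hz = sampling_rate_hz,
                 positions = positions,
                 stim_electrode = as.integer(stim_electrode),
                 breakpoints = as.numeric(breakpoints),
                 layout = layout),
            class = "trace_series")
}

#' @export
print.trace_series <- function(x, ...) {
  d <- dim(x$Y[[1]])
  cat(sprintf(
    "<trace_series> E = %d electrodes, T = %d samples @ %g kHz, J = %d amplitudes (%.3g-%.3g uA), n_j = %s trials\n",
    d[2], d[1], x$sampling_rate_hz / 1000, length(x$Y),
    min(x$amplitudes), max(x$amplitudes),
    paste(range(vapply(x$Y, function(y) dim(y)[3], integer(1))),
          collapse = "-")))
  invisible(x)
}

#' Number of trials per amplitude
#' @param x a `trace_series`.
#' @return integer vector of trial counts.
#' @export
n_trials <- function(x) vapply(x$Y, function(y) dim(y)[3], integer(1))

#' Time grid of a trace series
#' @param x a `trace_series`.
#' @return sample times since stimulus onset (ms).
#' @export
time_ms <- function(x) {
  Tn <- dim(x$Y[[1]])[1]
  seq_len(Tn) * 1000 / x$sampling_rate_hz
}

#' Distances from each electrode to the stimulating electrode
#' @param x a `trace_series`.
#' @return numeric vector (um).
#' @export
stim_distances <- function(x) {
  p <- x$positions
  sqrt(colSums((t(p) - p[x$stim_electrode, ])^2))
}

#' Electrical-image set
#'
#' One spatiotemporal spike template per neuron: the voltage footprint of a
#' single spike over all array electrodes, in a window of `T'` samples.
#'
#' @param templates list, one per neuron, of `(T', E)` matrices (uV); `T'`
#'   may differ from the recording window length.
#' @param neuron_ids identifiers (defaults to `1:N`).
#' @return object of class `ei_set`.
#' @export
ei_set <- function(templates, neuron_ids = NULL) {
  stopifnot(is.list(templates), length(templates) >= 1L)
  E <- ncol(templates[[1]])
  for (m in templates)
    if (!is.matrix(m) || ncol(m) != E)
      stop("all EI templates must be (T', E) matrices on the same array")
  if (is.null(neuron_ids)) neuron_ids <- seq_along(templates)
  structure(list(templates = templates, neuron_ids = neuron_ids, E = E),
            class = "ei_set")
}

#' @export
print.ei_set <- function(x, ...) {
  pk <- vapply(x$templates, function(m) max(abs(m)), numeric(1))
  cat(sprintf("<ei_set> %d neurons on %d electrodes, peak |EI| %.1f-%.1f uV\n",
              length(x$templates), x$E, min(pk), max(pk)))
  invisible(x)
}

#' Peak EI strength per neuron
#' @param eis an [ei_set()].
#' @return maximum absolute template voltage (uV) per neuron.
#' @export
ei_peak_strength <- function(eis) {
  vapply(eis$templates, function(m) max(abs(m)), numeric(1))
}
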