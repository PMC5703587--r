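#' Containers on disk
#'
#' Trace series and EI sets are stored with R's native serialization
#' (schema-validated plain lists); hyperparameters and run manifests as
#' JSON; spike tables and activation curves as CSV. Reads validate the
#' schema and name any missing field.
#'
#' @name io
NULL

.require_fields <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop(sprintf("%s is missing required field(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(x)
}

#' Write / read a trace series
#'
#' @param x a [trace_series()].
#' @param path file path.
#' @return `read_traces` returns a [trace_series()]; `write_traces`
#'   returns `path` invisibly. Round-trips are lossless.
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_series"))
  obj <- list(Y = x$Y, amplitudes = x$amplitudes,
              sampling_rate_hz = x$sampling_rate_hz,
              stim_electrodes = x$stim_electrode,
              breakpoints = x$breakpoints, positions = x$positions,
              layout = if (is.null(x$layout)) NULL else
                x$layout[c("rows", "cols", "pitch")])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  obj <- readRDS(path)
  .require_fields(obj, c("Y", "amplitudes", "sampling_rate_hz",
                         "stim_electrodes", "breakpoints", "positions"),
                  "trace container")
  layout <- NULL
  if (!is.null(obj$layout))
    layout <- make_layout(obj$layout$rows, obj$layout$cols,
                          obj$layout$pitch)
  trace_series(obj$Y, obj$amplitudes, obj$sampling_rate_hz,
               obj$positions, obj$stim_electrodes[1],
               breakpoints = obj$breakpoints, layout = layout)
}

#' Write / read an EI set
#'
#' @param x an [ei_set()].
#' @param path file path.
#' @return `read_eis` returns an [ei_set()].
#' @export
write_eis <- function(x, path) {
  stopifnot(inherits(x, "ei_set"))
  saveRDS(list(templates = x$templates, neuron_ids = x$neuron_ids), path)
  invisible(path)
}

#' @rdname write_eis
#' @export
read_eis <- function(path) {
  obj <- readRDS(path)
  .require_fields(obj, c("templates", "neuron_ids"), "EI container")
  ei_set(obj$templates, obj$neuron_ids)
}

.axis_to_list <- function(p) list(lam = p$lam, alpha = p$alpha,
                                  beta = p$beta)

#' Write / read fitted hyperparameters as JSON
#'
#' Serializes a `series_model` (or a bare `nonstim`/`stim`/`noise` list):
#' per-axis `{lam, alpha, beta}`, the scales `rho`, the jitters, noise
#' estimates, and one stimulating-electrode entry per breakpoint range
#' keyed by its amplitude interval.
#'
#' @param model a `series_model` (the centered traces, if present, are
#'   not serialized).
#' @param path JSON file path.
#' @return `read_hyperparams` returns a list usable as the `model`
#'   argument of [run_amplitude_series()].
#' @export
write_hyperparams <- function(model, path) {
  ns <- model$nonstim
  doc <- list(
    nonstim = list(rho = ns$rho, phi2 = ns$phi2, nll = ns$nll,
                   time = .axis_to_list(ns$params$time),
                   electrode = .axis_to_list(ns$params$electrode),
                   stimulus = .axis_to_list(ns$params$stimulus)),
    noise = unclass(model$noise))
  if (!is.null(model$stim)) {
    st <- model$stim
    bounds <- c(-Inf, st$breakpoints, Inf)
    ranges <- lapply(seq_along(st$ranges), function(r) {
      x <- st$ranges[[r]]
      list(interval = sprintf("(%g, %g]", bounds[r], bounds[r + 1]),
           rho = x$rho, time = .axis_to_list(x$time),
           stimulus = .axis_to_list(x$stimulus),
           scale_profile = x$scale_profile)
    })
    doc$stim <- list(phi2 = st$phi2, breakpoints = st$breakpoints,
                     amplitudes = st$amplitudes, ranges = ranges)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.axis_from_list <- function(l) axis_params(l$lam, l$alpha, l$beta)

#' @rdname write_hyperparams
#' @export
read_hyperparams <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  .require_fields(doc, c("nonstim", "noise"), "hyperparameter document")
  ns <- doc$nonstim
  nonstim <- structure(
    list(kind = "nonstim",
         params = list(time = .axis_from_list(ns$time),
                       electrode = .axis_from_list(ns$electrode),
                       stimulus = .axis_from_list(ns$stimulus)),
         rho = ns$rho, phi2 = ns$phi2, nll = ns$nll),
    class = "artifact_hyperparams")
  stim <- NULL
  if (!is.null(doc$stim)) {
    st <- doc$stim
    amps <- st$amplitudes
    rid <- findInterval(amps, sort(st$breakpoints)) + 1L
    ranges <- lapply(seq_len(nrow(st$ranges)), function(r)
      list(time = .axis_from_list(as.list(st$ranges$time[r, ])),
           stimulus = .axis_from_list(as.list(st$ranges$stimulus[r, ])),
           rho = st$ranges$rho[r],
           scale_profile = unlist(st$ranges$scale_profile[r]),
           idx = which(rid == r)))
    stim <- structure(list(ranges = ranges,
                           breakpoints = st$breakpoints,
                           amplitudes = amps, phi2 = st$phi2),
                      class = "stim_hyperparams")
  }
  structure(list(nonstim = nonstim, stim = stim,
                 noise = do.call(noise_estimates, as.list(doc$noise))),
            class = "series_model")
}

#' Write a spike table as CSV
#'
#' Fixed column order: `stim_electrode`, `amplitude_index`,
#' `amplitude_uA`, `trial`, `neuron_id`, `onset_sample`, `latency_ms`.
#'
#' @param fit a `series_fit`.
#' @param stim_electrode the stimulating electrode index recorded in the
#'   table.
#' @param path CSV file path.
#' @export
write_spikes <- function(fit, stim_electrode, path) {
  s <- fit$spikes
  out <- data.frame(stim_electrode = rep(stim_electrode, nrow(s)),
                    s[, c("amplitude_index", "amplitude_uA", "trial",
                          "neuron_id", "onset_sample", "latency_ms")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write activation curves as CSV
#'
#' @param curves list from [activation_curves()].
#' @param path CSV file path.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(names(curves), function(n) {
    cv <- curves[[n]]
    data.frame(neuron_id = n, mu_a = cv$mu_a, s_a = cv$s_a,
               activated = cv$activated, threshold_uA = cv$threshold_uA,
               degenerate = cv$degenerate)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration snapshot, seeds, package
#' version, input-file hashes and warnings, so that reruns with an
#' identical manifest reproduce the outputs.
#'
#' @param path JSON file path.
#' @param command the command or function being recorded.
#' @param config configuration list.
#' @param seed integer seed(s) in effect.
#' @param inputs named character vector of input file paths (hashed with
#'   md5).
#' @param warnings character vector of warnings raised.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL,
                           inputs = character(0), warnings = NULL) {
  plain <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), plain))
    x
  }
  config <- plain(config)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  doc <- list(command = command,
              package_version = as.character(utils::packageVersion("artsort")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config, input_md5 = hashes,
              warnings = warnings)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
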