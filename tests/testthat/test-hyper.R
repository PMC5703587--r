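make_tiny_series <- function(Y1, Y2, amplitudes = c(0.5, 1)) {
  # two electrodes, two samples; Y arrays are (T, E, n)
  trace_series(list(Y1, Y2), amplitudes = amplitudes,
               sampling_rate_hz = 20000,
               positions = cbind(c(0, 60), c(0, 0)),
               stim_electrode = 1L)
}

test_that("switching-mean subtraction matches hand arithmetic and round-trips", {
  # lowest-amplitude trials {1, 3} -> mean 2; other amplitude single trial 10
  Y1 <- array(c(1, 1, 1, 1, 3, 3, 3, 3), dim = c(2, 2, 2))
  Y2 <- array(10, dim = c(2, 2, 1))
  ts <- make_tiny_series(Y1, Y2)
  cs <- subtract_switching_mean(ts)
  expect_equal(cs$switching_mean, matrix(2, 2, 2))
  expect_equal(as.vector(cs$traces$Y[[1]][, , 1]), rep(-1, 4))
  expect_equal(as.vector(cs$traces$Y[[1]][, , 2]), rep(1, 4))
  expect_equal(as.vector(cs$traces$Y[[2]]), rep(8, 4))
  expect_equal(add_switching_mean(cs), ts)
  # constant traces center to exactly zero
  tsc <- make_tiny_series(array(7, c(2, 2, 3)), array(7, c(2, 2, 2)))
  csc <- subtract_switching_mean(tsc)
  expect_true(all(unlist(csc$traces$Y) == 0))
  expect_equal(csc$switching_mean, matrix(7, 2, 2))
})

test_that("stimulating-electrode proxy takes trial mean or median", {
  Y1 <- array(0, dim = c(1, 2, 3)); Y1[1, 1, ] <- c(1, 2, 3)
  Y2 <- array(0, dim = c(1, 2, 3)); Y2[1, 1, ] <- c(1, 2, 30)
  ts <- make_tiny_series(Y1, Y2)
  centered <- list(traces = ts, switching_mean = matrix(0, 1, 2))
  class(centered) <- "centered_traces"
  pm <- build_proxy_stim(centered, "mean")
  expect_equal(as.vector(pm$values), c(2, 11))
  pmed <- build_proxy_stim(centered, "median")
  expect_equal(as.vector(pmed$values), c(2, 2))
  # single trial: the proxy is that trial
  ts1 <- make_tiny_series(array(c(5, 0), c(1, 2, 1)),
                          array(c(9, 0), c(1, 2, 1)))
  c1 <- structure(list(traces = ts1, switching_mean = matrix(0, 1, 2)),
                  class = "centered_traces")
  expect_equal(as.vector(build_proxy_stim(c1)$values), c(5, 9))
})

test_that("non-stimulating proxy pools translated datasets", {
  cfg <- tiny_sim_config()
  ds <- simulate_series(cfg, seed = 21)
  centered <- subtract_switching_mean(ds$traces)
  # single dataset: proxy equals the trial means on the kept electrodes
  proxy <- build_proxy_nonstim(list(centered), ds$layout, keep_frac = 0.5)
  tm <- vapply(centered$traces$Y, function(y) apply(y, c(1, 2), mean),
               matrix(0, cfg$n_samples, 16))
  expect_equal(proxy$values, tm[, proxy$kept_electrodes, ],
               tolerance = 1e-12)
  expect_false(ds$layout$center %in% proxy$kept_electrodes)
  expect_true(all(diff(sort(proxy$distances)) >= 0))
  # two datasets whose traces are v and -v cancel
  flipped <- centered
  flipped$traces$Y <- lapply(centered$traces$Y, function(y) -y)
  p2 <- build_proxy_nonstim(list(centered, flipped), ds$layout)
  expect_equal(max(abs(p2$values)), 0)
})

test_that("pooling across stimulating electrodes averages out spikes", {
  # shared artifact plus dataset-specific spike contamination: the pooled
  # proxy is closer to the true artifact than any single-dataset mean
  layout <- make_layout(4, 4, 60)
  Tn <- 20; E <- 16; J <- 3
  set.seed(31)
  A <- array(rnorm(Tn * E * J, sd = 10), dim = c(Tn, E, J))
  A[, , 1] <- 0   # lowest amplitude carries no artifact -> centering no-op
  mk_dataset <- function(seed) {
    set.seed(seed)
    Y <- lapply(1:J, function(j) {
      y <- array(A[, , j], dim = c(Tn, E, 2))
      # dataset-specific "spikes": large deflections on a few electrodes
      es <- sample(E, 3)
      for (e in es) y[sample(Tn, 4), e, ] <- y[sample(Tn, 4), e, ] + 80
      y + array(rnorm(length(y), sd = 1), dim = dim(y))
    })
    ts <- trace_series(Y, amplitudes = 1:J, sampling_rate_hz = 20000,
                       positions = layout$positions,
                       stim_electrode = layout$center, layout = layout)
    structure(list(traces = ts, switching_mean = matrix(0, Tn, E)),
              class = "centered_traces")
  }
  datasets <- lapply(41:46, mk_dataset)
  pooled <- build_proxy_nonstim(datasets, layout, keep_frac = 0.9)
  kept <- pooled$kept_electrodes
  rmse <- function(p) sqrt(mean((p$values - A[, p$kept_electrodes, ])^2))
  singles <- vapply(datasets, function(d)
    rmse(build_proxy_nonstim(list(d), layout, keep_frac = 0.9)),
    numeric(1))
  expect_lt(rmse(pooled), min(singles))
})

test_that("phi2 background estimate ignores early-time artifact", {
  tms <- (1:40) / 20
  amps <- c(1, 2)
  vals <- array(0, dim = c(40, 8, 2))
  proxy <- structure(list(values = vals, kind = "nonstim", time_ms = tms,
                          amplitudes = amps,
                          distances = seq(60, 480, by = 60)),
                     class = "proxy_artifact")
  expect_equal(estimate_phi2(proxy), 0)
  # big early-time artifact leaves the background window untouched
  set.seed(8)
  vals[1:10, , ] <- 500
  vals[31:40, 7:8, 1] <- rnorm(20, sd = 2)
  proxy$values <- vals
  expect_equal(estimate_phi2(proxy), var(as.vector(vals[31:40, 7:8, 1])))
  # i.i.d. background recovers the variance within 20%
  big <- structure(list(values = array(rnorm(40 * 40 * 2, sd = 2),
                                       dim = c(40, 40, 2)),
                        kind = "nonstim", time_ms = tms, amplitudes = amps,
                        distances = seq_len(40) * 30),
                   class = "proxy_artifact")
  expect_equal(estimate_phi2(big), 4, tolerance = 0.2)
})

test_that("sigma2 is the across-trial variance on distant electrodes", {
  set.seed(9)
  E <- 50; Tn <- 20; n <- 20
  Y1 <- array(rnorm(Tn * E * n, sd = 6), dim = c(Tn, E, n))
  common <- matrix(rnorm(Tn * E, sd = 30), Tn, E)  # common artifact
  Y1c <- Y1 + as.vector(common)
  pos <- cbind(runif(E, 0, 600), runif(E, 0, 600))
  ts <- trace_series(list(Y1, Y1), amplitudes = c(1, 2),
                     sampling_rate_hz = 20000, positions = pos,
                     stim_electrode = 1L)
  cs <- structure(list(traces = ts, switching_mean = matrix(0, Tn, E)),
                  class = "centered_traces")
  est <- estimate_sigma2(cs)
  expect_equal(est, 36, tolerance = 0.15)
  # adding a common artifact to all trials leaves the estimate unchanged
  tsc <- ts; tsc$Y <- list(Y1c, Y1c)
  csc <- structure(list(traces = tsc, switching_mean = matrix(0, Tn, E)),
                   class = "centered_traces")
  expect_equal(estimate_sigma2(csc), est)
  # identical trials have zero variance
  ts0 <- ts; ts0$Y <- list(array(rep(common, 3), dim = c(Tn, E, 3)), Y1)
  cs0 <- structure(list(traces = ts0, switching_mean = matrix(0, Tn, E)),
                   class = "centered_traces")
  expect_equal(estimate_sigma2(cs0), 0)
  ts1 <- ts; ts1$Y <- list(Y1[, , 1, drop = FALSE], Y1)
  cs1 <- structure(list(traces = ts1, switching_mean = matrix(0, Tn, E)),
                   class = "centered_traces")
  expect_error(estimate_sigma2(cs1), "two trials")
})

test_that("neg_log_marglik matches closed forms and the dense Gaussian", {
  # zero data, identity covariance: both terms vanish
  kI <- kron_kernel(list(diag(2), diag(3)), rho = 0, phi2 = 1)
  expect_equal(neg_log_marglik(rep(0, 6), kI), 0)
  # scalar case a^2 / (2k) + log(k) / 2
  ks <- kron_kernel(list(matrix(1)), rho = 0, phi2 = 2.5)
  expect_equal(neg_log_marglik(3, ks), 9 / (2 * 2.5) + log(2.5) / 2)
  set.seed(10)
  for (i in 1:10) {
    k <- random_kron_kernel(sample(2:3, 1), dim_cap = 200)
    n <- prod(k$dims)
    v <- rnorm(n)
    Kd <- dense_kron(k) + diag(k$phi2, n)
    ref <- 0.5 * sum(v * solve(Kd, v)) +
      0.5 * determinant(Kd)$modulus[1]
    expect_equal(neg_log_marglik(v, k), ref, tolerance = 1e-8)
  }
})

test_that("hyperparameter fitting recovers scales and respects the init contract", {
  # proxy sampled from known hyperparameters on a small grid
  set.seed(12)
  tms <- (1:12) / 10
  coords <- as.matrix(expand.grid(x = (0:2) * 60, y = (0:1) * 60))
  dstim <- sqrt(rowSums(sweep(coords, 2, c(60, 0))^2)) + 30
  amps <- seq(0.5, 3, length.out = 4)
  true <- list(time = axis_params(2, 1, 2),
               electrode = axis_params(0.008, 0, 0.004),
               stimulus = axis_params(0.5))
  kt <- assemble_nonstim_kernel(
    axis_grid(tms), axis_grid(coords, envelope = dstim),
    axis_grid(amps, envelope = rep(0, 4)), true, rho = 400, phi2 = 1)
  vals <- kron_sample(kron_op(kt), seed = 13)
  proxy <- structure(list(values = vals, kind = "nonstim", time_ms = tms,
                          amplitudes = amps, coords = coords,
                          distances = dstim),
                     class = "proxy_artifact")
  fit <- suppressWarnings(
    fit_hyperparameters(proxy, phi2 = 1, n_starts = 3, seed = 1,
                        maxit = 60))
  expect_lte(fit$nll, neg_log_marglik(vals, kt) + 1e-6)
  # bounds respected
  b <- c(1e-3, 1e3)
  for (ax in c("time", "electrode", "stimulus"))
    expect_true(fit$params[[ax]]$lam >= b[1] && fit$params[[ax]]$lam <= b[2])
  expect_true(fit$params$time$alpha >= 0 && fit$params$time$alpha <= 20)
  # re-fitting from the fit itself cannot do worse (fixed-point contract)
  fit2 <- suppressWarnings(
    fit_hyperparameters(proxy, phi2 = 1, init = fit, n_starts = 1,
                        seed = 1, maxit = 30))
  expect_lte(fit2$nll, fit$nll + 1e-8)
})

test_that("doubling the proxy amplitude raises rho, not the length-scales", {
  set.seed(14)
  tms <- (1:10) / 10
  coords <- as.matrix(expand.grid(x = (0:2) * 60, y = (0:1) * 60))
  dstim <- sqrt(rowSums(sweep(coords, 2, c(60, 0))^2)) + 30
  amps <- c(1, 2, 3)
  true <- list(time = axis_params(2, 1, 2),
               electrode = axis_params(0.008, 0, 0.004),
               stimulus = axis_params(0.5))
  kt <- assemble_nonstim_kernel(
    axis_grid(tms), axis_grid(coords, envelope = dstim),
    axis_grid(amps, envelope = rep(0, 3)), true, rho = 200, phi2 = 0.5)
  vals <- kron_sample(kron_op(kt), seed = 15)
  mk <- function(v) structure(
    list(values = v, kind = "nonstim", time_ms = tms, amplitudes = amps,
         coords = coords, distances = dstim), class = "proxy_artifact")
  f1 <- suppressWarnings(fit_hyperparameters(mk(vals), phi2 = 0.5,
                                             n_starts = 2, seed = 2,
                                             maxit = 60))
  # doubling the data doubles the background too, so phi2 re-estimates to
  # 4x; the Gaussian likelihood is then exactly scale-equivariant and the
  # fit should move rho up (by ~4) while leaving the length-scales alone
  f2 <- suppressWarnings(fit_hyperparameters(mk(2 * vals), phi2 = 2,
                                             n_starts = 2, seed = 2,
                                             maxit = 60))
  expect_gt(f2$rho, f1$rho)
  expect_equal(f2$rho / f1$rho, 4, tolerance = 0.4)
  expect_lt(abs(log(f2$params$time$lam / f1$params$time$lam)), log(1.5))
  expect_lt(abs(log(f2$params$electrode$lam / f1$params$electrode$lam)),
            log(1.5))
})

test_that("stimulating-electrode hyperparameters are fitted per range", {
  set.seed(16)
  tms <- (1:15) / 10
  amps <- 1:6
  mkk <- function(lam_t, rho, idx) {
    kron_kernel(list(build_axis_kernel(axis_grid(tms),
                                       axis_params(lam_t, 1, 2)),
                     build_axis_kernel(axis_grid(amps[idx],
                                                 rep(1, length(idx))),
                                       axis_params(0.5))),
                rho = rho, phi2 = 0.5)
  }
  v1 <- kron_sample(kron_op(mkk(2, 900, 1:3)), seed = 17)
  v2 <- kron_sample(kron_op(mkk(2, 2500, 4:6)), seed = 18)
  proxy <- structure(list(values = cbind(v1, v2), kind = "stim",
                          time_ms = tms, amplitudes = amps),
                     class = "proxy_artifact")
  st <- suppressWarnings(
    fit_stim_hyperparameters(proxy, breakpoints = 3.5, phi2 = 0.5,
                             n_starts = 2, seed = 3, maxit = 50))
  expect_length(st$ranges, 2)
  expect_equal(st$ranges[[1]]$idx, 1:3)
  expect_equal(st$ranges[[2]]$idx, 4:6)
  # each range's fitted marginal variance tracks the realized scale of
  # its own data (single GP draws are too correlated for the generating
  # rho itself to be identifiable)
  fitted_var <- function(r) {
    Kt <- build_axis_kernel(axis_grid(tms), st$ranges[[r]]$time)
    Ks <- build_axis_kernel(axis_grid(amps[st$ranges[[r]]$idx],
                                      envelope = amps[st$ranges[[r]]$idx]),
                            st$ranges[[r]]$stimulus)
    st$ranges[[r]]$rho * mean(diag(Kt)) * mean(diag(Ks))
  }
  expect_lt(abs(log(fitted_var(1) / mean(v1^2))), log(5))
  expect_lt(abs(log(fitted_var(2) / mean(v2^2))), log(5))
})
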