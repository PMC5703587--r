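tiny_bank <- function(n_samples = 30, threshold = 30, peaks = c(120, 90)) {
  cfg <- tiny_sim_config()
  cfg$roster$ei_peak <- peaks
  layout <- make_layout(cfg$rows, cfg$cols, cfg$pitch)
  eis <- make_eis(layout, cfg$roster, cfg$sampling_rate_hz)
  make_template_bank(eis, n_samples, cfg$sampling_rate_hz,
                     strength_threshold = threshold)
}

test_that("template bank enumerates onsets and enforces the strength threshold", {
  # at T = 40 no truncation reaches the spike peak: the full 0.25-1.5 ms
  # window at 20 kHz gives onsets 5..30, 26 rows per neuron
  bank40 <- tiny_bank(n_samples = 40)
  expect_equal(bank40$onsets, 5:30)
  expect_equal(nrow(bank40$rows), 2 * 26)
  # at T = 30 the last onsets lose the spike peak to truncation and are
  # dropped by the same strength rule that filters weak neurons
  bank <- tiny_bank(n_samples = 30)
  expect_lt(nrow(bank$rows), 2 * 26)
  expect_true(all(vapply(seq_len(nrow(bank$rows)), function(k)
    max(abs(bank$rows[k, ])), numeric(1)) >= 30))
  expect_true(all(5:26 %in% bank$onset[bank$neuron == 1]))
  # row structure: onset o at electrode e carries EI(k, e) at time o + k - 1
  cfg <- tiny_sim_config()
  layout <- make_layout(4, 4, 60)
  eis <- make_eis(layout, cfg$roster, 20000)
  row <- bank$rows[bank$neuron == 1 & bank$onset == 7, ]
  m <- matrix(row, 30, 16)
  expect_equal(m[7:26, ], eis$templates[[1]][1:20, ])
  expect_true(all(m[1:6, ] == 0))
  # truncation at the trace end: norms computed on the in-range part
  row15 <- bank$rows[bank$neuron == 1 & bank$onset == 15, ]
  m15 <- matrix(row15, 30, 16)
  expect_equal(m15[15:30, ], eis$templates[[1]][1:16, ])
  expect_equal(sum(row15^2), sum(eis$templates[[1]][1:16, ]^2))
  # weak neuron excluded and reported
  bank_w <- tiny_bank(peaks = c(120, 10))
  expect_equal(bank_w$retained, 1L)
  expect_equal(bank_w$excluded, 2L)
  expect_error(tiny_bank(peaks = c(10, 10)), "no neuron")
})

test_that("matching pursuit recovers planted templates and stays silent on zeros", {
  bank <- tiny_bank()
  zero <- matrix(0, 30, 16)
  expect_equal(nrow(matching_pursuit(zero, bank)$spikes), 0)
  # exact copy of a bank row is recovered with zero residual
  for (row_id in c(3L, nrow(bank$rows) %/% 2L, nrow(bank$rows))) {
    r <- matrix(bank$rows[row_id, ], 30, 16)
    out <- matching_pursuit(r, bank)
    expect_equal(out$spikes$neuron, bank$neuron[row_id])
    expect_equal(out$spikes$onset, bank$onset[row_id])
    expect_lt(max(abs(out$residual)), 1e-10)
  }
  # two planted neurons at distinct onsets
  r1_id <- which(bank$neuron == 1 & bank$onset == 14)
  r2_id <- which(bank$neuron == 2 & bank$onset == 24)
  r2 <- matrix(bank$rows[r1_id, ] + bank$rows[r2_id, ], 30, 16)
  out2 <- matching_pursuit(r2, bank)
  expect_equal(nrow(out2$spikes), 2)
  expect_lt(max(abs(out2$residual)), 1e-10)
})

test_that("greedy matching pursuit equals exhaustive search for one neuron", {
  cfg <- tiny_sim_config()
  cfg$roster <- cfg$roster[1, , drop = FALSE]
  layout <- make_layout(4, 4, 60)
  eis <- make_eis(layout, cfg$roster, 20000)
  bank <- make_template_bank(eis, 30, 20000)
  set.seed(20)
  for (i in 1:120) {
    r <- matrix(rnorm(480, sd = 40), 30, 16)
    out <- matching_pursuit(r, bank)
    # exhaustive search over {none} and every onset
    obj_none <- sum(r^2)
    objs <- vapply(seq_len(nrow(bank$rows)), function(k)
      sum((as.vector(r) - bank$rows[k, ])^2), numeric(1))
    if (min(objs) < obj_none) {
      expect_equal(nrow(out$spikes), 1)
      expect_equal(out$spikes$onset, bank$onset[which.min(objs)])
      expect_equal(sum(out$residual^2), min(objs))
    } else {
      expect_equal(nrow(out$spikes), 0)
    }
  }
})

test_that("residual norm is non-increasing across accepted spikes", {
  bank <- tiny_bank()
  set.seed(22)
  for (i in 1:20) {
    r0 <- matrix(rnorm(480, sd = 30), 30, 16) +
      matrix(bank$rows[sample(nrow(bank$rows), 1), ], 30, 16)
    out <- matching_pursuit(r0, bank)
    expect_lte(sum(out$residual^2), sum(r0^2) + 1e-9)
  }
})

test_that("electrode exclusion removes those samples from the likelihood", {
  bank <- tiny_bank()
  # energy only on the excluded electrode: no detection possible
  e <- 6L
  r <- matrix(0, 30, 16)
  r[, e] <- matrix(bank$rows[8, ], 30, 16)[, e]
  out <- matching_pursuit(r, bank, exclude_electrodes = e)
  expect_equal(nrow(out$spikes), 0)
})

test_that("filter_artifact is exact at zero noise and shrinks eigencomponents", {
  set.seed(23)
  Kt <- build_axis_kernel(random_axis(6), random_axis_params())
  Ke <- build_axis_kernel(random_axis(5), random_axis_params())
  kj <- kron_kernel(list(Kt, Ke), rho = 2, phi2 = 0)
  x <- matrix(rnorm(30), 6, 5)
  # sigma2 / n + phi2 = 0: identity
  expect_identical(filter_artifact(x, kj, sigma2 = 0, n_j = 10, phi2 = 0), x)
  # eigenvector input scaled by kappa / (kappa + c)
  et <- eigen(Kt, symmetric = TRUE)
  ee <- eigen(Ke, symmetric = TRUE)
  v <- outer(et$vectors[, 1], ee$vectors[, 1])
  kap <- 2 * et$values[1] * ee$values[1]
  c_ <- 36 / 20 + 0.5
  out <- filter_artifact(v, kj, sigma2 = 36, n_j = 20, phi2 = 0.5)
  expect_equal(out, v * kap / (kap + c_), tolerance = 1e-10)
  # dense posterior-mean formula
  Kd <- 2 * (Ke %x% Kt)
  ref <- Kd %*% solve(Kd + diag(c_, 30), as.vector(x))
  expect_equal(as.vector(out * 0 +
                           filter_artifact(x, kj, 36, 20, 0.5)),
               as.vector(ref), tolerance = 1e-8)
})

test_that("extrapolation matches dense conditioning and its limits", {
  set.seed(24)
  Kt <- build_axis_kernel(random_axis(4), random_axis_params())
  Ke <- build_axis_kernel(random_axis(3), random_axis_params())
  # perfect correlation across amplitudes, no jitter: constant in, constant out
  Ks1 <- matrix(1, 4, 4)
  k1 <- kron_kernel(list(Kt, Ke, Ks1), rho = 1, phi2 = 0)
  a <- outer(rnorm(4), rnorm(3))
  A3 <- array(rep(a, 3), dim = c(4, 3, 3))
  pred <- extrapolate_artifact(A3, k1, 1:3, 4, phi2 = 0)
  expect_equal(pred[, , 1], a, tolerance = 1e-6)
  # diagonal stimulus kernel: prediction falls back to the prior mean 0
  kd <- kron_kernel(list(Kt, Ke, diag(4)), rho = 1, phi2 = 0)
  expect_equal(as.vector(extrapolate_artifact(A3, kd, 1:3, 4, 0.1)),
               rep(0, 12))
  # dense oracle
  Ks <- build_axis_kernel(random_axis(4), random_axis_params())
  k <- kron_kernel(list(Kt, Ke, Ks), rho = 1.5, phi2 = 0)
  A <- array(rnorm(36), dim = c(4, 3, 3))
  pred <- extrapolate_artifact(A, k, 1:3, 4, phi2 = 0.3)
  Kd <- dense_kron(k)
  io <- 1:36; it <- 37:48
  ref <- Kd[it, io] %*% solve(Kd[io, io] + diag(0.3, 36), as.vector(A))
  expect_equal(as.vector(pred), as.vector(ref), tolerance = 1e-8)
})

test_that("coordinate ascent on zero traces returns zero artifact in one sweep", {
  bank <- tiny_bank()
  Yj <- array(0, dim = c(30, 16, 4))
  kj <- kron_kernel(list(diag(30), diag(16)), rho = 1, phi2 = 0.1)
  out <- coordinate_ascent(Yj, matrix(0, 30, 16), bank, sigma2 = 1,
                           kernel_j = kj, phi2 = 0.1)
  expect_equal(out$sweeps, 1L)
  expect_true(out$converged)
  expect_equal(nrow(out$spikes), 0)
  expect_equal(max(abs(out$A)), 0)
})

test_that("coordinate ascent recovers planted spikes and a smooth artifact", {
  cfg <- tiny_sim_config(sigma = 1)
  ds <- simulate_series(cfg, seed = 25)
  model <- oracle_model(ds)
  j <- 5L   # high amplitude: both neurons reliably active
  centered <- subtract_switching_mean(ds$traces)
  Yj <- centered$traces$Y[[j]]
  bank <- make_template_bank(ds$eis, cfg$n_samples, cfg$sampling_rate_hz)
  kernels <- artsort:::.series_kernels(ds$traces, model)
  kj <- fixed_j_kernel(kernels$nonstim, j)
  truth_j <- ds$truth$spikes[ds$truth$spikes$amplitude_index == j, ]
  A0 <- matrix(0, cfg$n_samples, 16)
  out <- coordinate_ascent(Yj, A0, bank, sigma2 = 1, kernel_j = kj,
                           kernel_electrodes = kernels$e_nonstim,
                           phi2 = model$nonstim$phi2)
  got <- out$spikes[order(out$spikes$trial, out$spikes$neuron), ]
  want <- truth_j[order(truth_j$trial, truth_j$neuron_id), ]
  expect_equal(got$trial, want$trial)
  expect_equal(got$neuron, want$neuron_id)
  expect_equal(got$onset, want$onset_sample)
  # artifact error comparable to the trial-mean noise level sigma / sqrt(n)
  swm <- apply(ds$traces$Y[[1]], c(1, 2), mean)
  err <- out$A[, kernels$e_nonstim] + swm[, kernels$e_nonstim] -
    ds$truth$artifact[, kernels$e_nonstim, j]
  expect_lt(sqrt(mean(err^2)), 3 * 1 / sqrt(dim(Yj)[3]) + 1.5)
})

test_that("noise-free artifact-free data reduces to exact template matching", {
  cfg <- tiny_sim_config(sigma = 0, artifact_sd_peak = 0,
                         stim_artifact_sd_peak = 0, phi_true = 0)
  ds <- simulate_series(cfg, seed = 26)
  fit <- run_simplified(ds$traces, ds$eis)
  sc <- score_spikes(fit$spikes, ds$truth$spikes, n_trials(ds$traces),
                     nrow(cfg$roster))
  expect_equal(sc$FP + sc$FN, 0)
})

test_that("full and simplified methods agree on noise-free high-trial data", {
  cfg <- tiny_sim_config(sigma = 0, phi_true = 0, n_j = 12)
  ds <- simulate_series(cfg, seed = 27)
  model <- oracle_model(ds)
  f_full <- run_amplitude_series(ds$traces, model, ds$eis)
  f_simp <- run_simplified(ds$traces, ds$eis)
  cols <- c("amplitude_index", "trial", "neuron_id", "onset_sample")
  expect_equal(f_full$spikes[, cols], f_simp$spikes[, cols],
               ignore_attr = TRUE)
  # and both recover the planted truth exactly in this limit
  sc <- score_spikes(f_full$spikes, ds$truth$spikes, n_trials(ds$traces),
                     nrow(cfg$roster))
  expect_equal(sc$FP + sc$FN, 0)
})

test_that("run_amplitude_series outputs are reproducible and well-formed", {
  cfg <- tiny_sim_config()
  ds <- simulate_series(cfg, seed = 28)
  model <- oracle_model(ds)
  f1 <- run_amplitude_series(ds$traces, model, ds$eis)
  f2 <- run_amplitude_series(ds$traces, model, ds$eis)
  expect_identical(f1$spikes, f2$spikes)
  expect_identical(f1$artifact, f2$artifact)
  expect_equal(dim(f1$artifact), c(30, 16, 6))
  expect_true(all(f1$spikes$onset_sample >= 5 &
                    f1$spikes$onset_sample <= 30))
  expect_true(all(f1$spikes$latency_ms ==
                    f1$spikes$onset_sample * 1000 / 20000))
  # EI / trace electrode mismatch caught before inference
  bad_eis <- ei_set(list(matrix(40, 10, 5)))
  expect_error(run_amplitude_series(ds$traces, model, bad_eis),
               "electrode count")
})

test_that("trial budget freezes the artifact and preserves agreement", {
  cfg <- tiny_sim_config()
  ds <- simulate_series(cfg, seed = 29)
  model <- oracle_model(ds)
  full <- run_amplitude_series(ds$traces, model, ds$eis)
  # budget = n_j is identical to the unbudgeted run
  same <- apply_trial_budget(ds$traces, model, ds$eis, budget_n = cfg$n_j)
  expect_identical(full$spikes, same$spikes)
  # a modest budget keeps spike agreement high
  bud <- apply_trial_budget(ds$traces, model, ds$eis, budget_n = 3)
  key <- function(s) paste(s$amplitude_index, s$trial, s$neuron_id,
                           s$onset_sample)
  agree <- length(intersect(key(full$spikes), key(bud$spikes))) /
    max(nrow(full$spikes), 1)
  expect_gte(agree, 0.95)
  # budget 1 degrades gracefully and is flagged
  b1 <- apply_trial_budget(ds$traces, model, ds$eis, budget_n = 1)
  expect_true(any(grepl("budget", b1$warnings)))
})

test_that("breakpoint restart zeroes the stimulating electrode initialization", {
  cfg <- tiny_sim_config(amplitudes = seq(0.5, 3, length.out = 6),
                         breakpoints = 1.8)
  ds <- simulate_series(cfg, seed = 30)
  model <- oracle_model(ds)
  fit <- run_amplitude_series(ds$traces, model, ds$eis)
  expect_equal(length(fit$sweeps), 6)
  expect_true(is.numeric(fit$artifact))
  # the restart index is the first amplitude past the breakpoint
  expect_equal(artsort:::.range_starts_after_break(cfg$amplitudes, 1.8), 4L)
})
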