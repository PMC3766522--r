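test_that("build_structure inverts the pairwise-correlation relation", {
  sp <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20, rate = 5)
  st <- build_structure(sp)
  expect_equal(st[20], 0.05 * 5 * 100 * 99 / (20 * 19), tolerance = 1e-12)
  expect_equal(st[20], 6.513158, tolerance = 1e-6)
  expect_equal(st[1], 1000 * 5 - 20 * st[20])
  expect_equal(max_order(st), 20L)

  # independent population
  st0 <- build_structure(population_spec(N = 300, rate = 4))
  expect_equal(as.numeric(st0), 1200)
  expect_equal(max_order(st0), 1L)

  # minimal pair case
  st2 <- build_structure(population_spec(N = 2, N_c = 2, c = 0.01,
                                         order = 2, rate = 10))
  expect_equal(st2[2], 0.1)
  expect_equal(st2[1], 19.8)

  # infeasible: correlation stronger than the rate budget allows
  expect_error(build_structure(population_spec(N = 10, N_c = 10, c = 0.9,
                                               order = 2, rate = 1)),
               "too strong")
})

test_that("spec validation rejects inconsistent populations", {
  expect_error(population_spec(N = 10, N_c = 20, c = 0.1, order = 2,
                               rate = 1))
  expect_error(population_spec(N = 10, N_c = 5, c = 0.1, order = 6,
                               rate = 1), "order")
  expect_error(population_spec(N = 10, c = 1, rate = 1), "0, 1")
  expect_error(correlation_structure(c(0, 0)), "positive")
  expect_error(correlation_structure(c(-1, 2)), "nonnegative")
})

test_that("binomial-shaped structure keeps the rate and correlation", {
  N <- 200; c <- 0.01; lam <- 10
  st <- build_structure_binomial(N, N, c, lam)
  # every neuron's marginal rate: sum n nu_n = N lambda
  expect_equal(sum(seq_along(st) * as.numeric(st)), N * lam,
               tolerance = 1e-9)
  # implied pairwise correlation equals c exactly
  ker <- exp_kernel(1, 0.01)
  c_hat <- pairwise_c_from_cumulants(theoretical_cumulant(st, ker, 1),
                                     theoretical_cumulant(st, ker, 2),
                                     ker, N = N, N_c = N)
  expect_equal(c_hat, c, tolerance = 1e-12)
})

test_that("simulated CPP counts have the theoretical moments", {
  set.seed(601)
  # pure independent: total count is Poisson(nu1 * T)
  st1 <- correlation_structure(800)
  z1 <- simulate_cpp(st1, T = 20, dt = 1e-3)
  expect_lt(abs(sum(z1$counts) - 800 * 20), 4 * sqrt(800 * 20))

  # mixed structure: mean count per step -> sum n nu_n dt
  st <- correlation_structure(c(100, 0, 0, 0, 20))
  z <- simulate_cpp(st, T = 100, dt = 1e-3)
  rate <- 100 + 5 * 20
  expect_lt(abs(mean(z$counts) - rate * 1e-3),
            4 * sqrt(100 + 25 * 20) * 1e-3 / sqrt(100 * 1e-3))

  # Fano factor of a pure order-5 structure: var/mean = 5
  st5 <- correlation_structure(c(0, 0, 0, 0, 1))
  z5 <- simulate_cpp(st5, T = 2000, dt = 1e-3)
  expect_equal(stats::var(z5$counts) / mean(z5$counts), 5, tolerance = 0.4)

  # determinism under a seed
  za <- simulate_cpp(st, T = 5, dt = 1e-3, seed = 99)
  zb <- simulate_cpp(st, T = 5, dt = 1e-3, seed = 99)
  expect_identical(za$counts, zb$counts)
})

test_that("raster realizations have per-neuron rate lambda and pool correlation c", {
  set.seed(602)
  sp <- population_spec(N = 40, N_c = 10, c = 0.1, order = 5, rate = 20)
  T <- 200
  ras <- simulate_raster(sp, T)
  rate_i <- tabulate(ras$neuron, 40) / T
  se <- sqrt(20 / T)
  expect_true(all(abs(rate_i - 20) < 4 * se))

  # pairwise count correlation: within pool ~ c, across ~ 0
  dt <- 2e-3
  nb <- as.integer(T / dt)
  cnt <- vapply(1:40, function(i)
    tabulate(cubicm:::bin_index(ras$time[ras$neuron == i], dt, nb), nb),
    integer(nb))
  cm <- stats::cor(cnt)
  pool <- 1:10
  within <- cm[pool, pool][upper.tri(diag(10))]
  across <- cm[pool, 11:40]
  expect_equal(mean(within), 0.1, tolerance = 0.02)
  expect_lt(abs(mean(across)), 0.005)
})

test_that("filtered simulations match theoretical cumulants", {
  set.seed(603)
  sp <- population_spec(N = 100, N_c = 20, c = 0.1, order = 5, rate = 10)
  st <- build_structure(sp)
  tau <- 0.01; dt <- 5e-5
  ker <- exp_kernel(1, tau)
  R <- 20
  ks <- matrix(0, R, 3)
  for (i in seq_len(R)) {
    tr <- cubicm:::sim_structure_trace(st, ker, T = 20, dt = dt)
    cu <- sample_cumulants(tr)
    ks[i, ] <- c(cu$k1, cu$k2, cu$k3)
  }
  n <- seq_along(st)
  for (m in 1:3) {
    # grid-sampled kernel: the exact stationary cumulant of the simulated
    # trace replaces int phi^m by dt * sum_i phi(i dt)^m
    target_disc <- sum(n^m * as.numeric(st)) * dt / (1 - exp(-m * dt / tau))
    se <- stats::sd(ks[, m]) / sqrt(R)
    expect_lt(abs(mean(ks[, m]) - target_disc), 3 * se)
    # at 20 kHz the continuum value agrees to the discretization bias,
    # about m*dt/(2*tau) in relative terms
    target_cont <- theoretical_cumulant(st, ker, m)
    expect_lt(abs(mean(ks[, m]) / target_cont - 1), m * dt / tau)
  }
})

test_that("jitter moves spikes but never creates or deletes them", {
  set.seed(604)
  sp <- population_spec(N = 20, N_c = 20, c = 0.05, order = 4, rate = 10)
  ras <- simulate_raster(sp, 10)
  expect_identical(apply_jitter(ras, 0), ras)
  jit <- apply_jitter(ras, 0.005, t_max = 10)
  expect_equal(nrow(jit), nrow(ras))
  expect_identical(jit$neuron, ras$neuron)
  expect_true(all(jit$time >= 0 & jit$time < 10))
  expect_true(all(abs(jit$time - ras$time) <= 0.005 + 1e-12))
})

test_that("lognormal renewal trains have the requested ISI statistics", {
  set.seed(605)
  sp <- population_spec(N = 1, rate = 20, isi_cv = 0.5)
  out <- simulate_nonpoisson(sp, T = 600, dt = 1e-3, raster = TRUE)
  isi <- diff(sort(out$raster$time[out$raster$neuron == 1]))
  expect_gt(length(isi), 1e4)
  expect_equal(mean(isi), 1 / 20, tolerance = 0.03)
  expect_equal(stats::sd(isi) / mean(isi), 0.5, tolerance = 0.05)

  # near-regular trains are underdispersed relative to Poisson
  spr <- population_spec(N = 1, rate = 20, isi_cv = 0.1)
  zr <- simulate_nonpoisson(spr, T = 300, dt = 0.05)
  expect_lt(stats::var(zr$counts), mean(zr$counts))
})

test_that("correlated non-Poisson counts keep the imposed correlation structure", {
  set.seed(606)
  sp <- population_spec(N = 50, N_c = 50, c = 0.05, order = 5, rate = 10,
                        isi_cv = 2)
  st <- build_structure(sp)
  z <- simulate_nonpoisson(sp, T = 200, dt = 1e-3)
  # first two count cumulants of the summed activity match the CPP values
  n <- seq_along(st)
  m1 <- sum(n * as.numeric(st)) * 1e-3
  m2 <- sum(n^2 * as.numeric(st)) * 1e-3
  expect_equal(mean(z$counts), m1, tolerance = 0.03 * m1)
  expect_equal(stats::var(z$counts), m2, tolerance = 0.12 * m2)
})

test_that("inhibitory admixture shifts the mean by -R_I A tau", {
  set.seed(607)
  ker <- exp_kernel(1, 0.01)
  tr <- poisson_trace(1000, ker, T = 20, dt = 5e-4)
  sp0 <- population_spec(N = 100, rate = 10, inhib_rate = 0)
  expect_identical(mix_inhibition(tr, sp0, ker), tr)
  sp <- population_spec(N = 100, rate = 10, inhib_rate = 5)
  mixed <- mix_inhibition(tr, sp, ker, warmup = 1)
  kappa1_shift <- 100 * 5 * 1 * 0.01
  expect_equal(mean(mixed$samples) - mean(tr$samples), -kappa1_shift,
               tolerance = 0.1 * kappa1_shift)
})

test_that("heterogeneous amplitudes preserve the mean and reduce to the plain filter", {
  set.seed(608)
  sp <- population_spec(N = 50, N_c = 50, c = 0.05, order = 5, rate = 10)
  T <- 20; dt <- 5e-4
  ras <- simulate_raster(sp, T)
  ker <- exp_kernel(1.5, 0.01)
  tr0 <- heterogeneous_amplitude_filter(ras, 50, ker, 0, T, dt, seed = 1)
  z <- bin_raster(ras, T, dt)
  tr_plain <- filter_counts(z, ker, warmup = 1)
  expect_equal(tr0$samples, tr_plain$samples, tolerance = 1e-12)

  tr2 <- heterogeneous_amplitude_filter(ras, 50, ker, 2, T, dt, seed = 2)
  # mean amplitude is fixed at kernel$A, so the trace mean is CV-invariant
  expect_equal(mean(tr2$samples), mean(tr0$samples),
               tolerance = 0.15 * mean(tr0$samples))
})
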