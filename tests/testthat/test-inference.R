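test_that("rectangular-kernel bound reduces to the count-based formula", {
  # with A = 1 all power integrals equal h, and the bound becomes
  # k1 + (k+1)(k2 - k1) for any window width
  for (h in c(1, 0.005)) {
    ker <- rect_kernel(1, h)
    for (k in c(1, 2, 7, 30)) {
      k1 <- 3.2; k2 <- 4.1
      b <- h0_bound(k1, k2, k, ker, L = 1e5)
      expect_equal(b$kappa3_star, k1 + (k + 1) * (k2 - k1),
                   tolerance = 1e-12)
    }
  }
})

test_that("analytic bound equals the vertex-enumeration optimum", {
  set.seed(701)
  for (rep in 1:100) {
    k <- sample(2:50, 1)
    ker <- exp_kernel(stats::runif(1, 0.2, 3), stats::runif(1, 0.001, 0.1))
    nu <- rand_feasible_instance(k)
    n <- seq_len(k)
    k1 <- sum(n * nu) * kernel_integral_power(ker, 1)
    k2 <- sum(n^2 * nu) * kernel_integral_power(ker, 2)
    b <- h0_bound(k1, k2, k, ker, L = 1e4)
    oracle <- lp_bound_oracle(k1, k2, k, ker)
    expect_equal(b$kappa3_star, oracle, tolerance = 1e-8)
  }
})

test_that("independent Poisson input sits exactly on the order-1 boundary", {
  ker <- exp_kernel(1, 0.02)
  R <- 500
  k1 <- R * 0.02          # R tau
  k2 <- R * 0.02 / 2      # R tau / 2
  b <- h0_bound(k1, k2, 1, ker, L = 1e5)
  expect_equal(b$kappa3_star, (4 * k2 - k1) / 3, tolerance = 1e-12)
  expect_equal(b$kappa3_star, R * 0.02 / 3, tolerance = 1e-12)
})

test_that("the exponential-kernel bound does not depend on tau", {
  k1 <- 2.3; k2 <- 3.7; L <- 1e5
  for (k in c(1, 3, 10)) {
    vals <- vapply(seq(0.001, 0.1, length.out = 25), function(tau)
      h0_bound(k1, k2, k, exp_kernel(1, tau), L)$kappa3_star, 0)
    expect_lt(diff(range(vals)) / abs(mean(vals)), 1e-10)
  }
})

test_that("infeasible corners are clamped conservatively", {
  ker <- exp_kernel(1, 0.01)
  a <- vapply(1:3, function(m) kernel_integral_power(ker, m), 0)
  # sub-Poisson signal (k2/a2 < k1/a1): order-k mass clamped to zero
  b <- h0_bound(1, 0.3, 4, ker, L = 1e4)
  expect_true(b$clamped)
  expect_equal(b$nuk_star, 0)
  expect_equal(b$kappa3_star, a[3] * 1 / a[1], tolerance = 1e-12)
  # unclamped bound would be larger than the clamped one
  # very dispersed signal: nu1 would go negative, all mass at order k
  b2 <- h0_bound(0.01, 5, 2, ker, L = 1e4)
  expect_true(b2$clamped)
  expect_equal(b2$nu1_star, 0)
  expect_equal(b2$nuk_star, (5 / a[2]) / 4, tolerance = 1e-12)
  expect_error(h0_bound(1, 1, 2, exp_kernel(-1, 0.01), 1e4), "sign-flip")
})

test_that("p-values follow the one-sided normal form", {
  expect_equal(cubicm_p_value(2, 2, 0.5), 0.5)
  expect_equal(cubicm_p_value(2 + 1.6449 * 0.5, 2, 0.5), 0.05,
               tolerance = 1e-3)
  expect_gt(cubicm_p_value(-50, 2, 0.5), 1 - 1e-10)
  expect_error(cubicm_p_value(1, 1, 0), "positive")
})

test_that("correction factor is near 1 when samples are independent", {
  set.seed(702)
  # tau far below dt: consecutive samples carry no shared kernel mass
  ker <- exp_kernel(1, 1e-5)
  dt <- 1e-3
  fc <- correction_factor(k1 = 2000 * 1e-5, ker, dt, L = 5e4,
                          n_surrogates = 100)
  expect_gt(fc$f_c, 0.8)
  expect_lt(fc$f_c, 1.25)
  expect_error(correction_factor(-1, ker, dt, 1e4), "positive")
})

test_that("correction factor is reproducible and stable in surrogate count", {
  set.seed(703)
  ker <- exp_kernel(1, 0.005)
  fa <- correction_factor(10, ker, 5e-4, 2e4, n_surrogates = 30, seed = 5)
  fb <- correction_factor(10, ker, 5e-4, 2e4, n_surrogates = 30, seed = 5)
  expect_identical(fa$f_c, fb$f_c)
  fc2 <- correction_factor(10, ker, 5e-4, 2e4, n_surrogates = 60, seed = 6)
  expect_lt(abs(log(fc2$f_c / fa$f_c)), log(1.6))
  expect_gt(fa$f_c, 1)  # correlated samples inflate sd(k3)
})

test_that("the sequential test returns a coherent result object", {
  set.seed(704)
  ker <- exp_kernel(1, 0.002)
  tr <- poisson_trace(2000, ker, T = 10, dt = 1e-4)
  res <- cubicm(tr, ker, seed = 42)
  expect_s3_class(res, "cubicm_result")
  expect_true(res$xi_hat >= 1)
  expect_false(res$censored)
  expect_equal(length(res$p_values), res$xi_hat)
  n_p <- length(res$p_values)
  expect_gt(res$p_values[n_p], res$alpha)
  if (n_p > 1) expect_true(all(res$p_values[-n_p] <= res$alpha))
  expect_equal(nrow(res$tests), n_p)
  # same seed reproduces the analysis exactly (including surrogates)
  res2 <- cubicm(tr, ker, seed = 42)
  expect_identical(res$tests, res2$tests)
  expect_identical(res$f_c, res2$f_c)
  expect_error(cubicm(shot_noise_trace(rep(1, 100), 1e-3), ker),
               "degenerate")
})

test_that("censoring is reported when every order is rejected", {
  set.seed(705)
  st <- build_structure(population_spec(N = 100, N_c = 20, c = 0.2,
                                        order = 10, rate = 10))
  ker <- exp_kernel(1, 0.01)
  tr <- cubicm:::sim_structure_trace(st, ker, T = 20, dt = 5e-4)
  res <- cubicm(tr, ker, correction = FALSE, k_max = 2)
  expect_true(res$censored)
  expect_equal(res$xi_hat, 2L)
})

test_that("inhibitory-only input is analyzed through the sign flip", {
  set.seed(706)
  ker <- exp_kernel(-1, 0.005)
  tr <- poisson_trace(1000, ker, T = 20, dt = 2e-4)
  expect_lt(mean(tr$samples), 0)
  res <- cubicm(tr, ker, seed = 7)
  expect_true(res$flipped)
  expect_equal(res$xi_hat, 1L)
})

test_that("pairwise correlation readout matches the construction", {
  sp <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20, rate = 5)
  st <- build_structure(sp)
  ker <- exp_kernel(1, 0.02)
  c_hat <- pairwise_c_from_cumulants(theoretical_cumulant(st, ker, 1),
                                     theoretical_cumulant(st, ker, 2),
                                     ker, N = 1000, N_c = 100)
  expect_equal(c_hat, 0.05, tolerance = 1e-12)

  # independent population: kappa2/kappa1 = a2/a1 -> c = 0
  st0 <- correlation_structure(700)
  expect_equal(pairwise_c_from_cumulants(
    theoretical_cumulant(st0, ker, 1), theoretical_cumulant(st0, ker, 2),
    ker, N = 1000, N_c = 100), 0, tolerance = 1e-12)

  # under-subtracted resting potential inflates kappa1 -> c underestimated
  k1 <- theoretical_cumulant(st, ker, 1)
  k2 <- theoretical_cumulant(st, ker, 2)
  c_shift <- pairwise_c_from_cumulants(k1 - (-0.5), k2, ker, 1000, 100)
  expect_lt(c_shift, 0.05)
})
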