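# Independent oracles used by the tests.

# Exact solution of the constrained third-cumulant maximization by vertex
# enumeration: with two equality constraints every basic feasible solution
# has at most two nonzero rates, so the optimum is found by solving all
# 2x2 systems (and all single-rate systems) over orders 1..k and keeping
# the best feasible candidate.  Independent of the closed-form in h0_bound.
lp_bound_oracle <- function(k1, k2, k, kernel, tol = 1e-9) {
  a1 <- kernel_integral_power(kernel, 1)
  a2 <- kernel_integral_power(kernel, 2)
  a3 <- kernel_integral_power(kernel, 3)
  best <- -Inf
  scale_nu <- abs(k1 / a1) + abs(k2 / a2)
  for (i in seq_len(k)) {
    # single nonzero rate: feasible only if both constraints agree
    nu <- k1 / (i * a1)
    if (nu >= -tol * scale_nu &&
        abs(i^2 * nu * a2 - k2) <= tol * abs(k2)) {
      best <- max(best, i^3 * nu * a3)
    }
    if (i < k) {
      for (j in (i + 1):k) {
        M <- matrix(c(i * a1, j * a1, i^2 * a2, j^2 * a2),
                    2, 2, byrow = TRUE)
        nu2 <- tryCatch(solve(M, c(k1, k2)), error = function(e) NULL)
        if (is.null(nu2) || any(nu2 < -tol * scale_nu)) next
        best <- max(best, (i^3 * nu2[1] + j^3 * nu2[2]) * a3)
      }
    }
  }
  best
}

# random correlation structure supported on 1..k, guaranteed feasible
rand_feasible_instance <- function(k) {
  support <- sort(sample.int(k, min(k, sample(1:3, 1))))
  nu <- numeric(k)
  nu[support] <- stats::rexp(length(support), rate = 1 / 100)
  if (all(nu == 0)) nu[1] <- 1
  nu
}

# brute-force discrete convolution of counts with the sampled exponential
# impulse response (full length), the oracle for exact integration
conv_exp_oracle <- function(counts, A, tau, dt) {
  n <- length(counts)
  phi <- A * exp(-(seq_len(n) - 1) * dt / tau)
  stats::convolve(counts, rev(phi), type = "open")[seq_len(n)]
}

# independent-input shot-noise trace at total rate `rate`
poisson_trace <- function(rate, kernel, T, dt, warmup = 1) {
  n_tot <- as.integer(round((T + warmup) / dt))
  cnt <- stats::rpois(n_tot, rate * dt)
  filter_counts(cnt, kernel, warmup = warmup, dt = dt)
}
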