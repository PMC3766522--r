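#' Upper bound on the third cumulant under correlations of order at most k
#'
#' Solves, in closed form, the constrained maximization of the third
#' shot-noise cumulant over correlation structures with entries only up to
#' order `k`, subject to the first two measured cumulants:
#' \deqn{\kappa^*_{3,k} = \max_{\nu \ge 0} \sum_{n \le k} n^3 \nu_n a_3
#'   \quad s.t.\ k_1 = \sum n \nu_n a_1,\ k_2 = \sum n^2 \nu_n a_2,}
#' with \eqn{a_m = \int \phi^m}.  The optimum puts mass on orders 1 and
#' `k` only: \eqn{\nu^*_k = (k_2/a_2 - k_1/a_1)/(k(k-1))} and
#' \eqn{\nu^*_1 = k_1/a_1 - k \nu^*_k}.  In a form valid for all
#' \eqn{k \ge 1} (continuous extension at `k = 1`),
#' \deqn{\kappa^*_{m,k} = a_m\left[\frac{k_1}{a_1}
#'   + \Big(\sum_{i=0}^{m-2} k^i\Big)
#'     \Big(\frac{k_2}{a_2} - \frac{k_1}{a_1}\Big)\right],}
#' evaluated for `m = 3` (the bound) and `m = 2..6` (for the null standard
#' deviation via [var_k3()]).  For the exponential kernel the bound does
#' not depend on the time constant.
#'
#' Infeasible corners are clamped conservatively: if
#' \eqn{k_2/a_2 < k_1/a_1} (sub-Poisson signal) the order-`k` rate is set
#' to zero, and if \eqn{\nu^*_1 < 0} all mass is moved to order `k`; both
#' choices lower the bound and never inflate rejections.
#'
#' Kernels with \eqn{\int \phi^3 < 0} (inhibitory) are handled upstream by
#' sign-flipping trace and kernel, which turns the minimization into this
#' maximization; `h0_bound` itself requires \eqn{\int \phi^3 > 0}.
#'
#' @param k1,k2 first and second sample cumulants of the trace.
#' @param k tested order of correlation (`>= 1`).
#' @param kernel kernel object with \eqn{\int \phi^3 > 0}.
#' @param L sample count of the trace (enters the null variance).
#' @return A list of class `"h0_bound"` with elements `k`, `nu1_star`,
#'   `nuk_star` (`NA` at `k = 1`, where the extension is not an achievable
#'   structure), `kappa3_star`, `kappa_star` (named vector, orders 2..6),
#'   `sigma_star` and `clamped`.
#' @examples
#' h0_bound(k1 = 0.1, k2 = 0.08, k = 3, exp_kernel(1, 0.01), L = 1e5)
#' @export
h0_bound <- function(k1, k2, k, kernel, L) {
  stopifnot(is.numeric(k1), is.numeric(k2), k >= 1, k == round(k), L >= 3)
  a <- vapply(1:6, function(m) kernel_integral_power(kernel, m), 0)
  if (a[1] == 0 || a[2] == 0) stop("degenerate kernel: zero power integral")
  if (a[3] <= 0)
    stop("h0_bound requires int(phi^3) > 0; sign-flip trace and kernel ",
         "for inhibitory kernels")
  r1 <- k1 / a[1]
  r2 <- k2 / a[2]
  d <- r2 - r1
  clamped <- FALSE
  ms <- 2:6
  if (d < 0) {
    # sub-Poisson: no order-k mass is feasible
    nu1 <- r1; nuk <- 0; clamped <- TRUE
    kap <- a[ms] * r1
  } else if (k == 1L) {
    nu1 <- r1; nuk <- NA_real_
    kap <- a[ms] * (r1 + (ms - 1) * d)
  } else {
    nuk <- d / (k * (k - 1))
    nu1 <- r1 - k * nuk
    if (nu1 < 0) {
      nu1 <- 0
      nuk <- r2 / k^2
      clamped <- TRUE
      kap <- a[ms] * k^ms * nuk
    } else {
      kap <- a[ms] * (nu1 + k^ms * nuk)
    }
  }
  names(kap) <- paste0("kappa", ms)
  sigma <- sqrt(var_k3(kap, L))
  structure(list(k = as.integer(k), nu1_star = nu1, nuk_star = nuk,
                 kappa3_star = kap[["kappa3"]], kappa_star = kap,
                 sigma_star = sigma, clamped = clamped),
            class = "h0_bound")
}

#' @export
print.h0_bound <- function(x, ...) {
  cat(sprintf(
    "<H0^%d bound>  kappa3* = %.6g, sigma* = %.6g%s\n",
    x$k, x$kappa3_star, x$sigma_star,
    if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Correction factor for temporally correlated samples
#'
#' Kernel overlap makes consecutive trace samples statistically dependent,
#' so the iid formula for the standard deviation of `k3` underestimates the
#' true one and the test rejects too often.  The correction estimates the
#' underestimation ratio on matched independent-input surrogates: the rate
#' of independent spike activity is approximated as
#' \eqn{\lambda = k_1 / \int\phi}, `n_surrogates` Poisson shot-noise traces
#' with the same kernel, `dt`, warm-up and length are simulated, and
#' \deqn{f_c = sd(k_3) / \sigma^*_1} is returned, where \eqn{sd(k_3)} is
#' the empirical standard deviation of the surrogates' third k-statistics.
#' The relative bias of \eqn{\sigma^*_1} is assumed to carry over to
#' \eqn{\sigma^*_k} for `k > 1`, so the factor is computed once and reused
#' for every tested order.
#'
#' By default the reference \eqn{\sigma^*_1} is computed from the
#' surrogates' own mean first and second k-statistics, so the ratio
#' isolates the sample-correlation effect; `sigma_ref = "data"` uses the
#' data's `(k1, k2)` instead.
#'
#' @param k1 first sample cumulant of the (sign-corrected) data trace.
#' @param kernel kernel object (positive \eqn{\int\phi^3}).
#' @param dt sampling interval in seconds.
#' @param L number of analysis samples.
#' @param n_surrogates number of surrogate traces (default 20).
#' @param warmup warm-up duration in seconds.
#' @param sigma_ref `"surrogate"` (default) or `"data"`; see Details.
#' @param k2 data second cumulant, required for `sigma_ref = "data"`.
#' @param seed optional integer seed for the surrogate simulation.
#' @return A list of class `"cubicm_fc"` with elements `f_c`,
#'   `sd_k3`, `sigma1_star`, `rate` and `n_surrogates`.
#' @export
correction_factor <- function(k1, kernel, dt, L, n_surrogates = 20,
                              warmup = 1, sigma_ref = c("surrogate", "data"),
                              k2 = NULL, seed = NULL) {
  sigma_ref <- match.arg(sigma_ref)
  stopifnot(inherits(kernel, "cubicm_kernel"), dt > 0, L >= 3,
            n_surrogates >= 2)
  a1 <- kernel_integral_power(kernel, 1)
  rate <- k1 / a1
  if (!is.finite(rate) || rate <= 0)
    stop("implied independent rate k1/int(phi) must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_tot <- as.integer(round(warmup / dt)) + L
  ks <- matrix(0, n_surrogates, 3L)
  for (i in seq_len(n_surrogates)) {
    cnt <- stats::rpois(n_tot, rate * dt)
    tr <- filter_counts(cnt, kernel, warmup = warmup, dt = dt)
    cu <- sample_cumulants(tr)
    ks[i, ] <- c(cu$k1, cu$k2, cu$k3)
  }
  sd_k3 <- stats::sd(ks[, 3L])
  ref <- if (sigma_ref == "surrogate") {
    h0_bound(mean(ks[, 1L]), mean(ks[, 2L]), 1L, kernel, L)
  } else {
    if (is.null(k2)) stop("sigma_ref = \"data\" needs the data 'k2'")
    h0_bound(k1, k2, 1L, kernel, L)
  }
  structure(list(f_c = sd_k3 / ref$sigma_star, sd_k3 = sd_k3,
                 sigma1_star = ref$sigma_star, rate = rate,
                 n_surrogates = n_surrogates),
            class = "cubicm_fc")
}

#' @export
print.cubicm_fc <- function(x, ...) {
  cat(sprintf(
    "<correction factor>  f_c = %.4g (sd(k3) = %.4g / sigma1* = %.4g, %d surrogates at %.4g events/s)\n",
    x$f_c, x$sd_k3, x$sigma1_star, x$n_surrogates, x$rate))
  invisible(x)
}

#' P-value of the order-k test
#'
#' Under the null that correlations do not exceed order `k`, the third
#' sample cumulant is approximately normal with mean \eqn{\kappa^*_{3,k}}
#' and standard deviation `sigma`, so
#' \eqn{p_k = 1 - \Phi((k_3 - \kappa^*_{3,k}) / \sigma)}.
#'
#' @param k3 observed third sample cumulant.
#' @param kappa3_star null mean (the [h0_bound()] optimum).
#' @param sigma null standard deviation, possibly inflated by the
#'   correction factor; must be positive.
#' @return The p-value in `[0, 1]`.
#' @export
cubicm_p_value <- function(k3, kappa3_star, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be positive")
  1 - stats::pnorm((k3 - kappa3_star) / sigma)
}

#' Infer a lower confidence bound on the maximal order of correlation
#'
#' Runs the full sequential test on a filtered signal: subtracts the
#' resting offset, measures the first three sample cumulants, estimates
#' the correlated-samples correction factor once (if enabled), and tests
#' the null hypotheses of correlation order at most `k` for
#' `k = 1, 2, ...` until the first non-rejection.  The returned
#' \eqn{\hat\xi} is the smallest order whose null could not be rejected —
#' a lower confidence bound for the true maximal order of correlation in
#' the presynaptic population.
#'
#' For kernels with \eqn{\int\phi^3 < 0} (inhibitory input) the trace and
#' kernel are sign-flipped before the analysis, which maps the
#' third-cumulant minimization onto the implemented maximization.
#'
#' @param trace a [shot_noise_trace()] (or numeric vector with `dt`).
#' @param kernel the assumed postsynaptic kernel.
#' @param alpha significance level of each test (default 0.05).
#' @param correction logical: apply the correlated-samples correction
#'   factor (default `TRUE`); when `FALSE`, `f_c = 1`.
#' @param n_surrogates surrogate traces for the correction (default 20).
#' @param resting resting offset \eqn{U_r} subtracted from every sample
#'   (signal units; default 0).
#' @param k_max largest tested order (default 1000).  If every null up to
#'   `k_max` is rejected the result is censored, not a valid bound.
#' @param warmup warm-up used for the correction surrogates, in seconds.
#' @param sigma_ref reference sigma for the correction factor, see
#'   [correction_factor()].
#' @param dt sampling interval when `trace` is a bare vector.
#' @param seed optional integer seed; the surrogate seed is derived from
#'   it so one seed reproduces the whole analysis.
#' @return An object of class `"cubicm_result"`: a list with `xi_hat`,
#'   `p_values` (one per tested order), `alpha`, `f_c`, `censored`,
#'   `cumulants`, `tests` (a data.frame with `k`, `kappa3_star`,
#'   `sigma_star`, `p`), the kernel, `resting`, `L` and `dt`.
#' @examples
#' set.seed(1)
#' z <- simulate_cpp(correlation_structure(2000), T = 6, dt = 5e-4)
#' tr <- filter_counts(z, exp_kernel(1, 0.01), warmup = 1)
#' cubicm(tr, exp_kernel(1, 0.01), correction = FALSE)
#' @export
cubicm <- function(trace, kernel, alpha = 0.05, correction = TRUE,
                   n_surrogates = 20, resting = 0, k_max = 1000,
                   warmup = 1, sigma_ref = c("surrogate", "data"),
                   dt = NULL, seed = NULL) {
  sigma_ref <- match.arg(sigma_ref)
  if (!inherits(trace, "cubicm_trace")) {
    if (is.null(dt)) stop("'dt' must be supplied for a bare sample vector")
    trace <- shot_noise_trace(trace, dt)
  }
  stopifnot(inherits(kernel, "cubicm_kernel"),
            alpha > 0, alpha < 1, k_max >= 1)
  if (!is.null(seed)) set.seed(seed)
  surrogate_seed <- if (is.null(seed)) NULL else
    sample.int(.Machine$integer.max - 1L, 1L)
  x <- trace$samples - resting
  flipped <- kernel_integral_power(kernel, 3) < 0
  work_kernel <- kernel
  if (flipped) {
    x <- -x
    work_kernel$A <- -kernel$A
  }
  if (stats::var(x) == 0) stop("degenerate (constant) trace")
  cum <- sample_cumulants(x)
  L <- cum$L
  fc_detail <- NULL
  f_c <- 1
  if (correction) {
    fc_detail <- correction_factor(cum$k1, work_kernel, trace$dt, L,
                                   n_surrogates = n_surrogates,
                                   warmup = warmup, sigma_ref = sigma_ref,
                                   k2 = cum$k2, seed = surrogate_seed)
    f_c <- fc_detail$f_c
  }
  ks <- integer(0); kappa3s <- sigmas <- ps <- numeric(0)
  xi_hat <- NA_integer_
  censored <- FALSE
  for (k in seq_len(k_max)) {
    b <- h0_bound(cum$k1, cum$k2, k, work_kernel, L)
    p <- cubicm_p_value(cum$k3, b$kappa3_star, f_c * b$sigma_star)
    ks <- c(ks, k); kappa3s <- c(kappa3s, b$kappa3_star)
    sigmas <- c(sigmas, b$sigma_star); ps <- c(ps, p)
    if (p > alpha) {
      xi_hat <- k
      break
    }
  }
  if (is.na(xi_hat)) {
    xi_hat <- as.integer(k_max)
    censored <- TRUE
  }
  structure(list(xi_hat = xi_hat,
                 p_values = ps,
                 alpha = alpha,
                 f_c = f_c,
                 correction = correction,
                 fc_detail = fc_detail,
                 censored = censored,
                 cumulants = cum,
                 tests = data.frame(k = ks, kappa3_star = kappa3s,
                                    sigma_star = sigmas, p = ps),
                 kernel = kernel,
                 flipped = flipped,
                 resting = resting,
                 L = L,
                 dt = trace$dt,
                 seed = seed),
            class = "cubicm_result")
}

#' @export
print.cubicm_result <- function(x, ...) {
  cat("Cumulant-based inference of the maximal order of correlation\n")
  cat(sprintf("  L = %d samples at dt = %g s, alpha = %g\n",
              x$L, x$dt, x$alpha))
  cat(sprintf("  k1 = %.5g, k2 = %.5g, k3 = %.5g\n",
              x$cumulants$k1, x$cumulants$k2, x$cumulants$k3))
  if (x$correction)
    cat(sprintf("  correction factor f_c = %.4g\n", x$f_c))
  else
    cat("  no correlated-samples correction (f_c = 1)\n")
  if (x$censored)
    cat(sprintf("  all H0^k rejected up to k_max: xi_hat >= %d (censored)\n",
                x$xi_hat))
  else
    cat(sprintf("  xi_hat = %d  (p_%d = %.4g > alpha)\n",
                x$xi_hat, x$xi_hat, x$p_values[length(x$p_values)]))
  invisible(x)
}

#' Pairwise correlation coefficient from signal cumulants
#'
#' Converts the first two cumulants of the filtered signal into the
#' pairwise count correlation coefficient of the correlated subpopulation:
#' \deqn{c = \left(\frac{N \kappa_2 \int\phi}{\kappa_1 \int\phi^2}
#'   - N\right) / (N_c^2 - N_c).}
#' An independent population (\eqn{\kappa_2/\kappa_1 = a_2/a_1}) gives
#' `c = 0`; note that a wrongly subtracted resting offset shifts
#' \eqn{\kappa_1} and therefore biases `c`.
#'
#' @param kappa1,kappa2 first and second cumulants of the signal
#'   (theoretical or sample).
#' @param kernel the kernel.
#' @param N population size.
#' @param N_c correlated subpopulation size (`>= 2`).
#' @return The pairwise correlation coefficient.
#' @examples
#' sp <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20, rate = 5)
#' st <- build_structure(sp)
#' ker <- exp_kernel(1, 0.02)
#' pairwise_c_from_cumulants(theoretical_cumulant(st, ker, 1),
#'                           theoretical_cumulant(st, ker, 2),
#'                           ker, N = 1000, N_c = 100)  # 0.05
#' @export
pairwise_c_from_cumulants <- function(kappa1, kappa2, kernel, N, N_c) {
  stopifnot(N_c >= 2, N >= N_c)
  if (kappa1 <= 0) stop("'kappa1' must be positive")
  a1 <- kernel_integral_power(kernel, 1)
  a2 <- kernel_integral_power(kernel, 2)
  (N * kappa2 * a1 / (kappa1 * a2) - N) / (N_c^2 - N_c)
}
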