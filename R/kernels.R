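#' Postsynaptic-potential filter kernels
#'
#' A kernel \eqn{\phi(t)} describes the deflection of the filtered signal
#' caused by a single input spike.  Three families are supported:
#'
#' * `exponential`: \eqn{\phi(t) = A e^{-t/\tau}}, the impulse response of a
#'   leaky integrator with membrane time constant \eqn{\tau}; the standard
#'   model of a postsynaptic potential with pulse-like synaptic current.
#' * `rectangular`: \eqn{\phi(t) = A} on \eqn{[0, h)}, zero elsewhere.
#'   Filtering with it and reading the result at multiples of `h` is
#'   identical to binning spikes, which connects the membrane-potential
#'   analysis to population spike counts.
#' * `alpha`: the postsynaptic potential of an alpha-synapse current,
#'   represented as a difference of two exponentials
#'   \eqn{\phi(t) = B (e^{-t/\tau} - e^{-t/\tau_\alpha})} with rise time
#'   \eqn{\tau_\alpha < \tau}, normalized so that the peak amplitude equals
#'   `A`.  The peak occurs at
#'   \eqn{t^\ast = \tau\tau_\alpha \log(\tau/\tau_\alpha)/(\tau-\tau_\alpha)};
#'   as \eqn{\tau_\alpha \to 0} the kernel tends to the exponential one.
#'
#' `A` may be negative (inhibitory input); it must be nonzero, and all time
#' constants are in seconds and must be positive.
#'
#' @param A amplitude of the postsynaptic potential per input spike, in
#'   signal units (e.g. mV).  Sign carries through: negative `A` models
#'   inhibitory kernels.
#' @param tau decay time constant in seconds (for `rect_kernel`, the window
#'   width `h`).
#' @param tau_alpha rise time constant in seconds (`alpha_kernel` only);
#'   must satisfy `0 < tau_alpha < tau`.
#' @return An object of class `"cubicm_kernel"`: a list with elements
#'   `family`, `A`, `tau` and (alpha family) `tau_alpha`.
#' @examples
#' k <- exp_kernel(A = 1, tau = 0.02)
#' kernel_integral_power(k, 1)  # = tau
#' @seealso [kernel_integral_power()], [filter_counts()]
#' @export
exp_kernel <- function(A = 1, tau = 0.01) {
  new_kernel("exponential", A = A, tau = tau)
}

#' @rdname exp_kernel
#' @param h window width in seconds (rectangular family).
#' @export
rect_kernel <- function(A = 1, h = 0.005) {
  new_kernel("rectangular", A = A, tau = h)
}

#' @rdname exp_kernel
#' @export
alpha_kernel <- function(A = 1, tau = 0.01, tau_alpha = 0.001) {
  new_kernel("alpha", A = A, tau = tau, tau_alpha = tau_alpha)
}

new_kernel <- function(family, A, tau, tau_alpha = NULL) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (A == 0) stop("kernel amplitude 'A' must be nonzero")
  if (tau <= 0) stop("kernel time constant must be positive")
  k <- list(family = family, A = A, tau = tau)
  if (family == "alpha") {
    stopifnot(is.numeric(tau_alpha), length(tau_alpha) == 1L)
    if (tau_alpha <= 0) stop("'tau_alpha' must be positive")
    if (tau_alpha >= tau)
      stop("'tau_alpha' must be smaller than 'tau' for the alpha kernel")
    k$tau_alpha <- tau_alpha
  }
  class(k) <- "cubicm_kernel"
  k
}

#' @export
print.cubicm_kernel <- function(x, ...) {
  cat(sprintf("<%s kernel>  A = %g", x$family, x$A))
  if (x$family == "rectangular") {
    cat(sprintf(", h = %g s\n", x$tau))
  } else if (x$family == "alpha") {
    cat(sprintf(", tau = %g s, tau_alpha = %g s (t_peak = %g s)\n",
                x$tau, x$tau_alpha, alpha_t_peak(x)))
  } else {
    cat(sprintf(", tau = %g s\n", x$tau))
  }
  invisible(x)
}

# time of the peak of the (unnormalized) difference-of-exponentials kernel
alpha_t_peak <- function(kernel) {
  tau <- kernel$tau; ta <- kernel$tau_alpha
  tau * ta * log(tau / ta) / (tau - ta)
}

# peak-normalization constant B with B*(exp(-t*/tau) - exp(-t*/tau_alpha)) = A
alpha_scale <- function(kernel) {
  tp <- alpha_t_peak(kernel)
  kernel$A / (exp(-tp / kernel$tau) - exp(-tp / kernel$tau_alpha))
}

#' Power integrals of a filter kernel
#'
#' Computes \eqn{\int_0^\infty \phi(t)^m \, dt} in closed form.  These
#' integrals link the rates of synchronous input events to the cumulants of
#' the filtered signal: for compound-Poisson input the m-th cumulant is
#' \eqn{\kappa_m = \sum_n n^m \nu_n \int \phi^m}.
#'
#' Closed forms: exponential \eqn{A^m \tau / m}; rectangular \eqn{A^m h};
#' alpha family by binomial expansion of the difference of exponentials.
#'
#' @param kernel a [exp_kernel()]-style kernel object.
#' @param m integer order, 1 to 6.
#' @return The value of \eqn{\int \phi^m} (signal units to the m-th power
#'   times seconds).  Negative for odd `m` when `A < 0`.
#' @examples
#' kernel_integral_power(exp_kernel(1, 0.02), 3)  # tau/3
#' @export
kernel_integral_power <- function(kernel, m) {
  stopifnot(inherits(kernel, "cubicm_kernel"))
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 1 || m > 6)
    stop("'m' must be an integer between 1 and 6")
  A <- kernel$A; tau <- kernel$tau
  switch(kernel$family,
    exponential = A^m * tau / m,
    rectangular = A^m * tau,
    alpha = {
      B <- alpha_scale(kernel)
      ta <- kernel$tau_alpha
      j <- 0:m
      # int (e^{-t/tau} - e^{-t/ta})^m = sum_j C(m,j) (-1)^j / (j/ta + (m-j)/tau)
      B^m * sum(choose(m, j) * (-1)^j / (j / ta + (m - j) / tau))
    },
    stop("unknown kernel family"))
}

# kernel sampled on the time grid, for discrete convolution.  The kernel is
# truncated where the envelope has decayed below `tol` of its peak.
sample_kernel <- function(kernel, dt, tol = 1e-12) {
  stopifnot(dt > 0)
  switch(kernel$family,
    exponential = {
      n <- ceiling(-log(tol) * kernel$tau / dt)
      kernel$A * exp(-(seq_len(n) - 1) * dt / kernel$tau)
    },
    rectangular = {
      n <- max(1L, as.integer(round(kernel$tau / dt)))
      rep(kernel$A, n)
    },
    alpha = {
      n <- ceiling(-log(tol) * kernel$tau / dt)
      t <- (seq_len(n) - 1) * dt
      alpha_scale(kernel) * (exp(-t / kernel$tau) - exp(-t / kernel$tau_alpha))
    })
}

#' Filter a spike-count series into a shot-noise trace
#'
#' Convolves per-time-step summed spike counts with a kernel to produce the
#' model subthreshold signal \eqn{S(t) = (Z * \phi)(t)} sampled on the same
#' grid.  For the exponential family the exact-integration recursion
#' `s[i] = s[i-1] * exp(-dt/tau) + A * n[i]` is used (the update is exact
#' for grid-aligned impulses); rectangular and alpha kernels use discrete
#' convolution with the sampled kernel.  A spike in step `i` contributes
#' \eqn{\phi(0)} at sample `i`.
#'
#' Samples within the initial warm-up window are computed (so the trace has
#' reached its stationary regime) but excluded from the returned analysis
#' segment.
#'
#' @param counts a [spike_counts()] object, or a plain integer/numeric
#'   vector (then `dt` must be given).
#' @param kernel a kernel object.
#' @param warmup warm-up duration in seconds excluded from the output
#'   (default 1 s).
#' @param dt sampling interval in seconds; only needed when `counts` is a
#'   bare vector.
#' @return A [shot_noise_trace()] with the post-warm-up samples.
#' @examples
#' n <- integer(2000); n[1] <- 1L
#' tr <- filter_counts(n, exp_kernel(1, 0.01), warmup = 0, dt = 5e-5)
#' head(tr$samples)  # impulse response exp(-t/tau)
#' @export
filter_counts <- function(counts, kernel, warmup = 1, dt = NULL) {
  if (inherits(counts, "spike_counts")) {
    dt <- counts$dt
    n <- counts$counts
  } else {
    if (is.null(dt)) stop("'dt' must be supplied for a bare count vector")
    n <- counts
  }
  stopifnot(inherits(kernel, "cubicm_kernel"))
  if (dt <= 0) stop("'dt' must be positive")
  if (length(n) == 0L) stop("empty count series")
  n_warm <- as.integer(round(warmup / dt))
  if (n_warm >= length(n))
    stop("warm-up window is at least as long as the count series")
  if (kernel$family == "exponential") {
    s <- stats::filter(kernel$A * n, exp(-dt / kernel$tau),
                       method = "recursive")
    s <- as.numeric(s)
  } else {
    phi <- sample_kernel(kernel, dt)
    s <- conv_open(n, phi)[seq_along(n)]
  }
  if (n_warm > 0L) s <- s[-seq_len(n_warm)]
  shot_noise_trace(s, dt = dt)
}

# linear ("open") convolution via FFT, stats::convolve
conv_open <- function(x, y) {
  stats::convolve(x, rev(y), type = "open")
}

#' Shot-noise / membrane-potential trace
#'
#' Container for a uniformly sampled scalar signal: the samples, the
#' sampling interval `dt` (seconds) and the sample count `L`.
#'
#' @param samples numeric vector of signal samples.
#' @param dt sampling interval in seconds.
#' @return An object of class `"cubicm_trace"`.
#' @export
shot_noise_trace <- function(samples, dt) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(samples = as.numeric(samples), dt = dt,
                 L = length(samples)),
            class = "cubicm_trace")
}

#' @export
print.cubicm_trace <- function(x, ...) {
  cat(sprintf(
    "<trace>  L = %d samples, dt = %g s (%.6g s), mean = %.4g, sd = %.4g\n",
    x$L, x$dt, x$L * x$dt, mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}
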