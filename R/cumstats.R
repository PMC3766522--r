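#' First three sample cumulants (k-statistics)
#'
#' Computes the unbiased k-statistics of a sample: `k1` is the mean,
#' `k2 = L/(L-1) m2` and `k3 = L^2 / ((L-1)(L-2)) m3`, where `m2`, `m3`
#' are the central sample moments.  The k-statistics are the unique
#' symmetric unbiased estimators of the cumulants for iid samples;
#' on temporally correlated traces they remain consistent for `k1..k3`
#' but the sampling variance of `k3` is larger than the iid formula — that
#' effect is handled by the correction factor in the test, not here.
#'
#' @param x a [shot_noise_trace()] or numeric vector with at least 3
#'   samples.
#' @return A list of class `"cumulant_set"` with elements `k1`, `k2`,
#'   `k3` and `L`.
#' @examples
#' sample_cumulants(c(0, 0, 3))  # k1 = 1, k2 = 3, k3 = 9
#' @export
sample_cumulants <- function(x) {
  if (inherits(x, "cubicm_trace")) x <- x$samples
  stopifnot(is.numeric(x))
  L <- length(x)
  if (L < 3L) stop("need at least 3 samples for k1..k3")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  structure(list(k1 = m,
                 k2 = L / (L - 1) * m2,
                 k3 = L^2 / ((L - 1) * (L - 2)) * m3,
                 L = L),
            class = "cumulant_set")
}

#' @export
print.cumulant_set <- function(x, ...) {
  cat(sprintf("<sample cumulants>  L = %d\n  k1 = %.6g  k2 = %.6g  k3 = %.6g\n",
              x$L, x$k1, x$k2, x$k3))
  invisible(x)
}

#' Theoretical cumulant of compound-Poisson shot noise
#'
#' For a compound Poisson process with correlation structure
#' \eqn{(\nu_n)} filtered with kernel \eqn{\phi}, the m-th cumulant of the
#' stationary signal is \eqn{\kappa_m = \sum_n n^m \nu_n \int \phi^m}
#' (a Campbell-type relation; synchronous events of order `n` enter the
#' m-th cumulant with weight \eqn{n^m}).
#'
#' @param structure a [correlation_structure()].
#' @param kernel a kernel object.
#' @param m cumulant order, 1 to 6.
#' @return The theoretical cumulant \eqn{\kappa_m} in signal units to the
#'   m-th power.
#' @examples
#' st <- correlation_structure(c(1000))
#' theoretical_cumulant(st, exp_kernel(1, 0.02), 1)  # rate * A * tau
#' @export
theoretical_cumulant <- function(structure, kernel, m) {
  stopifnot(inherits(structure, "correlation_structure"))
  n <- seq_along(structure)
  sum(n^m * as.numeric(structure)) * kernel_integral_power(kernel, m)
}

#' Sampling variance of the third k-statistic
#'
#' Classical iid variance of `k3` for a sample of size `L` from a
#' distribution with cumulants \eqn{\kappa_2 \ldots \kappa_6}:
#' \deqn{Var(k_3) = \kappa_6/L + 9(\kappa_2\kappa_4 + \kappa_3^2)/(L-1)
#'   + 6 L \kappa_2^3 / ((L-1)(L-2)).}
#' The test evaluates it at the cumulants of the null-hypothesis optimum
#' to obtain the null standard deviation \eqn{\sigma^*_k}.
#'
#' @param kappa numeric vector of length 5: the cumulants
#'   \eqn{\kappa_2, \kappa_3, \kappa_4, \kappa_5, \kappa_6} (\eqn{\kappa_5}
#'   does not enter the formula but is kept for a uniform interface).
#' @param L sample size (`>= 3`).
#' @return The variance of `k3` (signal units to the 6th power).
#' @examples
#' var_k3(c(1, 0, 0, 0, 0), 1e3)  # standard normal: ~6/L^2 * L
#' @export
var_k3 <- function(kappa, L) {
  stopifnot(is.numeric(kappa), length(kappa) == 5L, L >= 3)
  k2 <- kappa[[1]]; k3 <- kappa[[2]]; k4 <- kappa[[3]]; k6 <- kappa[[5]]
  k6 / L + 9 * (k2 * k4 + k3^2) / (L - 1) +
    6 * L * k2^3 / ((L - 1) * (L - 2))
}
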