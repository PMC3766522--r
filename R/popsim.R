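#' Correlation structure of a compound Poisson population
#'
#' The summed spike activity of a population is modeled as a compound
#' Poisson process \eqn{Z(t) = \sum_n n Y_n(t)}, where the carrier
#' processes \eqn{Y_n} are independent Poisson processes with rate
#' \eqn{\nu_n} and every event of \eqn{Y_n} stands for `n` neurons spiking
#' in synchrony.  The rate vector \eqn{(\nu_1, \nu_2, \ldots)} is the
#' correlation structure; the maximal order of correlation is
#' \eqn{\xi = \max\{n : \nu_n > 0\}}.
#'
#' @param nu numeric vector of carrier rates in events/s, indexed by order
#'   `n = 1, 2, ...`.  All entries must be nonnegative and at least one
#'   positive.
#' @return An object of class `"correlation_structure"` (a numeric vector
#'   with the class attribute).
#' @seealso [build_structure()], [simulate_cpp()], [max_order()]
#' @export
correlation_structure <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) >= 1L, all(is.finite(nu)))
  if (any(nu < 0)) stop("carrier rates must be nonnegative")
  if (all(nu == 0)) stop("at least one carrier rate must be positive")
  structure(as.numeric(nu), class = "correlation_structure")
}

#' @rdname correlation_structure
#' @param structure a `"correlation_structure"` object.
#' @return `max_order()`: the maximal order of correlation \eqn{\xi}.
#' @export
max_order <- function(structure) {
  stopifnot(inherits(structure, "correlation_structure"))
  max(which(structure > 0))
}

#' @export
print.correlation_structure <- function(x, ...) {
  nz <- which(x > 0)
  cat(sprintf("<correlation structure>  xi = %d, total event rate = %g /s\n",
              max(nz), sum(x)))
  cat("  nonzero rates (order: events/s):\n")
  for (n in nz) cat(sprintf("    %d: %g\n", n, x[n]))
  invisible(x)
}

#' Population specification for the simulator
#'
#' Describes a presynaptic population of `N` neurons firing at `rate`
#' spikes/s each, of which a subpopulation of `N_c` neurons carries
#' synchronous events of the given `order` with pairwise count correlation
#' coefficient `c`.  Optional fields configure the robustness variants:
#' uniform spike-time jitter, lognormal inter-spike-interval (renewal)
#' single-neuron statistics, heterogeneous per-neuron synaptic amplitudes
#' and an independent inhibitory population.
#'
#' @param N number of (excitatory) neurons.
#' @param N_c size of the correlated subpopulation (`order <= N_c <= N`).
#' @param c pairwise correlation coefficient within the subpopulation, in
#'   `[0, 1)`; `c = 0` gives an independent population.
#' @param order order of the synchronous events (ignored when `c = 0`).
#' @param rate firing rate per neuron, spikes/s.
#' @param jitter half-width `j` (seconds) of the uniform spike-time jitter.
#' @param isi_cv coefficient of variation of the lognormal inter-spike
#'   intervals for non-Poisson single-neuron trains (`NULL` = Poisson).
#' @param amplitude_cv coefficient of variation of per-neuron kernel
#'   amplitudes (0 = identical synapses).
#' @param inhib_rate firing rate per neuron of an additional independent
#'   inhibitory population of the same size (0 = none).
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(N, N_c = N, c = 0, order = 2, rate = 5,
                            jitter = 0, isi_cv = NULL, amplitude_cv = 0,
                            inhib_rate = 0) {
  stopifnot(N >= 1, N_c >= 1, N_c <= N, rate > 0, jitter >= 0,
            amplitude_cv >= 0, inhib_rate >= 0)
  if (c < 0 || c >= 1) stop("'c' must lie in [0, 1)")
  if (c > 0 && (order < 2 || order > N_c))
    stop("need 2 <= order <= N_c for a correlated population")
  if (!is.null(isi_cv) && isi_cv <= 0) stop("'isi_cv' must be positive")
  structure(list(N = as.integer(N), N_c = as.integer(N_c), c = c,
                 order = as.integer(order), rate = rate, jitter = jitter,
                 isi_cv = isi_cv, amplitude_cv = amplitude_cv,
                 inhib_rate = inhib_rate),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population>  N = %d, rate = %g spikes/s", x$N, x$rate))
  if (x$c > 0)
    cat(sprintf("; N_c = %d correlated at c = %g, order %d",
                x$N_c, x$c, x$order))
  cat("\n")
  if (x$jitter > 0) cat(sprintf("  jitter: +/- %g s\n", x$jitter))
  if (!is.null(x$isi_cv))
    cat(sprintf("  lognormal ISI, CV = %g\n", x$isi_cv))
  if (x$amplitude_cv > 0)
    cat(sprintf("  amplitude CV = %g\n", x$amplitude_cv))
  if (x$inhib_rate > 0)
    cat(sprintf("  inhibitory population at %g spikes/s each\n",
                x$inhib_rate))
  invisible(x)
}

#' Build the two-entry correlation structure for a population spec
#'
#' Inverts the relation between the pairwise count correlation coefficient
#' `c` and the carrier rates: synchronous events of the requested order are
#' inserted at rate
#' \eqn{\nu_{order} = c \lambda N_c (N_c - 1) / (order (order - 1))},
#' and the independent rate \eqn{\nu_1 = N\lambda - order \cdot \nu_{order}}
#' keeps every neuron's marginal rate at \eqn{\lambda}.
#'
#' @param spec a [population_spec()].
#' @return A [correlation_structure()] with nonzero entries at orders 1 and
#'   `order` only (order 1 only when `c = 0`).
#' @examples
#' s <- build_structure(population_spec(N = 1000, N_c = 100, c = 0.05,
#'                                      order = 20, rate = 5))
#' max_order(s)
#' @export
build_structure <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  N <- spec$N; lam <- spec$rate
  if (spec$c == 0) {
    nu <- N * lam
    return(correlation_structure(nu))
  }
  n <- spec$order
  nu_n <- spec$c * lam * spec$N_c * (spec$N_c - 1) / (n * (n - 1))
  nu1 <- N * lam - n * nu_n
  if (nu1 < 0)
    stop("requested correlation too strong: implied independent rate < 0")
  nu <- numeric(n)
  nu[1] <- nu1
  nu[n] <- nu_n
  correlation_structure(nu)
}

#' Binomial-shaped (multiple-interaction) correlation structure
#'
#' Alternative structure builder in which each carrier event is copied into
#' each of the `N_c` pool neurons independently with probability `p = c`,
#' producing carrier rates with a binomial profile
#' \eqn{\nu_n = (\lambda/c)\, \mathrm{Binom}(n; N_c, c)} for
#' \eqn{n \ge 1}; neurons outside the pool contribute independently to
#' \eqn{\nu_1}.  Every pool neuron's marginal rate is \eqn{\lambda} and the
#' pairwise count correlation within the pool equals `c`.
#'
#' @inheritParams population_spec
#' @return A [correlation_structure()] of length `N_c`.
#' @export
build_structure_binomial <- function(N, N_c, c, rate) {
  stopifnot(N >= N_c, N_c >= 2, c > 0, c < 1, rate > 0)
  nu_m <- rate / c                         # carrier ("mother") rate
  nu <- nu_m * stats::dbinom(seq_len(N_c), N_c, c)
  nu[1] <- nu[1] + (N - N_c) * rate
  correlation_structure(nu)
}

#' Summed spike counts per time step
#'
#' @param counts vector of summed spike counts per step (may be fractional
#'   when per-neuron amplitude weighting has been applied).
#' @param dt time step in seconds.
#' @return An object of class `"spike_counts"` with elements `counts`,
#'   `dt` and `T` (duration in seconds).
#' @export
spike_counts <- function(counts, dt) {
  stopifnot(is.numeric(counts), length(counts) >= 1L, dt > 0)
  structure(list(counts = counts, dt = dt, T = length(counts) * dt),
            class = "spike_counts")
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf(
    "<spike counts>  %d steps of %g s (T = %g s), total = %g events\n",
    length(x$counts), x$dt, x$T, sum(x$counts)))
  invisible(x)
}

#' Simulate compound-Poisson population spike counts
#'
#' Draws, for each order `n` with \eqn{\nu_n > 0}, carrier events as a
#' homogeneous Poisson process of rate \eqn{\nu_n} on `[0, T)`; each event
#' adds `n` to the count of the time step it falls in.
#'
#' @param structure a [correlation_structure()].
#' @param T duration in seconds (include the warm-up of the subsequent
#'   filtering step).
#' @param dt time step in seconds.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A [spike_counts()] object.
#' @examples
#' z <- simulate_cpp(correlation_structure(c(100, 5)), T = 2, dt = 1e-3,
#'                   seed = 1)
#' sum(z$counts) / 2  # about 100 + 2*5 events/s
#' @export
simulate_cpp <- function(structure, T, dt, seed = NULL) {
  stopifnot(inherits(structure, "correlation_structure"), T > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  nbins <- as.integer(round(T / dt))
  counts <- if (structure[1] > 0) {
    stats::rpois(nbins, structure[1] * dt)
  } else numeric(nbins)
  for (n in which(structure > 0)) {
    if (n == 1L) next
    m <- stats::rpois(1L, structure[n] * T)
    if (m == 0L) next
    b <- bin_index(stats::runif(m, 0, T), dt, nbins)
    add <- rowsum(rep.int(as.numeric(n), m), b)
    idx <- as.integer(rownames(add))
    counts[idx] <- counts[idx] + add[, 1L]
  }
  spike_counts(counts, dt)
}

bin_index <- function(t, dt, nbins) {
  pmin.int(pmax.int(floor(t / dt) + 1, 1L), nbins)
}

#' Simulate a per-neuron spike raster with synchronous events
#'
#' Realizes the population of a [population_spec()] as individual spike
#' trains: synchronous order-`order` events are drawn at the carrier rate
#' from [build_structure()] and each event is assigned to `order` distinct
#' neurons drawn uniformly from the correlated subpopulation (neurons
#' `1..N_c`); independent spikes are added so that every neuron's marginal
#' rate is `rate`.
#'
#' @inheritParams simulate_cpp
#' @param spec a [population_spec()].
#' @param T duration in seconds.
#' @return A `data.frame` with columns `neuron` (integer id in `1..N`) and
#'   `time` (seconds), unsorted.
#' @seealso [bin_raster()], [apply_jitter()]
#' @export
simulate_raster <- function(spec, T, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"), T > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- spec$N; lam <- spec$rate
  neuron <- integer(0); time <- numeric(0)
  rate_ind <- rep(lam, N)
  if (spec$c > 0) {
    st <- build_structure(spec)
    n <- spec$order
    nu_n <- st[n]
    m <- stats::rpois(1L, nu_n * T)
    if (m > 0L) {
      ev_t <- stats::runif(m, 0, T)
      members <- vapply(seq_len(m),
                        function(i) sample.int(spec$N_c, n),
                        integer(n))
      neuron <- as.integer(members)
      time <- rep(ev_t, each = n)
    }
    # pool neurons receive part of their rate through coincidences
    rate_ind[seq_len(spec$N_c)] <- lam - n * nu_n / spec$N_c
    if (any(rate_ind < -1e-12))
      stop("correlated rate exceeds the per-neuron rate")
    rate_ind <- pmax(rate_ind, 0)
  }
  k <- stats::rpois(N, rate_ind * T)
  tot <- sum(k)
  if (tot > 0L) {
    neuron <- c(neuron, rep.int(seq_len(N), k))
    time <- c(time, stats::runif(tot, 0, T))
  }
  data.frame(neuron = neuron, time = time)
}

#' Bin a raster into summed spike counts
#'
#' @param raster a `data.frame` with columns `neuron` and `time`.
#' @param T duration in seconds (defines the number of bins).
#' @param dt time step in seconds.
#' @return A [spike_counts()] object with the population-summed counts.
#' @export
bin_raster <- function(raster, T, dt) {
  stopifnot(is.data.frame(raster), T > 0, dt > 0)
  nbins <- as.integer(round(T / dt))
  counts <- tabulate(bin_index(raster$time, dt, nbins), nbins)
  spike_counts(counts, dt)
}

#' Jitter spike times uniformly
#'
#' Adds an independent displacement drawn from a uniform distribution on
#' `[-j, +j]` to every spike time, modeling imprecise synchrony.  Spikes
#' are jittered before binning; displaced times are clipped to
#' `[0, t_max)` so no spike is lost (the filtering warm-up absorbs the
#' boundary distortion).
#'
#' @param raster a `data.frame` with columns `neuron` and `time`.
#' @param j jitter half-width in seconds (`j = 0` returns the input).
#' @param t_max upper clip bound in seconds (default: leave the upper end
#'   unclipped).
#' @param seed optional integer seed.
#' @return The raster with jittered times.
#' @export
apply_jitter <- function(raster, j, t_max = Inf, seed = NULL) {
  stopifnot(is.data.frame(raster), j >= 0)
  if (j == 0) return(raster)
  if (!is.null(seed)) set.seed(seed)
  t <- raster$time + stats::runif(nrow(raster), -j, j)
  raster$time <- pmin(pmax(t, 0), t_max - .Machine$double.eps * t_max)
  raster
}

#' Simulate correlated non-Poisson (lognormal-ISI) population counts
#'
#' Two constructions are available, both imposing the synchrony by copying
#' carrier-event times into the participating neurons' trains so that the
#' correlation structure matches the corresponding Poisson construction
#' while single-train statistics do not:
#'
#' * `structure = "pairwise"`: single-neuron background spiking is a
#'   renewal process with lognormal inter-spike intervals (mean interval
#'   `1/rate`, coefficient of variation `isi_cv`); order-`order`
#'   synchronous events from [build_structure()] are copied into randomly
#'   chosen subpopulation trains on top of (rate-reduced) backgrounds.
#' * `structure = "binomial"`: a multiple-interaction construction whose
#'   carrier ("mother") process is a lognormal renewal process of rate
#'   `rate / c`; each mother spike is copied into each of the `N_c` pool
#'   neurons independently with probability `c`, yielding the
#'   binomial-shaped correlation structure of
#'   [build_structure_binomial()]; neurons outside the pool are
#'   independent lognormal renewal trains.
#'
#' @inheritParams simulate_raster
#' @param dt time step in seconds for the returned counts.
#' @param raster if `TRUE`, also return the per-neuron raster.
#' @param structure correlation-structure construction, see Details.
#' @return A [spike_counts()] object, or (with `raster = TRUE`) a list
#'   with elements `counts` and `raster`.
#' @export
simulate_nonpoisson <- function(spec, T, dt, seed = NULL, raster = FALSE,
                                structure = c("pairwise", "binomial")) {
  structure <- match.arg(structure)
  stopifnot(inherits(spec, "population_spec"), T > 0, dt > 0)
  if (is.null(spec$isi_cv)) stop("spec$isi_cv must be set (lognormal CV)")
  if (!is.null(seed)) set.seed(seed)
  N <- spec$N; lam <- spec$rate; cv <- spec$isi_cv
  rate_ind <- rep(lam, N)
  neuron <- integer(0); time <- numeric(0)
  if (structure == "binomial") {
    if (spec$c <= 0) stop("the binomial construction needs c > 0")
    ev_t <- lognormal_renewal(lam / spec$c, cv, T)
    if (length(ev_t)) {
      sizes <- stats::rbinom(length(ev_t), spec$N_c, spec$c)
      keep <- sizes > 0L
      ev_t <- ev_t[keep]; sizes <- sizes[keep]
      neuron <- as.integer(unlist(lapply(sizes, function(s)
        sample.int(spec$N_c, s))))
      time <- rep(ev_t, times = sizes)
    }
    rate_ind[seq_len(spec$N_c)] <- 0  # pool rate comes from the mother
  } else if (spec$c > 0) {
    st <- build_structure(spec)
    n <- spec$order
    nu_n <- st[n]
    m <- stats::rpois(1L, nu_n * T)
    if (m > 0L) {
      ev_t <- stats::runif(m, 0, T)
      members <- vapply(seq_len(m),
                        function(i) sample.int(spec$N_c, n),
                        integer(n))
      neuron <- as.integer(members)
      time <- rep(ev_t, each = n)
    }
    rate_ind[seq_len(spec$N_c)] <- pmax(lam - n * nu_n / spec$N_c, 0)
  }
  for (i in seq_len(N)) {
    if (rate_ind[i] <= 0) next
    ti <- lognormal_renewal(rate_ind[i], cv, T)
    if (length(ti)) {
      neuron <- c(neuron, rep.int(i, length(ti)))
      time <- c(time, ti)
    }
  }
  ras <- data.frame(neuron = neuron, time = time)
  cnt <- bin_raster(ras, T, dt)
  if (raster) list(counts = cnt, raster = ras) else cnt
}

# spike times of a lognormal renewal process on [0, T); the first interval
# starts at a uniform random phase-like offset drawn as a plain interval
lognormal_renewal <- function(rate, cv, T) {
  mu_isi <- 1 / rate
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mu_isi) - sdlog^2 / 2
  times <- numeric(0)
  t_last <- 0
  chunk <- max(32L, ceiling(rate * T * 1.2 + 6 * sqrt(rate * T) * (1 + cv)))
  repeat {
    isi <- stats::rlnorm(chunk, meanlog, sdlog)
    tt <- t_last + cumsum(isi)
    times <- c(times, tt)
    t_last <- times[length(times)]
    if (t_last >= T) break
    chunk <- max(32L, ceiling((T - t_last) * rate * 1.5))
  }
  times[times < T]
}

#' Add an independent inhibitory population to a trace
#'
#' Simulates `N` independent Poisson spike trains at `inhib_rate` spikes/s
#' each, filters their summed counts with the same kernel as the
#' excitatory activity but with opposite sign, and adds the result onto
#' the excitatory trace.
#'
#' @param trace the excitatory [shot_noise_trace()].
#' @param spec a [population_spec()] providing `N` and `inhib_rate`.
#' @param kernel the (excitatory) kernel; its sign is flipped internally.
#' @param warmup warm-up in seconds used for the inhibitory trace (should
#'   match the excitatory one).
#' @param seed optional integer seed.
#' @return A [shot_noise_trace()] of the mixed signal.
#' @export
mix_inhibition <- function(trace, spec, kernel, warmup = 1, seed = NULL) {
  stopifnot(inherits(trace, "cubicm_trace"),
            inherits(spec, "population_spec"),
            inherits(kernel, "cubicm_kernel"))
  if (spec$inhib_rate == 0) return(trace)
  if (!is.null(seed)) set.seed(seed)
  dt <- trace$dt
  rate_tot <- spec$N * spec$inhib_rate
  n_tot <- as.integer(round(warmup / dt)) + trace$L
  cnt <- stats::rpois(n_tot, rate_tot * dt)
  neg <- kernel
  neg$A <- -kernel$A
  inh <- filter_counts(cnt, neg, warmup = warmup, dt = dt)
  shot_noise_trace(trace$samples + inh$samples, dt)
}

#' Filter a raster with heterogeneous per-neuron amplitudes
#'
#' Each neuron's spike train is filtered with its own kernel amplitude
#' \eqn{A_i} drawn from a lognormal distribution with mean `kernel$A` and
#' the requested coefficient of variation; the trace is the sum of the
#' per-neuron filtered trains.  Because all neurons share the kernel time
#' course, this is computed by amplitude-weighted binning followed by a
#' single unit-amplitude filtering pass.
#'
#' @param raster a `data.frame` with columns `neuron` and `time`.
#' @param N number of neurons (amplitudes are drawn for ids `1..N`).
#' @param kernel kernel whose amplitude is the mean of the lognormal.
#' @param amplitude_cv coefficient of variation of the amplitudes
#'   (`0` reproduces [filter_counts()] on the summed counts).
#' @param T duration in seconds covered by the raster.
#' @param dt time step in seconds.
#' @param warmup warm-up in seconds excluded from the output.
#' @param seed optional integer seed.
#' @return A [shot_noise_trace()].
#' @export
heterogeneous_amplitude_filter <- function(raster, N, kernel, amplitude_cv,
                                           T, dt, warmup = 1, seed = NULL) {
  stopifnot(is.data.frame(raster), amplitude_cv >= 0, T > 0, dt > 0,
            inherits(kernel, "cubicm_kernel"))
  if (kernel$A <= 0)
    stop("heterogeneous amplitudes require a positive mean amplitude")
  if (!is.null(seed)) set.seed(seed)
  if (amplitude_cv == 0) {
    amp <- rep(kernel$A, N)
  } else {
    sdlog <- sqrt(log(1 + amplitude_cv^2))
    meanlog <- log(kernel$A) - sdlog^2 / 2
    amp <- stats::rlnorm(N, meanlog, sdlog)
  }
  nbins <- as.integer(round(T / dt))
  w <- numeric(nbins)
  b <- bin_index(raster$time, dt, nbins)
  add <- rowsum(amp[raster$neuron], b)
  idx <- as.integer(rownames(add))
  w[idx] <- add[, 1L]
  unit <- kernel
  unit$A <- 1
  filter_counts(w, unit, warmup = warmup, dt = dt)
}
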