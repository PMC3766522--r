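---
title: "Inferring higher-order input correlations from a single filtered signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring higher-order input correlations from a single filtered signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubicm)
```

## The problem

A neuron's subthreshold membrane potential is shaped by the spikes of its
entire presynaptic population — typically thousands of cells, far more
than any extracellular array can record, and sampled exactly as the neuron
itself "sees" them.  If groups of presynaptic neurons fire synchronously,
those coincidences leave a statistical fingerprint in the membrane
potential: they fatten the right tail of its amplitude distribution.
This package infers, from a single uniformly sampled trace, a lower
confidence bound on the *maximal order of correlation* among the
presynaptic spike sources: the largest group size that fires in precise
synchrony at a nonzero rate.

## Model

The summed presynaptic spike activity is modeled as a compound Poisson
process (CPP)
$$Z(t) = \sum_n n\, Y_n(t),$$
where each carrier process $Y_n$ is an independent Poisson process of rate
$\nu_n$ and each of its events represents $n$ neurons spiking together.
The vector $(\nu_1, \nu_2, \ldots)$ is the *correlation structure*, and
$\xi = \max\{n : \nu_n > 0\}$ the maximal order of correlation.  The
subthreshold signal is shot noise: the spike activity convolved with a
fixed postsynaptic kernel, $S = Z \ast \phi$.  For a leaky-integrator
membrane with pulse-like synaptic currents, $\phi(t) = A e^{-t/\tau}$ with
postsynaptic-potential amplitude $A$ (signal units per spike) and membrane
time constant $\tau$ (seconds).  Binning spikes is the special case of a
rectangular kernel read out at multiples of its width, which is how this
signal-level analysis connects to population spike counts.

The key relation is the Campbell-type cumulant formula
$$\kappa_m[S] = \sum_n n^m \nu_n \int \phi^m,$$
so an order-$n$ event enters the $m$-th cumulant with weight $n^m$:
higher cumulants are progressively more sensitive to higher orders of
synchrony, and the first three cumulants already carry usable information
about $\xi$.

## The test

For each candidate order $k = 1, 2, \ldots$ the null hypothesis
$H_0^k$ states that the measured first three sample cumulants
$(k_1, k_2, k_3)$ are consistent with correlations of order at most $k$.
Given $(k_1, k_2)$, the largest third cumulant any such structure can
produce is found by maximizing $\sum_{n \le k} n^3 \nu_n \int\phi^3$
subject to the first two cumulant constraints and $\nu \ge 0$.  The
optimum concentrates on orders $1$ and $k$ and is available in closed form
(`h0_bound()`); the package's tests verify it against an exact
vertex-enumeration solution of the same linear program.  For the
exponential kernel the bound is independent of $\tau$ — only $A$ matters
for the bound itself.

The observed $k_3$ is compared against this bound with a one-sided
Gaussian test, $p_k = 1 - \Phi((k_3 - \kappa^*_{3,k}) / \sigma^*_k)$,
where $\sigma^{*2}_k$ is the classical finite-sample variance of the third
k-statistic evaluated at the null-optimal cumulants up to order six.
Scanning upward, the reported bound is
$\hat\xi = \min\{k : H_0^k \text{ not rejected}\}$.

### Correction for correlated samples

The k-statistic variance formula assumes independent samples, but kernel
overlap makes consecutive samples of $S$ strongly dependent at
millisecond sampling, so $\sigma^*_k$ underestimates the true sampling
spread of $k_3$ and the uncorrected test over-rejects.  The remedy
(`correction_factor()`) estimates the underestimation ratio on matched
surrogates: the independent-input rate is approximated by
$\lambda = k_1 / \int\phi$, 20 Poisson shot-noise traces with the same
kernel, sampling interval, warm-up and length are simulated, and
$f_c = \mathrm{sd}(k_3) / \sigma^*_1$ rescales every $\sigma^*_k$ in the
scan.  The relative bias is assumed to be order-independent, so $f_c$ is
computed once per trace.  By default the reference $\sigma^*_1$ comes from
the surrogates' own mean $(k_1, k_2)$, which isolates the
sample-correlation effect; `sigma_ref = "data"` uses the data cumulants
instead (the two differ negligibly in practice).

A caveat worth stating explicitly: in our reference simulations of an
independent population (200 neurons at 10 spikes/s, $\tau$ = 10 ms,
20 kHz, 50 s) the iid formula understates the spread of $k_3$ by roughly
an order of magnitude, so the uncorrected test rejects far more often
than its nominal level — the acceptance script reports this fraction —
while the corrected test holds the level.  The uncorrected variant is
retained only as a diagnostic of that effect.

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `dt` | sampling interval (s) | `5e-5` (20 kHz, typical intracellular rate) |
| `warmup` | discarded onset transient (s) | `1` |
| `alpha` | per-order significance level | `0.05` |
| `n_surrogates` | surrogate traces for $f_c$ | `20` |
| `k_max` | scan ceiling; hitting it censors the result | `1000` |
| `resting` | resting offset $U_r$ subtracted before analysis | `0` |

The kernel must be supplied by the analyst ($A$, $\tau$, family).  Errors
in $\tau$ act only through the correction surrogates and are benign;
errors in $A$ bias $\hat\xi$ directly (underestimating $A$ inflates it),
and a mis-subtracted resting offset biases it through $k_1$ — both
directions are exercised by the robustness tests.

## The synthetic-data generator

`population_spec()` describes a population of $N$ neurons firing at
$\lambda$ spikes/s each, with a subpopulation of $N_c$ carrying
synchronous events of one order whose rate is set from the pairwise count
correlation coefficient $c$ by inverting
$\nu_{\mathrm{order}} = c \lambda N_c (N_c - 1) / (\mathrm{order}
(\mathrm{order} - 1))$; the independent rate $\nu_1$ is chosen so every
neuron's marginal rate is exactly $\lambda$ (correlated neurons receive
correspondingly less independent drive).  Event membership is re-drawn
uniformly per event, making all pool pairs exchangeable.  A second
builder, `build_structure_binomial()`, produces the binomial-shaped
(multiple-interaction) structure in which each carrier event is copied
into each pool neuron with probability $p = c$; this is the natural model
for diffuse synchrony across a large pool, where a single-order structure
at the same $(c, N_c)$ would be infeasible.

Robustness variants: uniform spike-time jitter on $[-j, +j]$ applied
before binning (clipped at the segment edges; the warm-up absorbs the
boundary distortion); lognormal-ISI renewal single-neuron trains with
synchrony imposed by copying carrier events into the trains (or, in the
binomial mode, a lognormal-renewal mother process); per-neuron kernel
amplitudes drawn from a lognormal with fixed mean and chosen CV; and an
independent inhibitory population filtered with the sign-flipped kernel.
Note that the inhibitory rate ratio must stay below 1, otherwise the net
mean — and with it the correction's implied rate — becomes non-positive
and the method's own correction procedure is undefined.

What the generator does *not* emulate: conductance-based synapses,
dendritic filtering and active channels, excitatory–inhibitory
correlations, and non-stationary rates.  Passing tests on these surrogates
therefore validates the statistical machinery under the stated model, not
the model's adequacy for any particular recording.

## Numerical choices

* Spikes are binned to the sampling grid (floor convention) before
  filtering; exponential filtering uses the exact-integration recursion
  $s_i = s_{i-1} e^{-\Delta t/\tau} + A n_i$ (a C-level recursive filter),
  rectangular and alpha kernels use FFT convolution with the sampled
  kernel.  The tests verify recursion–convolution agreement to $10^{-9}$.
* The sampled-grid stationary cumulants replace $\int\phi^m$ by
  $\Delta t \sum_i \phi(i\Delta t)^m$; at 20 kHz and $\tau \ge 5$ ms the
  relative difference is below 1 % and is shared by data and surrogates,
  so it cancels from the test's calibration.
* The alpha kernel is parameterized as a peak-normalized difference of
  exponentials $B(e^{-t/\tau} - e^{-t/\tau_\alpha})$, $\tau_\alpha <
  \tau$, with peak time $\tau\tau_\alpha\log(\tau/\tau_\alpha) /
  (\tau - \tau_\alpha)$ and peak value $A$; its power integrals are closed
  form by binomial expansion.  Peak normalization implies an intrinsic
  $(\tau_\alpha/\tau)\log(\tau/\tau_\alpha)$ deviation from the
  exponential limit, so convergence in $\tau_\alpha$ is logarithmically
  slowed (a few percent at $\tau_\alpha = \tau/1000$ for high powers).
* Degenerate corners of the bound are clamped conservatively: a
  sub-Poisson signal ($k_2/\!\int\!\phi^2 < k_1/\!\int\!\phi$) forces the
  order-$k$ rate to zero, and a negative implied $\nu_1$ moves all mass to
  order $k$; both choices lower the bound and can only make the test more
  conservative.  At $k = 1$ the two constraints cannot both be satisfied
  by a single rate; the bound uses the continuous extension of the
  $k \ge 2$ formula, validated against the linear-programming oracle.
* Kernels with $\int\phi^3 < 0$ (inhibitory input) are handled by
  sign-flipping trace and kernel, which maps the third-cumulant
  minimization onto the implemented maximization.
* The scan increments $k$ by one with no early exit; a scan that
  exhausts `k_max` is flagged `censored` and is a statement
  "$\hat\xi \ge k_\max$", never a valid bound.
* All randomness is consumed from R's global stream; passing `seed`
  seeds it and derives a separate surrogate seed, so one seed reproduces
  an entire analysis byte-for-byte (JSON reports contain no timestamps).

## Problem sizes used in the tests

The validation suite runs the reference study designs at these sizes:
type-I error with 200 repetitions uncorrected and 100 corrected; order-20
recovery (1000 neurons, $c = 0.05$, $\tau$ = 20 ms, 60 s) with 50
repetitions; order-40 recovery (10000 neurons, $c = 0.02$, $\tau$ = 5 ms,
100 s) with 20 repetitions; downsampling and directional-robustness
checks with 50 and 6 repetitions respectively, the latter as paired
three-point designs (the same realization analyzed at all three parameter
values) to maximize power per simulation.  Monte-Carlo oracles use
$10^4$ replicates.

## Known limitations

* The bound is a *lower* confidence limit: jitter at or above $\tau$,
  non-Poisson single-neuron statistics at long $\tau$, or admixed
  inhibition all push $\hat\xi$ down, never invalidating the bound's
  direction but reducing sensitivity.
* The method reports only $\hat\xi$, not the full correlation structure.
* Stationarity is assumed throughout; strongly co-fluctuating rates can
  masquerade as synchrony.
* The Gaussian approximation for $k_3$ requires long traces; below a few
  seconds of data at 20 kHz the per-order p-values become unreliable.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
spec <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20,
                        rate = 5)
ker <- exp_kernel(A = 1, tau = 0.020)
z <- simulate_cpp(build_structure(spec), T = 61, dt = 5e-5)
trace <- filter_counts(z, ker, warmup = 1)
cubicm(trace, ker, seed = 2)
```

The printed result shows the sample cumulants, the correction factor and
the first non-rejected order — the inferred lower bound on the maximal
order of synchrony seen by the neuron.
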