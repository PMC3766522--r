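# cubicm

Cumulant-based inference of higher-order spike correlations from
subthreshold membrane potentials.

## What it does, and for whom

Groups of presynaptic neurons firing in precise synchrony leave a
statistical fingerprint in the postsynaptic membrane potential.  `cubicm`
analyzes a single uniformly sampled subthreshold trace — no multi-electrode
recording, no spike sorting — and returns a lower confidence bound
$\hat\xi$ on the **maximal order of correlation** among the presynaptic
spike sources: the largest group size that fires synchronously at a
nonzero rate.  It is aimed at electrophysiologists with intracellular
(or any linearly filtered spike-driven) recordings and at modelers
studying higher-order synchrony.

## The model and the statistic

The summed presynaptic activity is a compound Poisson process
$Z(t) = \sum_n n Y_n(t)$, where each carrier $Y_n$ is Poisson with rate
$\nu_n$ and an event of $Y_n$ is a synchronous spike of $n$ neurons;
$\xi = \max\{n : \nu_n > 0\}$.  The trace is shot noise
$S = Z \ast \phi$ with a fixed postsynaptic kernel, for a leaky
integrator $\phi(t) = A e^{-t/\tau}$.  Its cumulants obey
$\kappa_m[S] = \sum_n n^m \nu_n \int \phi^m$, so synchrony of order $n$
is amplified $n^m$-fold in the $m$-th cumulant.

For each $k = 1, 2, \ldots$ the test asks whether the measured sample
cumulants $(k_1, k_2, k_3)$ are consistent with correlations of order at
most $k$: the largest third cumulant such a structure allows,
$\kappa^*_{3,k}$, is computed in closed form from $(k_1, k_2)$, and
$p_k = 1 - \Phi\bigl((k_3 - \kappa^*_{3,k}) / (f_c\,\sigma^*_k)\bigr)$.
$\sigma^*_k$ is the finite-sample standard deviation of the third
k-statistic under the null, and $f_c$ is a simulation-based correction
for the fact that trace samples are temporally correlated (kernel
overlap), estimated from 20 matched independent-Poisson surrogates.
The bound is $\hat\xi = \min\{k : p_k > \alpha\}$.

## Worked example

Simulate a 60 s membrane potential driven by 1000 Poisson neurons at
5 spikes/s, of which 100 carry order-20 synchronous events at pairwise
correlation 0.05, then analyze it with the true kernel:

```r
library(cubicm)
set.seed(1)
spec  <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20,
                         rate = 5)
ker   <- exp_kernel(A = 1, tau = 0.020)
z     <- simulate_cpp(build_structure(spec), T = 61, dt = 5e-5)
trace <- filter_counts(z, ker, warmup = 1)
cubicm(trace, ker, seed = 2)
```

```
Cumulant-based inference of the maximal order of correlation
  L = 1200000 samples at dt = 5e-05 s, alpha = 0.05
  k1 = 100.05, k2 = 75.786, k3 = 382.26
  correction factor f_c = 14.56
  xi_hat = 17  (p_17 = 0.1315 > alpha)
```

Reading the output: the mean trace level is $k_1 \approx 100$ (5000
spikes/s times $A\tau = 0.02$); the elevated third cumulant
($k_3 = 382$ versus $\approx 33$ for a purely independent population)
rejects every null up to order 16, so at least order-17 synchrony is
present — a lower bound close to the true order 20.  The correction
factor 14.6 is the measured inflation of the sampling spread of $k_3$
caused by correlated samples at 20 kHz with $\tau = 20$ ms.

A command-line wrapper is installed with the package
(`inst/exec/cubicm`) with `simulate`, `infer` and `reproduce`
subcommands; `run_reproduction()` reruns the packaged simulation studies
(type-I error, sensitivity, jitter, non-Poisson inputs, robustness).

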