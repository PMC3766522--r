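Package: cubicm
Title: Inference of Higher-Order Spike Correlations from Subthreshold
    Membrane Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a lower confidence bound on the maximal order of
    correlation among the presynaptic spike sources of a neuron from a
    single filtered signal, typically the subthreshold membrane potential.
    The signal is modeled as compound-Poisson shot noise (summed population
    spike activity convolved with a fixed postsynaptic-potential kernel),
    whose cumulants are weighted sums of the rates of synchronous events of
    each order.  A sequence of hypothesis tests on the third sample
    cumulant, with an analytic upper bound under the null of correlations
    up to order k and a simulation-based correction for temporally
    correlated samples, yields the bound.  Includes a population simulator
    for correlated Poisson and non-Poisson spike trains with jitter,
    heterogeneous synaptic amplitudes and inhibitory admixture, used to
    validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
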