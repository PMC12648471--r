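Package: insdyn
Title: Analysis of Infrared Neural Stimulation Evoked Thalamocortical Dynamics
Version: 0.1.0
Authors@R:
    person("INS", "Dynamics Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify local field potential (LFP) and single-unit
    dynamics evoked by pulsed infrared neural stimulation (INS) of the
    auditory thalamus. Implements evoked N1-P2 dose-response feature
    extraction, continuous-wavelet band-power statistics, temporal
    modulation transfer functions at the interpulse-interval frequency,
    a modified 0-1 test for chaos with a permutation-entropy
    stochasticity gate, bias-corrected stimulus-response mutual
    information, spike-field coherence, and Bayesian hierarchical and
    piecewise (knotted) regressions sampled by Gibbs/Metropolis MCMC.
    A synthetic-data generator emulates the trial structure of chronic
    INS recordings with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
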