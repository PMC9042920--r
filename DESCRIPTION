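Package: pepasync
Title: Asynchronous Decoding of Perturbation-Evoked Potentials from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and asynchronous decoding of perturbation-evoked
    potentials (PEPs) in continuous EEG. Provides a synthetic cockpit-EEG
    generator for an oddball tilt paradigm (standard 1.5 degree movements
    interleaved with rare 5/10 degree left/right perturbations), a causal
    preprocessing chain (notch, band-pass, downsampling, bad-channel handling,
    common average reference, epoch rejection, high-variance electrode artifact
    removal), bilinear common spatial pattern (BCSP) features, Fisher-score
    feature selection, a two-stage hierarchical RBF-SVM decoder, a simulated
    online sliding-window detection engine with refractory logic and F1-optimal
    threshold search, and channel-level statistics (signed r-squared maps,
    interval-based one-sided Wilcoxon rank-sum tests with Bonferroni
    correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
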