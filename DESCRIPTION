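Package: spikeassembly
Title: Multi-Timescale Cell Assembly Detection in Multivariate Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cell assemblies -- groups of neurons whose spiking forms
    recurring supra-chance patterns with specific time-lag constellations --
    in multivariate spike-time recordings, across a user-chosen range of
    temporal scales (bin widths). Pairwise dependence between spike-count
    series is assessed with a parametric test built on the first two moments
    of a multivariate hypergeometric distribution, corrected for slow firing
    rate (co-)fluctuations by differencing the forward-lag joint count
    against a reference-lag count and estimating the variance over short
    segments. Significant pairs are agglomerated recursively into
    higher-order assemblies under strict Bonferroni budgeting. Includes an
    inhomogeneous-Poisson ground-truth simulator with five embedded assembly
    archetypes, spike sorting-error corruption, and partition-agreement
    evaluation metrics (Rand index, retrieval score, assignment matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
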