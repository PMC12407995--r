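Package: edgeproject
Title: Discover-Then-Project Mapping of Connectome-Behavior Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-wise general linear model discovery of functional network
    connectivity and behavior associations in a large reference cohort, with
    Benjamini-Hochberg false-discovery-rate selection, permutation validation
    and bootstrap subsampling sensitivity analysis; constrained projection of
    the discovered edge set onto symptom scales in an independent target
    cohort; and tapered sliding-window dynamic connectivity analysis with
    k-means state clustering, elbow model selection, occupancy rates and
    occupancy-symptom regressions. Includes seeded synthetic multi-subject
    cohort generators with known ground truth (planted edge-behavior
    couplings and Markov regime-switching covariance states) so every stage
    of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
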