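Package: hotspotr
Title: Mutation-Spectrum and Hotspot-Potency Analysis for Bacterial
    Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mutational-hotspot potency in replicated
    evolution experiments. Parses point-mutation and deletion labels, classifies
    substitutions as transitions or transversions, builds mutation spectra per
    strain with a documented categorization policy, compares spectra by Pearson
    chi-square with asymptotic and fixed-margin Monte-Carlo p-values, tests
    transition enrichment or omission against the 1/3 combinatorial null with a
    bootstrap resampler and its exact binomial oracle, provides rank-based
    time-to-emergence comparisons (Kruskal-Wallis, Dunn, Wilcoxon rank-sum)
    implemented from formulas with tie corrections, and simulates replicate
    evolution experiments under a first-arrival model with exponential waiting
    times, mismatch-repair suppression of transitions and a censoring horizon,
    including hotspot-multiplier parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
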