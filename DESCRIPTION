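Package: icodiff
Title: Difference Mapping and Occupancy Analysis for Icosahedral Cryo-EM
    Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of icosahedrally symmetric
    single-particle cryo-EM reconstructions, built around the analysis used
    to localize substoichiometric proteins in dsRNA bacteriophage
    procapsids. Provides the icosahedral rotation group and its 5-/3-/2-fold
    axis sets, MRC2014 volume I/O, low-pass filtering and radial statistics,
    Fourier shell correlation with resolution-at-cutoff, intensity
    normalization by volume-matched thresholding against a protein mass
    budget with background-annulus standardization and radial scale factors,
    difference-map arithmetic with axis-constrained site detection, a
    fractional occupancy estimator referenced to the densest shell region,
    and a synthetic phantom generator producing mutant map triples with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
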