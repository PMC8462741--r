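Package: barseg
Title: Bayesian Change-Point Segmentation of Bisulfite Accessible Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bisulfite accessible regions (BARs) in single-molecule
    bisulfite-conversion matrices of immunoglobulin V genes. Implements a
    continuous-state Bayesian multiple change-point model with Beta-binomial
    conjugate forward/backward recursions that yields exact posterior
    accessibility means and change probabilities at every informative C site,
    together with Hamming-distance complete-linkage clustering of molecules,
    patch-size estimation under last-C and midpoint boundary definitions, and
    spatial correlation analyses relating BARs to somatic hypermutation
    hotspots and external per-site score tracks. Includes a synthetic-data
    generator with known piecewise-constant accessibility structure and an
    exact enumeration oracle for validating the recursions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
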