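Package: thinfilament
Title: Model Building, Density Simulation, Docking and Dissection of
    Muscle Thin Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the regulatory states of striated-muscle
    thin filaments at intermediate (~28 Angstrom) resolution. Builds
    parameterised pseudo-atomic models of the actin two-start helix with
    tropomyosin strands and staggered troponin complexes, simulates
    EM-like density maps with controlled noise, performs rigid-body
    global and localised per-subunit docking of component models,
    computes two-stage difference maps isolating tropomyosin and
    troponin, and quantifies per-pseudo-repeat tropomyosin azimuths,
    blocked/closed/myosin state calls, troponin stagger, axial spans and
    Fourier shell correlation. Includes a synthetic-data generator with
    ground-truth manifests for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
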