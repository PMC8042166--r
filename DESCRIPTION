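Package: ftszdyn
Title: Conformational-State and Assembly Analysis of FtsZ Filament Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterise the assembly dynamics of FtsZ-like
    protofilaments from multi-model PDB or XYZ trajectories: inter-subunit
    rotation decomposition (twist and bending angles in a filament-anchored
    frame), Shrake-Rupley solvent-accessible surface area and buried
    interface area, T/R subunit and open/closed interface classification
    with nucleation-species censuses, SVD-based free-energy landscapes with
    funnel detection, decorrelation-adjusted regression, anisotropic network
    model cross-correlation maps, and a synthetic filament-trajectory
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
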