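Package: fibwave
Title: High-Density Epicardial Mapping Analysis of Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-density epicardial contact mapping of
    atrial fibrillation (AF): ventricular far-field (QRST) cancellation and
    local activation-time detection on unipolar electrograms, neighbor-link
    conduction/block classification, local conduction velocity by activation
    plane fitting, circular-variance anisotropy, electrical dissociation and
    AF cycle-length metrics, fibrillation-wave reconstruction with
    peripheral/breakthrough origin classification, conduction-path and
    re-entry detection, and region/timepoint summary tables. Includes a
    synthetic atrial-propagation and electrogram generator (planar, colliding
    and focal wavefronts, conduction-block lines, rotors, ventricular
    far-field, noise) that supplies exact ground truth for every stage of the
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
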