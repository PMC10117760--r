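Package: caimseg
Title: Neuron Segmentation for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance segmentation of neuronal somata in motion-corrected
    two-photon calcium imaging movies. Converts videos into fused 2D images
    that combine the average projection with a Gaussian-weighted local
    correlation map, so that both anatomically visible and sparsely firing
    neurons are represented; segments neurons with a compact Mask R-CNN-style
    detector featuring efficient channel attention on the lateral connections
    of its feature pyramid and an augmented bottom-up pyramid path; evaluates
    detections against ground truth by IoU-based Hungarian matching with
    precision/recall/F1 reporting; and supports tiled inference for
    mesoscopic fields of view. Includes a ground-truthed synthetic movie
    generator (donut-shaped somata, sparsely firing and overlapping neurons)
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
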