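Package: nematrace
Title: Detection, Tracking and Identification of C. elegans Head Neurons
    from Volumetric Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts single-neuron activity traces and neuron identities from
    3D time-lapse calcium-imaging recordings of the Caenorhabditis elegans
    head. Nuclei are detected per volume with a 3D Laplacian-of-Gaussian
    filter, linked across frames by solving linear assignment problems
    (frame-to-frame linking, gap closing, and relative-distance track
    restoration), and positions of undetected neurons are inferred from the
    displacement of their closest neighbors. Tracked nuclei are refined to
    sub-voxel ellipsoid ROIs, background-corrected fluorescence traces are
    extracted, and a subset of head neurons (backward- and forward-locomotion
    command classes such as AVA, AVE, AIB, RIM, AVB, RIB, RME) is identified
    from activity correlations and spatial arrangement against a model atlas.
    Includes a ground-truth simulator of volumetric recordings and the
    detection-evaluation protocol (3 um matching, TP/(TP+FP+FN) accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
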