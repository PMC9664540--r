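Package: nodule4d
Title: Spatiotemporal Analysis of Osteoblast Morphology and Bone-Nodule
    Matrix Production in 4D Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("nodule4d", "developers", email = "nodule4d@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying in vitro bone nodule
    formation from two-channel (cell fluorescence + second harmonic
    generation collagen) 3D time-lapse stacks: preprocessing (median
    filter, local contrast, temporal differencing, drift registration),
    SHG surface and cell segmentation, lacuna extraction by regional
    minima, per-cell morphometrics (volume, surface area, Wadell
    sphericity, oblateness, prolateness), compartment classification
    (IN/ON vs OUT) by concave boundary and point-in-polygon, crowding by
    Delaunay triangulation, subROI correlation of high-sphericity cell
    counts with matrix increase, membrane bleb detection/tracking with
    duration, area and polarity readouts, cell motility, the statistical
    toolbox used for these readouts, and a ground-truthed synthetic
    4D scene generator that makes every stage testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
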