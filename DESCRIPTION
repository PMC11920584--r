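Package: rootcarve
Title: Refraction-Corrected Octree Space Carving for Hydroponic Root Volume
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nondestructive estimation of plant root volume and biomass
    density from turntable silhouette images of roots grown in transparent
    cylindrical hydroponic canisters. Camera poses are recovered from
    fiducial-marker correspondences (PnP), silhouettes are extracted with a
    hybrid Otsu/hysteresis pipeline, per-pixel viewing rays are refracted
    through the air-acrylic-water interfaces of the canister with Snell's
    law, and an octree mark-and-refine space carver intersects the refracted
    silhouette cones into a visual hull whose occupied-voxel volume converts
    to millilitres and, with wet-mass measurements, to g/mL densities. A
    synthetic-scene generator forward-renders analytic shapes through the
    same optical model so the whole pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++11
Config/testthat/edition: 3
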