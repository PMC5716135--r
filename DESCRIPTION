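Package: scintQA
Title: Binary Multileaf Collimator Delivery Verification with a
    Scintillator-Camcorder System
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image-based quality assurance of the binary multileaf
    collimator (MLC) of a helical tomotherapy unit. The package simulates the
    measurement obtained by filming a cylindrical plastic scintillator with an
    ordinary camcorder during a delivery, and implements the full analysis
    pipeline that turns the recorded light frames back into a delivery
    sinogram: region-of-interest photometry with background subtraction,
    image back-rotation to the gantry reference frame, light-to-open-time
    calibration with lateral-profile and output-drift corrections,
    ROC/Youden threshold selection for the open/closed decision, sinogram
    reconstruction, and scoring of the reconstruction against the planned
    sinogram.  A gantry rotational-stability analysis based on tracking the
    edge of a narrow beam across frames is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
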