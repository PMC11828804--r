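Package: oxyzone
Title: Oxygen Zonation-on-Chip Transport Modelling and Ratiometric Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for two-layer PDMS liver zonation-on-chip
    devices. Solves steady and transient oxygen and glucose transport on a
    multi-material finite-volume grid (laminar chamber flow, partition
    coefficient at the PDMS/medium interface, Michaelis-Menten cellular
    oxygen consumption with a necrosis cutoff), computes wall shear stress
    from the plane-Poiseuille closed form, implements the two-site
    Stern-Volmer ratiometric oxygen sensing pipeline (calibration, ROI ratio
    extraction, inversion, QC flagging, response time), and quantifies
    zone-wise biology (viability, albumin relative fluorescence, one-way
    ANOVA). A synthetic-data generator produces sensor image stacks and
    zone-graded staining images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    tiff,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
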