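Package: tensiongrad
Title: Quantification of Plasma-Membrane Tension Gradients from FLIM of Flipper-TR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spatial gradients of plasma-membrane tension
    measured with the mechanosensitive lifetime probe Flipper-TR. Estimates
    per-pixel fluorescence lifetimes from TCSPC photon-arrival data (barycenter
    "fast lifetime" and bi-exponential reconvolution fits), builds masked and
    median-filtered lifetime images, quantifies lifetime gradients against
    distance transforms of segmentation masks (decay profiles, slope fits,
    front/rear regions, aligned average maps, condition-difference maps),
    derives edge kinematics and lifetime-velocity coupling from mask movies,
    analyses supported-lipid-bilayer spreading, performs line-scan fluctuation
    spectroscopy (ACF/pCF) and FRAP kinetics, and converts MALDI mass
    spectrometry imaging channel stacks into normalized lipid-fraction maps.
    A seeded synthetic-data generator produces every input modality with known
    ground truth so that each stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    class
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
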