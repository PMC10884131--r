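Package: acspect
Title: CT-Less Attenuation Correction for Myocardial Perfusion SPECT via
    Cycle-Consistent SPECT-to-PET Translation
Version: 0.1.0
Authors@R:
    person("acspect", "maintainers", email = "acspect@example.org",
           role = c("aut", "cre"))
Description: Simulates paired reference (PET-like) and attenuated
    (SPECT-like) left-ventricular short-axis perfusion image stacks with
    known segment-level ground truth, trains a cycle-consistent
    image-to-image translation model that generates attenuation-corrected
    ("PET-like") images from non-attenuation-corrected SPECT input, and
    quantifies the correction with AHA 17-segment polar-profile analysis,
    voxel-wise similarity metrics (NRMSE, PSNR, SSIM, joint histograms),
    and automated perfusion defect scoring (SSS/SRS/SDS) with
    coronary-territory ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
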