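Package: mmii
Title: Multimodal Image Integration for Epilepsy Presurgical Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for the multimodal image integration (MMII)
    workflow used in epilepsy presurgical evaluation. Co-registers PET, SPECT,
    CT, angiography and secondary MRI contrasts to a T1-weighted base volume by
    mutual-information rigid registration; transfers derived statistical maps
    via a carrier volume's transform; computes SISCOM (subtraction ictal SPECT
    co-registered to MRI) z-score maps and clusters; constructs the AC-PC-based
    Talairach proportional grid; plans straight-line stereo-EEG trajectories
    with vessel-clearance checks; segments and names electrode contacts from a
    post-implant CT; voxelizes resection proposals from pass markers; and burns
    point, line and mask annotations into volumes for neuronavigation hand-off.
    Includes geometric head phantoms with ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
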