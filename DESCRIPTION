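Package: dmnsubsys
Title: Activation Profiling and Connectivity of Default Mode Network Subsystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes default mode network (DMN) subsystems in task and
    resting-state fMRI. Computes per-participant percentages of activating and
    deactivating voxels within subsystem masks from thresholded z-maps, builds
    group consensus maps and derives connectivity seeds, runs seed-to-voxel
    resting-state functional connectivity with CompCor denoising, motion
    censoring and bandpass filtering, performs paired contrasts with sign-flip
    permutation cluster-extent inference, and localizes connectivity maps on
    macroscale cortical gradients via masked spatial correlation. Includes
    within-subject repeated-measures ANOVA with partial eta-squared, and a
    synthetic-data generator with known ground truth so the whole chain is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
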