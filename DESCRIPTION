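Package: fidtrack
Title: Fiducial-Based Intrafraction Tumor Motion Estimation from Stereo kV Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the intrafraction rigid motion of liver tumors from
    implanted fiducial markers seen in orthogonal stereo kilovoltage (kV)
    projection images. Provides marker segmentation (mean filtering,
    binarization, connected-component blob centroids), parallel-ray 3D
    reconstruction from orthogonal projection pairs, quaternion-based
    closed-form rigid registration embedded in an iterative closest point
    (ICP) loop, translational and rotational motion statistics with a
    translation-only versus rigid residual comparison (paired t-test), and a
    synthetic stereo-imaging simulator with retained ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
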