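Package: semdeform
Title: Deformation Fingerprinting of Micro- and Nanoplastics in Time-Lapse SEM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate micro- and nanoplastic particles from
    time-lapse scanning electron microscopy (SEM) recordings by quantifying
    electron-beam-induced shrinkage. Provides a synthetic SEM video generator
    with ground-truth masks and a saturating-exponential shrinkage kinetic,
    classical and trainable per-frame particle segmentation with
    intersection-over-union evaluation, overlap-based particle tracking and
    normalized cross-sectional deformation profiles, and a statistical
    identification procedure: threshold screening of suspect particles,
    mixed-design repeated-measures ANOVA similarity testing against reference
    polymer profiles, and per-material presence calls for blinded samples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    car,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
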