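Package: gcxgcfp
Title: Untargeted and Targeted Fingerprinting of GC x GC-TOF MS Volatilomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for combined untargeted and targeted (UT)
    fingerprinting of comprehensive two-dimensional gas chromatography
    time-of-flight mass spectrometry (GC x GC-TOF MS) volatilome data, as
    applied to maize-silage headspace profiles. Covers 2D chromatogram data
    cubes, watershed peak detection with signal-to-noise gating, NIST-style
    direct and reverse mass-spectral match factors, linear retention-index
    calibration from an n-alkane ladder, template-based peak alignment with
    reliable-peak selection, composite chromatograms and peak-region
    delineation, internal-standard normalised feature tables, composite class
    images with colorized fuzzy-ratio difference rendering, and the
    chemometric layer (Fisher-ratio sieving, PCA, Pearson correlation
    clustering, response ratios, two-way ANOVA with Bonferroni post hoc).
    A seeded synthetic-study generator emulates the study design so every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    cluster
Config/testthat/edition: 3
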