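Package: embryotrace
Title: Analysis of Live RNA-Imaging Data from CRISPR-dCas13 Labelling in
    Zebrafish Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of CRISPR-dCas13 live RNA
    imaging in early zebrafish embryos: screening transcriptomes for
    near-identical 20-nt repeat clusters suitable for multi-copy guide-RNA
    targeting, quantifying per-allele nascent-transcription traces
    (normalized intensity, signal-to-noise ratio, initiation timing,
    activation-pattern classes, plateau kinetics and transcriptional-memory
    statistics), decomposing allelic expression noise into intrinsic and
    extrinsic components via inter-allele output correlations, classifying
    mRNP motion from single-particle tracks with mean-squared-displacement
    model fits (stationary, corralled, diffusive, directed), timing
    nucleocytoplasmic mRNP export events, denoising spot movies with an
    L1/gradient-regularized deconvolution, and generating seeded synthetic
    data (trajectories, allele trace pairs, spot movies, transcriptomes
    with planted repeats) with the statistical structure those analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
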