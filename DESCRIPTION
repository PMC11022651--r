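Package: orbitomics
Title: Longitudinal Astronaut Genetics: Telomere qPCR, cfDNA Fragmentomics,
    Tissue-of-Origin Deconvolution and Clonal Hematopoiesis Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal blood-derived genetics data from
    short-duration spaceflight missions. Implements monochrome multiplex qPCR
    telomere quantification (standard curves, T/A ratios, plate and baseline
    normalization, repeated-measures ANOVA with Tukey post hoc), cell-free DNA
    fragmentomics (fragment-size distributions, per-chromosome RPKM,
    mitochondrial enrichment, exact Wilcoxon comparisons), transcription start
    site nucleosome-footprint tissue-of-origin deconvolution (neighborhood
    coverage normalization, Fourier periodicity scoring, expression correlation,
    Ward clustering), panel-of-normals validation of clonal hematopoiesis
    variants with longitudinal VAF trajectories, and two-timepoint variant-set
    comparison with consequence-severity ranking. A synthetic-data generator
    emulates every input so the full pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
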