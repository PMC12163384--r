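Package: openhrd
Title: Genomic Instability Scar Scoring for Homologous Recombination
    Deficiency from SNP Array Probe Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a laboratory-developed-test style pipeline that turns
    allele-specific SNP-array probe tracks (LogR and B-allele frequency) into
    a genomic instability scar (GIS) score for homologous recombination
    deficiency (HRD) assessment in tumor samples.  Provides quality-control
    gating (MAPD, ndSNPQC), joint piecewise-constant segmentation of LogR and
    mirrored BAF by exact dynamic programming, tumor purity and ploidy
    estimation by grid search with allele-specific integer copy-number
    calling, counting of the three genomic scars (loss of heterozygosity,
    large-scale state transitions, telomeric allelic imbalance), linear
    calibration of raw scores onto a reference-assay scale with HRD
    classification at the 42-point threshold, two-assay agreement statistics
    with Wilson score confidence intervals, and a simulator of clonal tumor
    genomes with known purity, ploidy and injected scar events so the whole
    pipeline is testable without array data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
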