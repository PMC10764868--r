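Package: melt2d
Title: Single-Tube Two-Dimensional PCR Melting-Curve Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for closed-tube multiplex genotyping assays that encode
    each allele as a point in a two-dimensional space of fluorophore channel
    and melting temperature (Tm). Bundles a nine-locus hereditary hearing-loss
    panel (GJB2, SLC26A4, GJB3, MT-RNR1 hotspot mutations) read out in three
    fluorescence channels (FAM, HEX, Alexa568); simulates three-channel
    melting curves for arbitrary genotypes; calls negative-derivative melt
    peaks with Savitzky-Golay smoothing and parabolic refinement; decodes
    (channel, Tm) peak coordinates into per-locus genotypes with QC flags;
    and aggregates cohorts into genotype-category tables, per-site allele
    frequencies, Pearson chi-square regional comparisons, and Cohen's kappa
    method concordance. A command-line interface ties the stages into a
    runnable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    readr,
    yaml,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
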