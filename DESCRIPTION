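Package: wavexon
Title: Exon Detection in Eukaryotic DNA by Period-3 Wavelet Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates protein-coding regions (exons) in eukaryotic DNA from
    the period-3 (codon) periodicity of coding sequence. Nucleotides are
    mapped to electron-ion interaction potential (EIIP) values, the signal is
    sharpened with a zero-phase band-pass filter centred at 2*pi/3, a
    multilevel discrete wavelet transform (Coiflet-5, two levels by default)
    yields a per-position energy profile, and thresholding the denoised,
    normalized profile calls candidate exons. Includes segment- and
    nucleotide-level evaluation against BED/GFF3 annotations (sensitivity,
    specificity, precision, FDR/FOR, ROC/AUC, coding-to-noncoding SNR), a
    synthetic gene generator with tunable codon-position bias, an independent
    sliding-window Fourier period-3 oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
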