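Package: chromatune
Title: Sonification of Quantitative Genomic Signals and Music-Based Track Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts quantitative genomic signal tracks (ChIP-seq coverage in
    bigWig or bedGraph form) into musical scores: per-base coverage is binned,
    log-transformed, quantized onto a musical scale and written as standard
    MIDI, then rendered to audio with an internal additive synthesizer.
    Rendered tracks are summarized as Mel-frequency cepstral coefficient
    (MFCC) frames and modelled with Gaussian mixtures; track similarity is the
    Hausdorff distance between mixture component sets under the Bhattacharyya
    ground distance. A replicate-aware contrast of between- versus
    within-condition distances (the D statistic) scores loci for differential
    expression, and all-pairs distance matrices feed Ward clustering of
    genomic loci. Includes a negative-binomial coverage simulator for
    two-condition, two-replicate designs and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    mclust,
    pROC,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
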