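Package: hashDemux
Title: Demultiplexing, Multiplet Rate Modeling, and Cluster Authentication
    for Sample-Barcoded Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Processes hashtag-oligonucleotide (HTO) count matrices from
    cell-hashing and MULTI-seq experiments. Fits a two-component Gaussian
    mixture to the centered-log-ratio transformed counts of each sample,
    classifies every droplet (GEM) into negative, single-sample, or
    multi-sample-multiplet classes with a confidence score, and estimates
    the rate of undetectable same-sample multiplets through a generative
    binomial droplet-formation model whose latent parameters (droplet
    count, capture rate, per-sample cell counts) are inferred by maximum
    likelihood. Also plans future multiplexing experiments (expected
    singlet/multiplet rates for a given cell load and sample count) and
    authenticates putative cell-type clusters as pure-type or phony-type
    via binomial hypothesis tests on their multiplet content. Includes a
    synthetic dataset generator with ground-truth droplet labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
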