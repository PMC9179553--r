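Package: loopweaver
Title: Chromatin-Loop-Aware Assignment of Nuclear-Receptor Binding Sites to Hormone-Responsive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq peaks, Hi-C chromatin
    loops, A/B compartment eigenvector tracks, and treatment-group expression
    matrices to assign candidate enhancer-gene interactions. Peaks are
    classified against loop anatomy (anchors and spans) into four
    interaction categories (direct promoter binding, anchor/anchor,
    anchor/span, span/anchor), intersected with differentially expressed
    genes called under explicit RPKM filtering rules, and compared against a
    closest-gene-within-100-kb baseline. Also labels 100-kb genomic bins as
    A/B compartments from a signed eigenvector and co-localizes peak sets
    with compartments. Ships a synthetic-landscape generator with
    machine-readable planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
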