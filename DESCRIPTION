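Package: termseqr
Title: Transcription Termination Analysis from Term-Seq 3'-End Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls primary transcription termination sites (TTSs) from
    replicate Term-seq 3'-end count tracks using replicate-consistent
    ratio and difference criteria, characterizes the uridine-rich
    intrinsic terminator motif around called sites, computes normalized
    TTS metaplots, and quantifies condition-dependent transcription
    read-through (TRT) into intergenic regions with a ratio-of-ratios
    TRT index and a four-way read-through classification. Includes FPKM
    quantification over transcription units and intergenic regions,
    expression-rank binning, mRNA half-life regression, delta-delta-Ct
    qPCR enrichment folds, and a fully seeded synthetic-data generator
    that produces genomes, annotations, and stranded tracks with known
    termination ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
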