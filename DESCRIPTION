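Package: promdiv
Title: Promoter Divergence Scanning, Indel Clustering and Selection Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies regulatory-region evolution from multi-species
    promoter alignments. Alignments of orthologous promoters are translated
    into per-column binary event channels (all changes, indels, base
    changes) anchored to the transcription start site; sliding event (Se)
    scores and the d statistic measure divergence over the TATA-distal
    promoter window, with chi-squared contrasts against a control gene set.
    A cumulative G-function test with Monte Carlo significance detects
    non-random clustering of indels along alignments and reports significant
    stretches. McDonald-Kreitman tests with FDR correction estimate the
    proportion of adaptive substitutions (alpha), including pooled estimates
    and bootstrap contrasts between gene sets. TSS-anchored per-base
    conservation vectors support group mean profiles and the dP divergence
    statistic. A synthetic-data generator with known ground truth (planted
    substitutions, geometric-length indels, optional hotspots, depressible
    conservation windows, count tables with known pooled alpha) makes the
    whole pipeline testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
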