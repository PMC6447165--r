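Package: tpscan
Title: Training-Free Detection of Protein-Coding Regions from
    Triplet-Periodicity Walks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scans DNA sequences for protein-coding regions without any
    training data, using the triplet-periodicity (TP) walk: a backward
    recursion converts a sequence into per-position phase-count vectors,
    each vector is mapped to a unit step in the complex plane, and the
    cumulative trajectory drifts directionally inside codon-biased
    (coding) DNA while diffusing near the origin in random (non-coding)
    DNA. The package adds an automated region caller on top of the walk
    (windowed drift profile, thresholding, recursive re-scanning of
    flanking fragments, and boundary refinement) and a synthetic-genome
    generator with known coding coordinates for end-to-end validation.
    Results are returned as GRanges and exportable to BED6, GFF3 and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: Sequencing, GenePrediction, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
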