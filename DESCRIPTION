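Package: genecat
Title: Concatenation, Partitioning and Validation of Multi-Marker DNA Sequence Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building phylogenetic supermatrices from multi-marker
    DNA sequence data. Reads single-marker FASTA and relaxed Phylip files,
    multi-marker Nexus files with character-set information and tab-delimited
    tables with specimen metadata; supports deleting, reordering and renaming
    markers and codon-position subsetting; concatenates markers into
    partitioned supermatrices (and splits them back into per-marker files);
    writes partition command files for downstream model selection in IQ-TREE
    or RAxML; and validates datasets by flagging per-marker outlier sequences
    with an entropy-based interquartile-range procedure and by detecting
    blocks of samples that share no overlapping sequence information. A
    deterministic synthetic-data generator with truth labels supports testing
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
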