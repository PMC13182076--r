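Package: rDNAscan
Title: Repeat Architecture, Copy Number and Intron Processing of Nucleolar
    rDNA Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing linear extrachromosomal ribosomal DNA
    (rDNA) chromosomes such as those of myxomycetes. Builds fully specified
    synthetic rDNA chromosomes (telomere arrays, a large non-transcribed-spacer
    palindrome with planted replication-origin motifs, direct-repeat arrays, an
    upstream promoter region of D-type units, and an rRNA transcription unit
    interrupted by group I introns and a spliceosomal intron) together with
    ground-truth annotation; simulates long DNA reads and 3'-tag RNA reads;
    rediscovers the repeat architecture blind from sequence via self dot-plots,
    palindrome, tandem-array and telomere detectors; estimates rDNA copy number
    from median read-depth ratios; and extracts RNA processing evidence
    (exon-ligation junctions, poly(A) sites, transcript species) to assemble
    and score a feature annotation against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, Coverage, Alignment
RoxygenNote: 7.3.3
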