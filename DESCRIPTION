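Package: ssrscape
Title: Genome-Wide Microsatellite Characterization and Two-Genome Comparison
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines perfect microsatellites (simple sequence repeats, SSRs) from
    genome assemblies under MISA-compatible unit-length/minimum-repeat
    thresholds, classifies repeat units into equivalence classes under cyclic
    rotation and reverse complementation, merges nearby repeats into compound
    loci, computes region-wise (gene, intergenic, exon, intron, CDS, UTR)
    abundance statistics from GFF3 annotation, and profiles repeat positions
    across a 13-element gene partition (500 bp flanks, first/second, middle
    and last exons and introns) with a binned relative-position statistic
    (P0.1-P1.0). Includes a seeded synthetic-genome generator that plants
    repeats with known coordinates, classes, region memberships and element
    positions so the whole pipeline is testable end to end, and a two-genome
    comparative reporter in the shape used by genome SSR surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, SequenceAnalysis, Annotation, Genetics, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
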