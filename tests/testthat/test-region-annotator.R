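test_that("gene/intergenic complement arithmetic holds on a 1-exon gene", {
    gff <- writeTestGFF3(list(list(id = "g1", seq = "chr1", strand = "+",
                                   exons = cbind(101, 400))))
    regions <- buildRegionSets(gff, c(chr1 = 1000))
    lens <- regionLengths(regions)
    expect_equal(unname(lens["gene"]), 300)
    expect_equal(unname(lens["intergenic"]), 700)
    expect_equal(unname(lens["intron"]), 0)
    expect_equal(unname(lens["UTR"]), 0)     # non-coding transcript
})

test_that("introns are the transcript span minus exons", {
    gff <- writeTestGFF3(list(list(id = "g1", seq = "chr1", strand = "+",
                                   exons = cbind(c(1, 201, 401),
                                                 c(100, 300, 500)))))
    regions <- buildRegionSets(gff, c(chr1 = 1000))
    intron <- regions$intron
    expect_equal(BiocGenerics::start(intron), c(101, 301))
    expect_equal(BiocGenerics::end(intron), c(200, 400))
    expect_equal(unname(regionLengths(regions)["intron"]), 200)
})

test_that("UTR is coding-transcript exon minus CDS; structural identities hold", {
    gff <- writeTestGFF3(list(
        list(id = "g1", seq = "chr1", strand = "+",
             exons = cbind(c(1001, 1301), c(1100, 1400)),
             cds = cbind(c(1051, 1301), c(1100, 1380))),
        list(id = "g2", seq = "chr1", strand = "-",
             exons = cbind(3001, 3500))))   # non-coding
    regions <- buildRegionSets(gff, c(chr1 = 5000))
    lens <- regionLengths(regions)
    expect_equal(unname(lens["CDS"]), 50 + 80)
    expect_equal(unname(lens["UTR"]), 200 - 130)   # g1 exons minus its CDS
    expect_equal(unname(lens["gene"] + lens["intergenic"]), 5000)
    expect_equal(unname(lens["exon"] + lens["intron"]),
                 (1400 - 1001 + 1) + (3500 - 3001 + 1))
})

test_that("multi-transcript genes union exons and introns across transcripts", {
    ## two transcripts of one gene; a base exonic in either counts as exonic
    gff <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
        "chr1\tt\tgene\t1001\t2000\t.\t+\t.\tID=g1",
        "chr1\tt\tmRNA\t1001\t2000\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\tt\texon\t1001\t1200\t.\t+\t.\tParent=t1",
        "chr1\tt\texon\t1801\t2000\t.\t+\t.\tParent=t1",
        "chr1\tt\tmRNA\t1001\t2000\t.\t+\t.\tID=t2;Parent=g1",
        "chr1\tt\texon\t1001\t1500\t.\t+\t.\tParent=t2",
        "chr1\tt\texon\t1801\t2000\t.\t+\t.\tParent=t2"), gff)
    regions <- buildRegionSets(gff, c(chr1 = 3000))
    lens <- regionLengths(regions)
    expect_equal(unname(lens["exon"]), 500 + 200)
    ## intron union: t1 contributes [1201,1800], t2 [1501,1800]
    expect_equal(unname(lens["intron"]), 600)
})

test_that("SSRs are counted in every overlapping category", {
    gff <- writeTestGFF3(list(list(id = "g1", seq = "chr1", strand = "+",
                                   exons = cbind(c(1001, 1501), c(1200, 1700)),
                                   cds = cbind(c(1101, 1501), c(1180, 1650)))))
    regions <- buildRegionSets(gff, c(chr1 = 3000))
    ssrs <- ssrGRanges("chr1",
        start = c(1120, 1195, 500, 1010),
        end = c(1140, 1215, 520, 1030))
    ## 1: inside CDS -> CDS, exon, gene; 2: straddles UTR tail/intron;
    ## 3: intergenic; 4: inside 5' UTR
    tab <- assignSSRs(ssrs, regions)
    counts <- stats::setNames(tab$count, tab$category)
    expect_equal(unname(counts["gene"]), 3L)
    expect_equal(unname(counts["intergenic"]), 1L)
    expect_equal(unname(counts["exon"]), 3L)
    expect_equal(unname(counts["intron"]), 1L)
    expect_equal(unname(counts["CDS"]), 1L)
    expect_equal(unname(counts["UTR"]), 2L)
    ## every SSR is in gene or intergenic
    expect_equal(counts["gene"] + counts["intergenic"], c(gene = 4L))
    ## densities recompute from counts and lengths
    expect_equal(tab$density_ssrs_per_mb,
                 tab$count / (tab$total_length_bp / 1e6))
    ## unknown sequence id errors
    expect_error(assignSSRs(ssrGRanges("chrX", 1, 20), regions), "absent")
})

test_that("region sets are invariant to GFF3 line order", {
    genes <- list(list(id = "g1", seq = "chr1", strand = "+",
                       exons = cbind(c(1001, 1301, 1601), c(1100, 1400, 1700)),
                       cds = cbind(c(1051, 1301), c(1100, 1400))))
    set.seed(9)
    a <- buildRegionSets(writeTestGFF3(genes), c(chr1 = 2500))
    b <- buildRegionSets(writeTestGFF3(genes, shuffle = TRUE), c(chr1 = 2500))
    expect_equal(regionLengths(a), regionLengths(b))
    for (cat in names(a)) expect_equal(a[[cat]], b[[cat]])
})

test_that("synthetic annotation reproduces the generator's region lengths", {
    sim <- smallSim()
    paths <- writeSimulation(sim, tempfile("sim"))
    annot <- readGeneAnnotation(paths["gff3"])
    sl <- stats::setNames(Biostrings::width(simSequences(sim)),
                          names(simSequences(sim)))
    lens <- regionLengths(buildRegionSets(annot, sl))
    truth <- stats::setNames(sim@regionTruth$total_length_bp,
                             sim@regionTruth$category)
    expect_equal(lens[names(truth)], truth)
})

test_that("malformed annotations are rejected", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
        "chr1\tt\tgene\t1001\t2000\t.\t+\t.\tID=g1",
        "chr1\tt\tmRNA\t1001\t2000\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\tt\texon\t1001\t1200\t.\t+\t.\tParent=t1",
        "chr1\tt\tCDS\t1300\t1400\t.\t+\t0\tParent=t1"), gff)
    expect_error(readGeneAnnotation(gff), "CDS outside exons")
    writeLines(c("##gff-version 3",
        "chr1\tt\tnothing\t1\t10\t.\t+\t.\tID=x"), gff)
    expect_error(readGeneAnnotation(gff), "no gene features")
})
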