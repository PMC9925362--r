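test_that("gene selection keeps >= 7 exons (more than six exons, five introns)", {
    models <- list(g6 = makeGeneModel(6, geneId = "g6"),
                   g7 = makeGeneModel(7, geneId = "g7"),
                   g9 = makeGeneModel(9, geneId = "g9"))
    kept <- selectMultiexonGenes(models)
    expect_named(kept, c("g7", "g9"))
    expect_named(selectMultiexonGenes(models, minExons = 6L),
                 c("g6", "g7", "g9"))
})

test_that("the 13-element partition is strand-aware with the odd middle exon left", {
    ## 7 exons, minus strand: exon1 is the genomically rightmost exon,
    ## 3 middle exons split 2 (5'-side) / 1
    gm <- makeGeneModel(7, strand = "-")
    part <- partitionGeneElements(gm)
    lab <- as.character(part$label)
    expect_setequal(lab, elementLabels())
    ex <- gm@exons
    labOf <- function(s) lab[BiocGenerics::start(part) == s]
    expect_equal(labOf(BiocGenerics::start(ex)[7]), "exon1")
    expect_equal(labOf(BiocGenerics::start(ex)[6]), "exon2")
    ## genomic middle exons are 3,4,5; on minus strand 5' order is 5,4,3
    expect_equal(labOf(BiocGenerics::start(ex)[5]), "middle_left_exon")
    expect_equal(labOf(BiocGenerics::start(ex)[4]), "middle_left_exon")
    expect_equal(labOf(BiocGenerics::start(ex)[3]), "middle_right_exon")
    expect_equal(labOf(BiocGenerics::start(ex)[1]), "last_exon")
    ## upstream flank sits genomically right of the gene
    up <- part[part$label == "upstream500"]
    expect_equal(BiocGenerics::start(up), BiocGenerics::end(ex)[7] + 1L)

    ## 8 exons, plus strand: 4 middle exons split 2/2, 3 pooled middle introns
    gm8 <- makeGeneModel(8, strand = "+")
    part8 <- partitionGeneElements(gm8)
    tab <- table(as.character(part8$label))
    expect_equal(unname(tab["middle_left_exon"]), 2L)
    expect_equal(unname(tab["middle_right_exon"]), 2L)
    expect_equal(unname(tab["middle_intron"]), 3L)
    expect_equal(sum(tab), 13L + 2L + 2L)   # 13 labels, 3 of them multi-interval
    ## per-gene element intervals are disjoint
    expect_false(any(BiocGenerics::start(BiocGenerics::sort(part8))[-1] <=
                     BiocGenerics::end(BiocGenerics::sort(part8))[-length(part8)]))

    ## fewer than 6 exons cannot be partitioned
    expect_error(partitionGeneElements(makeGeneModel(5)), "at least")
})

test_that("flanks are 500 bp, clipped at sequence boundaries", {
    gm <- makeGeneModel(7, firstStart = 201L)
    part <- partitionGeneElements(gm, seqLength = 10000L)
    up <- part[part$label == "upstream500"]
    expect_equal(c(BiocGenerics::start(up), BiocGenerics::end(up)), c(1L, 200L))
    down <- part[part$label == "downstream500"]
    expect_equal(BiocGenerics::width(down), 500L)
    gmEnd <- BiocGenerics::end(gm@exons)[7]
    part2 <- partitionGeneElements(gm, seqLength = gmEnd + 100L)
    down2 <- part2[part2$label == "downstream500"]
    expect_equal(BiocGenerics::width(down2), 100L)
})

test_that("relative position follows the offset/(L-l) formula with tenth bins", {
    rp <- relativePosition(41, 60, 1, 100, "+")
    expect_equal(rp$value, 0.5)
    expect_equal(rp$bin, "P0.5")
    expect_equal(relativePosition(1, 20, 1, 100, "+")$value, 0)
    expect_equal(relativePosition(1, 20, 1, 100, "+")$bin, "P0.1")
    expect_equal(relativePosition(81, 100, 1, 100, "+")$value, 1)
    expect_equal(relativePosition(81, 100, 1, 100, "+")$bin, "P1.0")
    ## minus strand measures from the genomic right end
    expect_equal(relativePosition(81, 100, 1, 100, "-")$value, 0)
    ## element length == SSR length: midpoint by convention
    expect_equal(relativePosition(1, 100, 1, 100, "+")$value, 0.5)
    expect_error(relativePosition(90, 110, 1, 100, "+"), "contained")
    ## strand mirror symmetry: mirrored coordinates give the same value
    set.seed(31)
    for (i in 1:40) {
        L <- sample(30:200, 1); l <- sample(5:25, 1)
        off <- sample(0:(L - l), 1)
        plus <- relativePosition(101 + off, 100 + off + l, 101, 100 + L, "+")
        minus <- relativePosition(101 + (L - l - off), 100 + (L - off),
                                  101, 100 + L, "-")
        expect_equal(plus$value, minus$value)
        expect_identical(plus$bin, minus$bin)
    }
    ## bins partition (0,1]: value just over a boundary moves up one bin
    expect_equal(relativePosition(11, 20, 1, 110, "+")$bin, "P0.1")  # 0.1
    expect_equal(relativePosition(12, 21, 1, 110, "+")$bin, "P0.2")  # 0.11
})

test_that("element profile recovers placements, majority rule and bin sums", {
    gm <- makeGeneModel(7, exonWidth = 100L, intronWidth = 200L)
    part <- partitionGenes(list(gm), seqlengths = c(chr1 = 50000))
    ## SSRs: one per flank, one inside exon1, one straddling the
    ## exon1/intron1 boundary with majority in the intron
    ex1 <- part[part$label == "exon1"]
    ssrs <- ssrGRanges("chr1",
        start = c(BiocGenerics::start(part[part$label == "upstream500"]) + 10,
                  BiocGenerics::start(part[part$label == "downstream500"]) + 10,
                  BiocGenerics::start(ex1) + 20,
                  BiocGenerics::end(ex1) - 4),
        end = c(BiocGenerics::start(part[part$label == "upstream500"]) + 21,
                BiocGenerics::start(part[part$label == "downstream500"]) + 21,
                BiocGenerics::start(ex1) + 31,
                BiocGenerics::end(ex1) + 7))
    prof <- elementProfile(ssrs, part)
    counts <- stats::setNames(prof$profile$ssr_count,
                              prof$profile$element_label)
    expect_equal(unname(counts[c("upstream500", "downstream500", "exon1",
                                 "intron1")]), c(1L, 1L, 1L, 1L))
    expect_equal(sum(counts), 4L)
    ## the straddler has no bin; bins sum to contained counts per label
    a <- prof$assignments
    expect_equal(sum(is.na(a$bin)), 1L)
    binSum <- tapply(prof$bins$count, prof$bins$element_label, sum)
    contained <- table(factor(a$element_label[a$contained],
                              levels = elementLabels()))
    expect_equal(as.integer(binSum[elementLabels()]),
                 as.integer(contained[elementLabels()]))
    ## a tie in overlap goes to the 5' element
    mid <- ssrGRanges("chr1", BiocGenerics::end(ex1) - 4,
                      BiocGenerics::end(ex1) + 5)   # 5 bp in each
    tieProf <- elementProfile(mid, part)
    expect_equal(tieProf$assignments$element_label, "exon1")
    ## abundance recomputes from count/length
    expect_equal(prof$profile$abundance_ssrs_per_mb,
                 prof$profile$ssr_count / (prof$profile$total_length_bp / 1e6))
})

test_that("flank-only planting yields a profile nonzero only at the flanks", {
    gm <- list(makeGeneModel(7, geneId = "gA"),
               makeGeneModel(8, geneId = "gB", firstStart = 20001L))
    part <- partitionGenes(gm, seqlengths = c(chr1 = 60000))
    flanks <- part[part$label %in% c("upstream500", "downstream500")]
    ssrs <- ssrGRanges("chr1", BiocGenerics::start(flanks) + 100,
                       BiocGenerics::start(flanks) + 111)
    prof <- elementProfile(ssrs, part)$profile
    hit <- prof$element_label[prof$ssr_count > 0]
    expect_setequal(hit, c("upstream500", "downstream500"))
    expect_equal(sum(prof$ssr_count), length(flanks))
})

test_that("profiling the synthetic genome recovers planted elements and bins", {
    sim <- smallSim()
    paths <- writeSimulation(sim, tempfile("sim"))
    annot <- readGeneAnnotation(paths["gff3"])
    sl <- stats::setNames(Biostrings::width(simSequences(sim)),
                          names(simSequences(sim)))
    models <- selectMultiexonGenes(geneModels(annot))
    expect_length(models, nrow(sim@geneTruth))
    part <- partitionGenes(models, seqlengths = sl)
    ssr <- mineGenome(simSequences(sim))
    prof <- elementProfile(ssr, part)
    tr <- planted(sim)
    tr <- tr[!is.na(tr$element), ]
    m <- merge(tr, prof$assignments, by = c("seq_id", "start", "end"))
    expect_equal(nrow(m), nrow(tr))
    expect_equal(m$element_label, m$element)
    expect_equal(m$bin.y, m$bin.x)
    expect_equal(m$rel_value.y, m$rel_value.x, tolerance = 1e-12)
})
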