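## In-code fixtures: GFF3 text built from simple gene descriptions, direct
## GeneModel construction, and bare SSR GRanges.

## genes: list of lists with fields id, seq, strand, exons (matrix/ 2-col
## data.frame of start,end), optional cds (same shape)
writeTestGFF3 <- function(genes, path = tempfile(fileext = ".gff3"),
                          shuffle = FALSE) {
    rows <- character()
    for (g in genes) {
        ex <- as.data.frame(g$exons); names(ex) <- c("start", "end")
        span <- c(min(ex$start), max(ex$end))
        tx <- paste0(g$id, ".t1")
        rows <- c(rows,
            sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    g$seq, span[1], span[2], g$strand, g$id),
            sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    g$seq, span[1], span[2], g$strand, tx, g$id),
            sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    g$seq, ex$start, ex$end, g$strand, tx))
        if (!is.null(g$cds)) {
            cds <- as.data.frame(g$cds); names(cds) <- c("start", "end")
            rows <- c(rows,
                sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                        g$seq, cds$start, cds$end, g$strand, tx))
        }
    }
    if (shuffle) rows <- rows[sample(length(rows))]
    writeLines(c("##gff-version 3", rows), path)
    path
}

## a GeneModel with equal-width exons/introns, for partition tests
makeGeneModel <- function(nExons, strand = "+", seqId = "chr1",
                          geneId = "g1", firstStart = 1001L,
                          exonWidth = 100L, intronWidth = 200L) {
    starts <- firstStart + (seq_len(nExons) - 1L) * (exonWidth + intronWidth)
    new("GeneModel", geneId = geneId, seqId = seqId, txId = paste0(geneId, ".t1"),
        strand = strand,
        exons = IRanges::IRanges(starts, starts + exonWidth - 1L),
        cds = IRanges::IRanges())
}

ssrGRanges <- function(seq, start, end, seqlengths = NULL) {
    gr <- GenomicRanges::GRanges(seq, IRanges::IRanges(start, end))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- unname(seqlengths)
    }
    gr
}

## small simulation reused across tests (computed once per test run)
smallSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateSSRGenome(seed = 421, nSeqs = 1,
                                        seqLength = 60000, genesPerSeq = 3)
        cache
    }
})
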