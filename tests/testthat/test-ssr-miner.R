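test_that("threshold boundaries follow the 12/6/5/5/4/4 minima", {
    r <- findPerfectSSRs(strrep("A", 12))
    expect_equal(nrow(r), 1L)
    expect_equal(r$repeat_count, 12L)
    expect_equal(r$length, 12L)
    expect_equal(nrow(findPerfectSSRs(strrep("A", 11))), 0L)
    expect_equal(nrow(findPerfectSSRs(strrep("AT", 5))), 0L)
    r <- findPerfectSSRs(strrep("AAG", 5))
    expect_equal(r$observed_unit, "AAG")
    expect_equal(r$canonical, "AAG")
    expect_equal(r$repeat_count, 5L)
    for (k in 4:6) {
        unit <- substr("ACGTAC", 1, k)
        minRep <- c(12, 6, 5, 5, 4, 4)[k]
        expect_equal(nrow(findPerfectSSRs(strrep(unit, minRep))), 1L)
        expect_equal(nrow(findPerfectSSRs(strrep(unit, minRep - 1))), 0L)
    }
})

test_that("runs are maximal, left-anchored and whole-unit only", {
    ## trailing partial unit is not part of the record
    r <- findPerfectSSRs(paste0(strrep("AAG", 5), "AA"))
    expect_equal(c(r$start, r$end, r$repeat_count), c(1L, 15L, 5L))
    ## a 13-base poly-A is one SSR of 13 repeats, not two overlapping of 12
    r <- findPerfectSSRs(strrep("A", 13))
    expect_equal(c(r$start, r$end, r$repeat_count), c(1L, 13L, 13L))
    ## flanked run keeps exact coordinates
    r <- findPerfectSSRs(paste0("GGT", strrep("CA", 8), "TGG"))
    expect_equal(c(r$start, r$end), c(4L, 19L))
    expect_equal(r$observed_unit, "CA")
    expect_equal(r$canonical, "AC")
})

test_that("primitive units only: a poly-A run is never reported as (AA)n", {
    r <- findPerfectSSRs(strrep("A", 30))
    expect_equal(nrow(r), 1L)
    expect_equal(r$unit_length, 1L)
    r <- findPerfectSSRs(strrep("ACG", 12))   # 36 bp: only the trinucleotide
    expect_equal(nrow(r), 1L)
    expect_equal(r$unit_length, 3L)
})

test_that("N and non-ACGT characters break runs without erroring", {
    expect_equal(nrow(findPerfectSSRs(paste0(strrep("A", 8), "N",
                                             strrep("A", 8)))), 0L)
    r <- findPerfectSSRs(paste0(strrep("A", 12), "N", strrep("AAG", 5)))
    expect_equal(nrow(r), 2L)
    expect_equal(r$start, c(1L, 14L))
    ## lowercase (soft-masked) input is mined
    expect_equal(nrow(findPerfectSSRs(strrep("a", 12))), 1L)
})

test_that("the miner equals the exhaustive oracle on random sequences", {
    set.seed(2024)
    for (i in 1:250) {
        s <- randomTestSequence(300L)
        got <- findPerfectSSRs(s)
        want <- oracleMine(s)
        expect_identical(ssrKey(got), ssrKey(want))
    }
})

test_that("motif classes are invariant under strand flip", {
    set.seed(77)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
        fwd <- findPerfectSSRs(s)
        rev <- findPerfectSSRs(as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s))))
        expect_identical(
            sort(paste(fwd$canonical, fwd$repeat_count)),
            sort(paste(rev$canonical, rev$repeat_count)))
    }
})

test_that("compound merging uses a strict 100 bp gap and chains transitively", {
    mk <- function(gaps, len = 12L) {
        starts <- cumsum(c(1L, rep(len, length(gaps)) + gaps))
        data.frame(seq_id = "chr1", start = starts, end = starts + len - 1L,
                   observed_unit = "A", canonical = "A", unit_length = 1L,
                   repeat_count = len, length = len,
                   stringsAsFactors = FALSE)
    }
    m <- mergeCompound(mk(99L))
    expect_equal(nrow(m$compounds), 2L)
    expect_equal(nrow(m$standalone), 0L)
    expect_equal(m$compounds$gap_before_bp[2L], 99L)
    m <- mergeCompound(mk(100L))
    expect_null(m$compounds)
    expect_equal(nrow(m$standalone), 2L)
    ## transitive chaining across enumerated gap patterns
    for (gaps in list(c(50L, 50L), c(99L, 99L), c(10L, 99L))) {
        m <- mergeCompound(mk(gaps))
        expect_equal(nrow(m$compounds), 3L)
        expect_equal(length(unique(m$compounds$compound_id)), 1L)
    }
    m <- mergeCompound(mk(c(50L, 150L, 20L)))
    expect_equal(sort(table(m$compounds$compound_id), decreasing = TRUE),
                 sort(c(2L, 2L)), ignore_attr = TRUE)
    ## count conservation on arbitrary gap patterns
    set.seed(5)
    for (i in 1:20) {
        gaps <- sample(c(5L, 99L, 100L, 500L), sample(1:6, 1), replace = TRUE)
        d <- mk(gaps)
        m <- mergeCompound(d)
        expect_equal(NROW(m$compounds) + nrow(m$standalone), nrow(d))
    }
    ## unsorted input is rejected
    bad <- mk(c(200L, 200L))[c(2, 1, 3), ]
    expect_error(mergeCompound(bad), "sorted")
})

test_that("mineGenome handles multi-FASTA, records seqlengths, keeps ids", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">chrA extra description",
                 paste0(strrep("G", 11), strrep("AAG", 5), strrep("T", 11)),
                 ">chrB",
                 paste0(strrep("C", 11), strrep("AT", 7), strrep("G", 11))),
               fa)
    ssr <- mineGenome(fa)
    df <- as.data.frame(ssr)
    expect_equal(df$seq_id, c("chrA", "chrB"))
    expect_equal(df$canonical, c("AAG", "AT"))
    expect_equal(genomeLength(ssr), 37 + 36)
    expect_equal(unname(GenomeInfoDb::seqlengths(ssrRanges(ssr))), c(37L, 36L))
    ## duplicate ids are rejected
    writeLines(c(">x", "ACGT", ">x", "ACGT"), fa)
    expect_error(mineGenome(fa), "duplicate")
})

test_that("MISA-style TSV round-trips through readMisaTSV", {
    sim <- smallSim()
    ssr <- mineGenome(simSequences(sim))
    path <- tempfile(fileext = ".tsv")
    writeMisaTSV(ssr, path)
    back <- readMisaTSV(path, GenomeInfoDb::seqlengths(ssrRanges(ssr)))
    expect_identical(as.data.frame(back), as.data.frame(ssr))
})
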