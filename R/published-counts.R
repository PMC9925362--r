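## Published genome-survey counts for the two bat assemblies the package's
## comparative reporting is shaped after. These are raw inputs (counts,
## summed lengths, genome sizes, per-motif counts) from which the package's
## frequency / abundance / content formulas recompute every derived value;
## they also drive the worked examples and the arithmetic regression tests.

#' Published per-unit-length SSR counts for two bat genomes
#'
#' Genome-wide perfect-SSR counts and summed lengths, by unit length, for the
#' large flying fox (\emph{Pteropus vampyrus}, assembly Pvam_2.0,
#' 2,198,284,804 bp) and Natal long-fingered bat (\emph{Miniopterus
#' natalensis}, assembly Mnat.v1, 1,803,099,001 bp), mined under thresholds
#' 1-12, 2-6, 3-5, 4-5, 5-4, 6-4. Only raw counts are stored; derived
#' statistics (abundance, frequency, content) are recomputed with
#' [unitLengthSummary()].
#'
#' @return named list of two lists, each with \code{counts} (data.frame:
#'   unit_length, count, total_length_bp) and \code{genome_length_bp}.
#' @examples
#' pv <- publishedBatSSRCounts()$Pvam
#' unitLengthSummary(pv$counts, genomeLength = pv$genome_length_bp)
#' @export
publishedBatSSRCounts <- function() {
    list(
        Pvam = list(
            species = "Pteropus vampyrus",
            genome_length_bp = 2198284804,
            counts = data.frame(
                unit_length = 1:6,
                count = c(246947, 163249, 36521, 43966, 15137, 6827),
                total_length_bp = c(3647964, 3649342, 750138, 1409268,
                                    382635, 199332))),
        Mnat = list(
            species = "Miniopterus natalensis",
            genome_length_bp = 1803099001,
            counts = data.frame(
                unit_length = 1:6,
                count = c(144835, 235344, 20959, 32493, 10320, 4723),
                total_length_bp = c(2174691, 4030076, 386283, 1259172,
                                    367900, 188970))))
}

#' Published per-motif SSR counts for the two bat genomes
#'
#' The most frequent motifs per unit length (top 4; both mononucleotide
#' classes) with their genome-wide counts, spelled as in the published
#' survey tables (class representatives such as CT or TAT rather than the
#' canonical labels AG and AAT). Within-unit-length percentages are
#' recomputed with [motifClassSummary()] against the per-unit-length totals
#' of [publishedBatSSRCounts()].
#'
#' @return named list of data.frames with columns unit_length, unit
#'   (published spelling), count.
#' @export
publishedBatMotifCounts <- function() {
    list(
        Pvam = data.frame(
            unit_length = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4,
                            5, 5, 5, 5, 6, 6, 6, 6),
            unit = c("A", "G",
                     "AC", "CT", "GC", "TA",
                     "CAA", "TAT", "CAT", "GAG",
                     "AAAC", "ATAG", "CATT", "TTTA",
                     "AACAA", "TTATT", "TTTCT", "CCACC",
                     "AAACAA", "GGGTTA", "CTGTCT", "TATCTA"),
            count = c(241850, 5097,
                      95909, 37060, 1394, 28886,
                      11151, 9997, 4202, 2974,
                      10035, 6429, 5268, 4488,
                      8277, 2174, 851, 295,
                      1561, 1282, 442, 414),
            stringsAsFactors = FALSE),
        Mnat = data.frame(
            unit_length = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4,
                            5, 5, 5, 5, 6, 6, 6, 6),
            unit = c("A", "G",
                     "AC", "CT", "GC", "TA",
                     "TAT", "CAA", "CAT", "ACC",
                     "TTTA", "ATAG", "CATT", "CCTT",
                     "AACAA", "TTATT", "TTTCT", "AGGGA",
                     "GAGAGG", "TATCTA", "CTGTCT", "GGGTTA"),
            count = c(133249, 11586,
                      80208, 126869, 467, 27800,
                      8458, 3341, 2508, 2380,
                      7092, 5488, 3802, 3721,
                      2623, 2515, 621, 606,
                      604, 271, 261, 215),
            stringsAsFactors = FALSE))
}
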