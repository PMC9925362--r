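#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom IRanges IRanges
NULL

#' MiningThresholds: MISA-style detection thresholds
#'
#' Holds the minimum whole-unit repeat count per unit length (1-6 bp) and the
#' maximum inter-repeat gap below which neighbouring SSRs are merged into a
#' compound locus. The defaults are the thresholds used throughout genome SSR
#' surveys of vertebrates: 12, 6, 5, 5, 4, 4 repeats for mono- through
#' hexanucleotides, and a strict 100 bp compound gap.
#'
#' @slot minRepeats named integer vector, names "1".."6"; minimum whole-unit
#'   repeat count for each unit length.
#' @slot compoundMaxGap integer; two SSRs with fewer than this many bases
#'   between them are merged into one compound SSR.
#' @seealso [miningThresholds()]
#' @exportClass MiningThresholds
setClass("MiningThresholds",
    representation(minRepeats = "integer", compoundMaxGap = "integer"))

setValidity("MiningThresholds", function(object) {
    msg <- NULL
    if (length(object@minRepeats) != 6L ||
        !identical(names(object@minRepeats), as.character(1:6)))
        msg <- c(msg, "minRepeats must be an integer vector named '1'..'6'")
    if (any(is.na(object@minRepeats)) || any(object@minRepeats < 1L))
        msg <- c(msg, "minRepeats must be positive integers")
    if (length(object@compoundMaxGap) != 1L || is.na(object@compoundMaxGap) ||
        object@compoundMaxGap < 0L)
        msg <- c(msg, "compoundMaxGap must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
})

#' Construct mining thresholds
#'
#' @param minRepeats integer vector of length 6: minimum whole-unit repeat
#'   counts for unit lengths 1-6.
#' @param compoundMaxGap single integer, bp; SSR pairs separated by strictly
#'   fewer bases are chained into compound SSRs.
#' @return A [MiningThresholds-class] object.
#' @examples
#' miningThresholds()            # the survey defaults 1-12, 2-6, 3-5, 4-5, 5-4, 6-4
#' miningThresholds(c(10, 6, 5, 5, 5, 5))
#' @export
miningThresholds <- function(minRepeats = c(12L, 6L, 5L, 5L, 4L, 4L),
                             compoundMaxGap = 100L) {
    mr <- as.integer(minRepeats)
    names(mr) <- as.character(1:6)
    new("MiningThresholds", minRepeats = mr,
        compoundMaxGap = as.integer(compoundMaxGap))
}

#' @describeIn MiningThresholds-class minimum repeat counts, named by unit length
#' @param x a \code{MiningThresholds} object
#' @export
minRepeats <- function(x) x@minRepeats

#' @describeIn MiningThresholds-class compound merge gap (bp)
#' @export
compoundMaxGap <- function(x) x@compoundMaxGap

setMethod("show", "MiningThresholds", function(object) {
    cat("MiningThresholds:",
        paste(sprintf("%d-%d", 1:6, object@minRepeats), collapse = ", "),
        sprintf("| compound gap < %d bp\n", object@compoundMaxGap))
})

#' MotifClass: repeat-unit equivalence class
#'
#' A motif class is the set of repeat units identified with one another under
#' cyclic rotation and reverse complementation, e.g. the AAG class contains
#' AAG, AGA, GAA and their reverse complements CTT, TTC, TCT. The class is
#' labelled by its lexicographically smallest member. Only primitive units
#' (not a whole-number repetition of a shorter unit) form classes.
#'
#' @slot canonical character(1); lexicographically smallest member.
#' @slot members character; all units in the class (at most 2 x unit length).
#' @slot unitLength integer(1); unit length, 1-6.
#' @seealso [canonicalClass()], [enumerateMotifClasses()]
#' @exportClass MotifClass
setClass("MotifClass",
    representation(canonical = "character", members = "character",
                   unitLength = "integer"))

setValidity("MotifClass", function(object) {
    msg <- NULL
    k <- object@unitLength
    if (length(k) != 1L || is.na(k) || k < 1L || k > 6L)
        msg <- c(msg, "unitLength must be a single integer in 1..6")
    if (!(object@canonical %in% object@members))
        msg <- c(msg, "canonical must be a member")
    if (object@canonical != min(object@members))
        msg <- c(msg, "canonical must be the lexicographically smallest member")
    if (length(object@members) > 2L * k)
        msg <- c(msg, "a class has at most 2 x unitLength members")
    if (!all(vapply(object@members, isPrimitiveMotif, logical(1))))
        msg <- c(msg, "all members must be primitive")
    closure <- unique(c(
        unlist(lapply(object@members, motifRotations), use.names = FALSE),
        vapply(object@members, revCompMotif, character(1), USE.NAMES = FALSE)))
    if (!setequal(closure, object@members))
        msg <- c(msg, "members must be closed under rotation and reverse complement")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MotifClass", function(object) {
    cat(sprintf("MotifClass %s (unit length %d): {%s}\n", object@canonical,
                object@unitLength, paste(sort(object@members), collapse = ", ")))
})

#' @describeIn MotifClass-class the canonical (smallest) member label
#' @param x a \code{MotifClass}
#' @export
classLabel <- function(x) x@canonical

#' @describeIn MotifClass-class all member spellings
#' @export
classMembers <- function(x) sort(x@members)

#' SSRSet: mined microsatellites plus assembly context
#'
#' The result container of [mineGenome()]: a \code{GRanges} of perfect SSR
#' loci whose metadata columns carry the observed repeat unit (forward-strand
#' spelling at the locus), the canonical class label, the unit length and the
#' whole-unit repeat count, together with the thresholds used for mining.
#' Sequence lengths (including N bases) live in the \code{seqinfo} and are the
#' denominators for all per-Mb statistics.
#'
#' @slot ranges GRanges with mcols observedUnit, canonical, unitLength,
#'   repeatCount.
#' @slot thresholds the [MiningThresholds-class] used.
#' @seealso [mineGenome()], [ssrRanges()], [unitLengthSummary()]
#' @exportClass SSRSet
setClass("SSRSet",
    representation(ranges = "GRanges", thresholds = "MiningThresholds"))

setValidity("SSRSet", function(object) {
    gr <- object@ranges
    need <- c("observedUnit", "canonical", "unitLength", "repeatCount")
    msg <- NULL
    if (!all(need %in% colnames(mcols(gr))))
        msg <- c(msg, paste("ranges must carry mcols:", paste(need, collapse = ", ")))
    else {
        bad <- BiocGenerics::width(gr) !=
            mcols(gr)$unitLength * mcols(gr)$repeatCount
        if (any(bad))
            msg <- c(msg, "width must equal unitLength * repeatCount")
    }
    if (any(is.na(GenomeInfoDb::seqlengths(gr))))
        msg <- c(msg, "seqlengths must be set (density denominators)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SSRSet-class the underlying \code{GRanges} of SSR loci
#' @param x an \code{SSRSet}
#' @export
ssrRanges <- function(x) x@ranges

#' @describeIn SSRSet-class number of SSR records
#' @export
ssrCount <- function(x) length(x@ranges)

#' @describeIn SSRSet-class total assembly length in bp (N included)
#' @export
genomeLength <- function(x) sum(as.numeric(GenomeInfoDb::seqlengths(x@ranges)))

#' @describeIn SSRSet-class thresholds the set was mined under
#' @export
miningParams <- function(x) x@thresholds

setMethod("show", "SSRSet", function(object) {
    cat(sprintf("SSRSet: %d SSRs on %d sequence(s), %.0f bp total\n",
                length(object@ranges),
                length(GenomeInfoDb::seqlengths(object@ranges)),
                genomeLength(object)))
    show(object@thresholds)
})

#' @export
#' @method as.data.frame SSRSet
as.data.frame.SSRSet <- function(x, ...) {
    gr <- x@ranges
    data.frame(
        seq_id = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr),
        end = BiocGenerics::end(gr),
        observed_unit = mcols(gr)$observedUnit,
        canonical = mcols(gr)$canonical,
        unit_length = mcols(gr)$unitLength,
        repeat_count = mcols(gr)$repeatCount,
        length = BiocGenerics::width(gr),
        stringsAsFactors = FALSE)
}

#' GeneModel: one gene with its representative transcript
#'
#' Minimal gene model used by the positional profiler: genomic exon and CDS
#' intervals (1-based closed, sorted by genomic position) of one
#' representative transcript (the transcript with the most exons).
#'
#' @slot geneId,seqId,txId character(1)
#' @slot strand character(1), "+" or "-"
#' @slot exons,cds \code{IRanges} of genomic exon / CDS intervals
#' @exportClass GeneModel
setClass("GeneModel",
    representation(geneId = "character", seqId = "character",
                   txId = "character", strand = "character",
                   exons = "IRanges", cds = "IRanges"))

setValidity("GeneModel", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) > 1L) {
        if (is.unsorted(BiocGenerics::start(ex)))
            msg <- c(msg, "exons must be sorted by genomic start")
        if (any(BiocGenerics::start(ex)[-1L] <=
                BiocGenerics::end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
    }
    if (length(object@cds) &&
        !all(IRanges::overlapsAny(object@cds, ex, type = "within")))
        msg <- c(msg, "CDS intervals must fall within exons")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GeneModel-class number of exons of the representative transcript
#' @param x a \code{GeneModel}
#' @export
nExons <- function(x) length(x@exons)

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s (%s%s): %d exon(s), tx %s\n", object@geneId,
                object@seqId, object@strand, length(object@exons), object@txId))
})

#' GeneAnnotation: parsed GFF3 gene models
#'
#' Parsed gene -> mRNA -> exon/CDS structure of a GFF3 annotation: gene spans,
#' per-transcript exon and CDS intervals, and the transcript-to-gene map.
#' Built by [readGeneAnnotation()]; consumed by [buildRegionSets()] and
#' [geneModels()].
#'
#' @slot genes GRanges of gene spans (names = gene IDs).
#' @slot exonsByTx,cdsByTx GRangesList keyed by transcript ID.
#' @slot txGene named character; transcript ID -> gene ID.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
    representation(genes = "GRanges", exonsByTx = "GRangesList",
                   cdsByTx = "GRangesList", txGene = "character"))

setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation: %d gene(s), %d transcript(s), %d with CDS\n",
                length(object@genes), length(object@exonsByTx),
                sum(lengths(object@cdsByTx) > 0L)))
})

#' SyntheticGenome: seeded simulation with planted SSR truth
#'
#' Output of [simulateSSRGenome()]: the generated assembly, its gene
#' annotation (GFF3-shaped GRanges), and ground-truth tables for every planted
#' SSR (coordinates, observed unit, canonical class, repeat count, region
#' categories, gene element label and relative-position bin) plus the
#' generator's own bookkeeping of region lengths and gene geometry.
#'
#' @slot sequences DNAStringSet
#' @slot features GRanges in GFF3 layout (type/ID/Parent mcols)
#' @slot truth data.frame, one row per planted SSR
#' @slot regionTruth data.frame of per-category total lengths
#' @slot geneTruth data.frame of per-gene geometry (exon count, strand, span)
#' @slot seed integer seed the simulation was generated from
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
    representation(sequences = "DNAStringSet", features = "GRanges",
                   truth = "data.frame", regionTruth = "data.frame",
                   geneTruth = "data.frame", seed = "integer"))

setMethod("show", "SyntheticGenome", function(object) {
    cat(sprintf(
        "SyntheticGenome (seed %d): %d sequence(s), %.0f bp, %d gene(s), %d planted SSR(s)\n",
        object@seed, length(object@sequences),
        sum(as.numeric(Biostrings::width(object@sequences))),
        nrow(object@geneTruth), nrow(object@truth)))
})

#' @describeIn SyntheticGenome-class the planted-SSR truth table
#' @param x a \code{SyntheticGenome}
#' @export
planted <- function(x) x@truth

#' @describeIn SyntheticGenome-class the simulated assembly
#' @export
simSequences <- function(x) x@sequences
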