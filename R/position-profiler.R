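## The 13-element gene partition and the relative-position statistic.
## A multi-exon gene (>= 7 exons) is divided, 5'->3', into: 500 bp upstream,
## exon1, intron1, exon2, intron2, the middle exons split into left and right
## halves (odd exon to the left) around the pooled middle introns, the
## last-second intron and exon, the last intron and exon, and 500 bp
## downstream. SSR positions within an element are expressed as the offset
## from the element's 5' end divided by (element length - SSR length) and
## binned into tenths P0.1..P1.0.

.ELEMENT_LABELS <- c("upstream500", "exon1", "intron1", "exon2", "intron2",
                     "middle_left_exon", "middle_intron", "middle_right_exon",
                     "last2_intron", "last2_exon", "last_intron", "last_exon",
                     "downstream500")

#' Element labels of the 13-part gene partition, in 5'->3' order
#' @return character vector of the 13 labels.
#' @export
elementLabels <- function() .ELEMENT_LABELS

#' Select genes eligible for positional profiling
#'
#' Keeps genes whose representative transcript has at least \code{minExons}
#' exons (default 7, i.e. more than six exons and hence more than five
#' introns), the filter under which the 13-element partition is well defined.
#'
#' @param models list of [GeneModel-class] (see [geneModels()]).
#' @param minExons minimum exon count, default 7.
#' @return the retained sublist.
#' @export
selectMultiexonGenes <- function(models, minExons = 7L) {
    Filter(function(m) nExons(m) >= minExons, models)
}

#' Partition one gene into the 13 positional elements
#'
#' Exon/intron ranks are counted from the gene's 5' end (strand-aware): on the
#' minus strand exon1 is the genomically rightmost exon. Middle exons (ranks
#' 3..n-2) are split into a left and a right half with the odd exon going
#' left; all middle introns are pooled under one label. Flanks are the 500 bp
#' immediately 5' and 3' of the gene span, clipped at sequence ends.
#'
#' @param gene a [GeneModel-class] with at least 6 exons (7 under the default
#'   selection filter; at 6 the middle exon halves hold one exon each).
#' @param flank flank width in bp (default 500).
#' @param seqLength length of the gene's sequence, used to clip the
#'   downstream/upstream flank; \code{NA} leaves the 3'-side unclipped.
#' @return GRanges of element intervals with metadata columns \code{label}
#'   (factor over the 13 labels), \code{elementRank} (position of the label in
#'   5'->3' order) and \code{geneId}. Pooled labels contribute one range per
#'   underlying interval.
#' @export
partitionGeneElements <- function(gene, flank = 500L, seqLength = NA_integer_) {
    stopifnot(is(gene, "GeneModel"))
    n <- nExons(gene)
    if (n < 6L)
        stop("gene ", gene@geneId, " has ", n,
             " exons; the 13-element partition needs at least 6")
    ex <- gene@exons                      # genomic order
    introns <- IRanges(BiocGenerics::end(ex)[-n] + 1L,
                       BiocGenerics::start(ex)[-1L] - 1L)
    minus <- gene@strand == "-"
    ord <- if (minus) rev(seq_len(n)) else seq_len(n)        # 5'->3'
    iord <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
    ex5 <- ex[ord]; in5 <- introns[iord]

    m <- n - 4L                             # middle exon count (>= 3)
    nLeft <- (m + 1L) %/% 2L
    exLabel <- c("exon1", "exon2", rep("middle_left_exon", nLeft),
                 rep("middle_right_exon", m - nLeft), "last2_exon", "last_exon")
    ni <- n - 1L
    inLabel <- c("intron1", "intron2", rep("middle_intron", ni - 4L),
                 "last2_intron", "last_intron")

    gStart <- BiocGenerics::start(ex)[1L]
    gEnd <- BiocGenerics::end(ex)[n]
    leftFlank <- IRanges(max(1L, gStart - flank), gStart - 1L)
    rightEnd <- if (is.na(seqLength)) gEnd + flank else min(seqLength, gEnd + flank)
    rightFlank <- IRanges(gEnd + 1L, rightEnd)
    if (minus) {
        up <- rightFlank; down <- leftFlank
    } else {
        up <- leftFlank; down <- rightFlank
    }

    ranges <- c(up, ex5, in5, down)
    labels <- c("upstream500", exLabel, inLabel, "downstream500")
    keep <- BiocGenerics::width(ranges) > 0L
    ranges <- ranges[keep]; labels <- labels[keep]
    lab <- factor(labels, levels = .ELEMENT_LABELS)
    out <- GRanges(gene@seqId, ranges)
    BiocGenerics::strand(out) <- gene@strand
    mcols(out) <- DataFrame(label = lab,
                            elementRank = as.integer(lab),
                            geneId = gene@geneId)
    out[order(mcols(out)$elementRank, BiocGenerics::start(out))]
}

#' Partition every selected gene
#'
#' @param models list of [GeneModel-class] that pass
#'   [selectMultiexonGenes()].
#' @inheritParams partitionGeneElements
#' @param seqlengths named vector of sequence lengths for flank clipping.
#' @return one GRanges concatenating the per-gene partitions.
#' @export
partitionGenes <- function(models, flank = 500L, seqlengths = NULL) {
    parts <- lapply(models, function(m) {
        sl <- if (!is.null(seqlengths) && m@seqId %in% names(seqlengths))
            as.integer(seqlengths[[m@seqId]]) else NA_integer_
        partitionGeneElements(m, flank = flank, seqLength = sl)
    })
    levels <- if (!is.null(seqlengths)) names(seqlengths) else
        unique(vapply(models, function(m) m@seqId, character(1)))
    parts <- lapply(parts, function(p) {
        GenomeInfoDb::seqlevels(p) <- levels
        p
    })
    do.call(c, unname(parts))
}

#' Relative position of an SSR within a gene element
#'
#' The distance from the element's 5' end to the SSR's 5'-proximal end,
#' divided by (element length - SSR length), clamped to [0, 1] and binned
#' into right-closed tenths P0.1..P1.0 (a value of exactly 0 falls in P0.1).
#' When element and SSR lengths are equal the value is 0.5 by convention.
#'
#' @param ssrStart,ssrEnd SSR coordinates (1-based closed).
#' @param elemStart,elemEnd element coordinates; must contain the SSR.
#' @param strand "+" or "-": the gene strand defining the 5' end.
#' @return list with \code{value} (numeric in [0,1]) and \code{bin}
#'   (character, "P0.1".."P1.0").
#' @examples
#' relativePosition(41, 60, 1, 100, "+")  # value 0.5, bin P0.5
#' @export
relativePosition <- function(ssrStart, ssrEnd, elemStart, elemEnd, strand) {
    if (ssrStart < elemStart || ssrEnd > elemEnd)
        stop("SSR is not contained in the element")
    L <- elemEnd - elemStart + 1L
    l <- ssrEnd - ssrStart + 1L
    offset <- if (strand == "-") elemEnd - ssrEnd else ssrStart - elemStart
    value <- if (L == l) 0.5 else offset / (L - l)
    value <- min(1, max(0, value))
    idx <- max(1L, as.integer(ceiling(round(value * 10, 9))))
    list(value = value, bin = sprintf("P%.1f", idx / 10))
}

#' Profile SSR abundance across the 13 gene elements
#'
#' SSRs fully contained in an element interval are counted there with their
#' relative-position bin. SSRs spanning an element boundary are counted once,
#' in the element holding the greater share (ties to the 5' element), with no
#' bin. Abundance per label is the count per Mb of the label's summed length
#' across genes.
#'
#' @param ssrs an [SSRSet-class] or GRanges of SSR loci.
#' @param partitions GRanges from [partitionGenes()].
#' @return list with \code{profile} (data.frame: element_label, n_genes,
#'   total_length_bp, ssr_count, abundance_ssrs_per_mb) and \code{bins}
#'   (data.frame: element_label, bin, count) and \code{assignments}
#'   (per-SSR data.frame used to build both).
#' @export
elementProfile <- function(ssrs, partitions) {
    gr <- if (is(ssrs, "SSRSet")) ssrRanges(ssrs) else ssrs
    hits <- GenomicRanges::findOverlaps(gr, partitions, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(gr)[q], IRanges::ranges(partitions)[s]))
    contained <- BiocGenerics::start(gr)[q] >= BiocGenerics::start(partitions)[s] &
                 BiocGenerics::end(gr)[q] <= BiocGenerics::end(partitions)[s]

    assign <- NULL
    if (length(q)) {
        ord <- order(q, -ov, mcols(partitions)$elementRank[s],
                     BiocGenerics::start(partitions)[s])
        first <- !duplicated(q[ord])
        pick <- ord[first]
        qi <- q[pick]; si <- s[pick]
        bins <- rep(NA_character_, length(qi))
        vals <- rep(NA_real_, length(qi))
        isIn <- contained[pick]
        for (j in which(isIn)) {
            rp <- relativePosition(
                BiocGenerics::start(gr)[qi[j]], BiocGenerics::end(gr)[qi[j]],
                BiocGenerics::start(partitions)[si[j]],
                BiocGenerics::end(partitions)[si[j]],
                as.character(BiocGenerics::strand(partitions))[si[j]])
            bins[j] <- rp$bin; vals[j] <- rp$value
        }
        assign <- data.frame(
            ssr_index = qi,
            seq_id = as.character(GenomeInfoDb::seqnames(gr))[qi],
            start = BiocGenerics::start(gr)[qi],
            end = BiocGenerics::end(gr)[qi],
            gene_id = mcols(partitions)$geneId[si],
            element_label = as.character(mcols(partitions)$label)[si],
            contained = isIn, rel_value = vals, bin = bins,
            stringsAsFactors = FALSE)
    }

    lab <- mcols(partitions)$label
    lens <- tapply(BiocGenerics::width(partitions), lab, sum, default = 0)
    ngene <- tapply(mcols(partitions)$geneId, lab,
                    function(g) length(unique(g)), default = 0L)
    cnt <- if (is.null(assign)) integer(length(.ELEMENT_LABELS)) else
        as.integer(table(factor(assign$element_label, levels = .ELEMENT_LABELS)))
    profile <- data.frame(
        element_label = .ELEMENT_LABELS,
        n_genes = as.integer(ngene[.ELEMENT_LABELS]),
        total_length_bp = as.numeric(lens[.ELEMENT_LABELS]),
        ssr_count = cnt,
        stringsAsFactors = FALSE)
    profile$abundance_ssrs_per_mb <-
        ifelse(profile$total_length_bp > 0,
               profile$ssr_count / (profile$total_length_bp / 1e6), NA_real_)

    binLv <- sprintf("P%.1f", (1:10) / 10)
    binDf <- if (is.null(assign)) {
        data.frame(element_label = character(), bin = character(),
                   count = integer(), stringsAsFactors = FALSE)
    } else {
        wb <- assign[!is.na(assign$bin), , drop = FALSE]
        tb <- table(factor(wb$element_label, levels = .ELEMENT_LABELS),
                    factor(wb$bin, levels = binLv))
        df <- as.data.frame(tb, stringsAsFactors = FALSE)
        names(df) <- c("element_label", "bin", "count")
        df
    }
    list(profile = profile, bins = binDf, assignments = assign)
}
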