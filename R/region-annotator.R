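## Gene-model interval arithmetic: gene / intergenic / exon / intron / CDS /
## UTR interval sets from GFF3, and region-wise SSR counts and densities.
## Categories are deliberately nested (gene contains exon and intron; exon
## contains CDS and UTR), so an SSR is counted in every category it overlaps.

.REGION_CATEGORIES <- c("gene", "intergenic", "exon", "intron", "CDS", "UTR")

.firstChar <- function(x) {
    ## GFF3 attribute columns come back as CharacterList from rtracklayer
    if (is(x, "List") || is.list(x))
        vapply(x, function(v) if (length(v)) v[[1L]] else NA_character_,
               character(1))
    else as.character(x)
}

#' Read a GFF3 gene annotation
#'
#' Parses the NCBI RefSeq dialect (gene -> mRNA/transcript -> exon/CDS linked
#' by ID/Parent attributes) into a [GeneAnnotation-class]. Feature line order
#' in the file is irrelevant.
#'
#' @param path GFF3 file path (or a GRanges already carrying type/ID/Parent
#'   metadata columns).
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
    gr <- if (is(path, "GRanges")) path
          else rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    id <- .firstChar(gr$ID)
    parent <- .firstChar(gr$Parent)

    genes <- gr[type == "gene"]
    if (length(genes) == 0L) stop("annotation contains no gene features")
    names(genes) <- .firstChar(genes$ID)
    mcols(genes) <- NULL

    isTx <- type %in% c("mRNA", "transcript")
    txIds <- id[isTx]
    txGene <- parent[isTx]
    names(txGene) <- txIds
    if (anyNA(txIds)) stop("transcript features must carry ID attributes")

    pickTx <- function(sel) {
        part <- gr[sel]
        pp <- parent[sel]
        if (anyNA(pp)) stop("exon/CDS features must carry Parent attributes")
        keep <- pp %in% txIds
        part <- part[keep]; pp <- pp[keep]
        mcols(part) <- NULL
        out <- S4Vectors::split(part, factor(pp, levels = txIds))
        GRangesList(lapply(out, function(g)
            BiocGenerics::sort(g, ignore.strand = TRUE)))
    }
    exonsByTx <- pickTx(type == "exon")
    cdsByTx <- pickTx(type == "CDS")

    ## sanity: exons inside their transcript's gene span; CDS inside exons
    for (tx in txIds) {
        ex <- exonsByTx[[tx]]
        if (length(ex) == 0L)
            stop("transcript without exons: ", tx)
        cds <- cdsByTx[[tx]]
        if (length(cds) &&
            !all(IRanges::overlapsAny(cds, ex, type = "within")))
            stop("CDS outside exons for transcript ", tx)
    }
    new("GeneAnnotation", genes = genes, exonsByTx = exonsByTx,
        cdsByTx = cdsByTx, txGene = txGene)
}

#' Derive region interval sets from a gene annotation
#'
#' Builds merged interval sets per category: \code{gene} is the union of gene
#' spans; \code{intergenic} its per-sequence complement; \code{exon} the union
#' of exon intervals across all transcripts; \code{intron} the union over
#' transcripts of (transcript span minus its exons); \code{CDS} the union of
#' CDS intervals; \code{UTR} the exonic sequence of coding transcripts outside
#' the CDS. All sets are reduced (non-overlapping) before lengths are summed.
#'
#' @param annotation a [GeneAnnotation-class] (or a GFF3 path).
#' @param seqlengths named vector of full sequence lengths (N included); e.g.
#'   \code{GenomeInfoDb::seqlengths()} of a mined [SSRSet-class].
#' @return named \code{GRangesList} with elements gene, intergenic, exon,
#'   intron, CDS, UTR.
#' @examples
#' \dontrun{
#' regions <- buildRegionSets("annot.gff3", c(chr1 = 100000))
#' regionLengths(regions)
#' }
#' @export
buildRegionSets <- function(annotation, seqlengths) {
    if (!is(annotation, "GeneAnnotation"))
        annotation <- readGeneAnnotation(annotation)
    if (is.null(names(seqlengths)))
        stop("seqlengths must be named by sequence id")
    annSeq <- unique(as.character(GenomeInfoDb::seqnames(annotation@genes)))
    if (!all(annSeq %in% names(seqlengths)))
        stop("annotation references unknown sequence id(s): ",
             paste(setdiff(annSeq, names(seqlengths)), collapse = ", "))

    strip <- function(gr) {
        gr <- GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr))
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- unname(seqlengths)
        gr
    }
    geneSet <- GenomicRanges::reduce(strip(annotation@genes))
    whole <- GRanges(names(seqlengths), IRanges(1L, unname(seqlengths)))
    GenomeInfoDb::seqlengths(whole) <- unname(seqlengths)
    intergenic <- GenomicRanges::setdiff(whole, geneSet)

    allExons <- strip(unlist(annotation@exonsByTx, use.names = FALSE))
    exonSet <- GenomicRanges::reduce(allExons)

    intronPerTx <- lapply(seq_along(annotation@exonsByTx), function(i) {
        ex <- strip(annotation@exonsByTx[[i]])
        GenomicRanges::setdiff(range(ex), ex)
    })
    intronSet <- GenomicRanges::reduce(
        do.call(c, c(intronPerTx, list(GRanges(seqinfo = GenomeInfoDb::seqinfo(whole))))))

    allCds <- strip(unlist(annotation@cdsByTx, use.names = FALSE))
    cdsSet <- GenomicRanges::reduce(allCds)

    coding <- names(annotation@cdsByTx)[lengths(annotation@cdsByTx) > 0L]
    codingExons <- GenomicRanges::reduce(
        strip(unlist(annotation@exonsByTx[coding], use.names = FALSE)))
    utrSet <- GenomicRanges::setdiff(codingExons, cdsSet)

    GRangesList(gene = geneSet, intergenic = intergenic, exon = exonSet,
                intron = intronSet, CDS = cdsSet, UTR = utrSet)
}

#' Total merged length of each region category
#'
#' @param regions result of [buildRegionSets()].
#' @return named numeric vector of bp totals.
#' @export
regionLengths <- function(regions) {
    vapply(regions, function(gr) sum(as.numeric(BiocGenerics::width(gr))),
           numeric(1))
}

#' Count SSRs and compute densities per region category
#'
#' An SSR is counted in every category whose interval set it overlaps by at
#' least 1 bp; an SSR straddling an exon/intron boundary is therefore counted
#' in exon, intron and gene. Density is count per Mb of the category's merged
#' length.
#'
#' @param ssrs an [SSRSet-class] or a GRanges of SSR loci.
#' @param regions result of [buildRegionSets()] on the same assembly.
#' @return data.frame with columns category, count, total_length_bp,
#'   density_ssrs_per_mb.
#' @export
assignSSRs <- function(ssrs, regions) {
    gr <- if (is(ssrs, "SSRSet")) ssrRanges(ssrs) else ssrs
    regSeq <- unique(unlist(lapply(regions, function(r)
        as.character(GenomeInfoDb::seqnames(r))), use.names = FALSE))
    ssrSeq <- unique(as.character(GenomeInfoDb::seqnames(gr)))
    known <- unique(unlist(lapply(regions, function(r)
        GenomeInfoDb::seqlevels(r)), use.names = FALSE))
    if (!all(ssrSeq %in% known))
        stop("SSR sequence id(s) absent from regions: ",
             paste(setdiff(ssrSeq, known), collapse = ", "))
    lens <- regionLengths(regions)
    counts <- vapply(regions, function(r)
        sum(IRanges::overlapsAny(gr, r, ignore.strand = TRUE)), numeric(1))
    data.frame(category = names(regions),
               count = as.integer(counts),
               total_length_bp = unname(lens),
               density_ssrs_per_mb = ifelse(lens > 0, counts / (lens / 1e6), NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Representative gene models from an annotation
#'
#' One [GeneModel-class] per gene, using the transcript with the most exons
#' (ties broken by transcript ID) as the representative.
#'
#' @param annotation a [GeneAnnotation-class].
#' @return named list of [GeneModel-class] objects.
#' @export
geneModels <- function(annotation) {
    stopifnot(is(annotation, "GeneAnnotation"))
    nex <- lengths(annotation@exonsByTx)
    byGene <- split(names(annotation@txGene),
                    unname(annotation@txGene))
    out <- lapply(names(byGene), function(g) {
        txs <- sort(byGene[[g]])
        tx <- txs[which.max(nex[txs])]
        ex <- annotation@exonsByTx[[tx]]
        cds <- annotation@cdsByTx[[tx]]
        gene <- annotation@genes[g]
        new("GeneModel", geneId = g,
            seqId = as.character(GenomeInfoDb::seqnames(gene)),
            txId = tx,
            strand = as.character(BiocGenerics::strand(gene)),
            exons = IRanges::ranges(BiocGenerics::sort(ex, ignore.strand = TRUE)),
            cds = IRanges::ranges(BiocGenerics::sort(cds, ignore.strand = TRUE)))
    })
    names(out) <- names(byGene)
    out[order(names(out))]
}
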