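## Perfect-microsatellite mining. The scan is vectorized: for each unit
## length k the sequence is compared against itself shifted by k, runs of
## equality are maximal perfect tandem regions of period k, and whole-unit
## repeat counts are taken from the run lengths. Non-ACGT characters (N, gaps)
## terminate runs; trailing partial units are never counted.

.ACGT_INT <- utf8ToInt("ACGT")

#' Find perfect microsatellites in one nucleotide sequence
#'
#' Reports every maximal perfect tandem run whose primitive unit is 1-6 bp
#' long and whose whole-unit repeat count meets the per-unit-length minimum.
#' Runs are left-anchored and cannot be extended by a full unit on either
#' side; a run is reported once, under its primitive unit (a poly-A run is a
#' mononucleotide SSR, never also (AA)n), and each position belongs to at most
#' one reported SSR. Coordinates are 1-based closed.
#'
#' @param sequence a character string or \code{DNAString}; case-insensitive.
#'   Characters outside A/C/G/T (e.g. N) break runs rather than erroring.
#' @param thresholds a [MiningThresholds-class]; defaults to 1-12, 2-6, 3-5,
#'   4-5, 5-4, 6-4.
#' @return data.frame with columns start, end, observed_unit (forward-strand
#'   spelling at the locus), canonical (class label), unit_length,
#'   repeat_count, length; sorted by start.
#' @examples
#' findPerfectSSRs(strrep("AAG", 5))
#' findPerfectSSRs(strrep("AT", 5))   # below the dinucleotide minimum: empty
#' @export
findPerfectSSRs <- function(sequence, thresholds = miningThresholds()) {
    stopifnot(is(thresholds, "MiningThresholds"))
    s <- toupper(as.character(sequence))
    n <- nchar(s)
    empty <- data.frame(start = integer(), end = integer(),
                        observed_unit = character(), canonical = character(),
                        unit_length = integer(), repeat_count = integer(),
                        length = integer(), stringsAsFactors = FALSE)
    if (n == 0L) return(empty)
    x <- utf8ToInt(s)
    ok <- x %in% .ACGT_INT
    minRep <- thresholds@minRepeats

    starts <- integer(); ks <- integer(); counts <- integer()
    for (k in 1:6) {
        minLen <- k * minRep[[k]]
        if (n < minLen) next
        eq <- x[seq_len(n - k)] == x[(k + 1L):n] &
              ok[seq_len(n - k)] & ok[(k + 1L):n]
        r <- rle(eq)
        rEnd <- cumsum(r$lengths)
        rStart <- rEnd - r$lengths + 1L
        hit <- which(r$values & (r$lengths + k >= minLen))
        for (i in hit) {
            st <- rStart[i]
            cnt <- (r$lengths[i] + k) %/% k
            unit <- substr(s, st, st + k - 1L)
            if (!isPrimitiveMotif(unit)) next
            starts <- c(starts, st); ks <- c(ks, k); counts <- c(counts, cnt)
        }
    }
    if (!length(starts)) return(empty)

    ## rare boundary overlaps between runs of different unit lengths:
    ## keep by (start asc, span desc), greedily dropping overlaps
    spans <- ks * counts
    o <- order(starts, -spans)
    starts <- starts[o]; ks <- ks[o]; counts <- counts[o]; spans <- spans[o]
    keep <- logical(length(starts))
    lastEnd <- 0L
    for (i in seq_along(starts)) {
        if (starts[i] > lastEnd) {
            keep[i] <- TRUE
            lastEnd <- starts[i] + spans[i] - 1L
        }
    }
    starts <- starts[keep]; ks <- ks[keep]; counts <- counts[keep]
    spans <- spans[keep]

    units <- substr(rep(s, length(starts)), starts, starts + ks - 1L)
    data.frame(start = starts, end = starts + spans - 1L,
               observed_unit = units,
               canonical = vapply(units, canonicalMotif, character(1),
                                  USE.NAMES = FALSE),
               unit_length = ks, repeat_count = counts, length = spans,
               stringsAsFactors = FALSE)
}

#' Mine a genome assembly for microsatellites
#'
#' Runs [findPerfectSSRs()] over every sequence of an assembly and returns an
#' [SSRSet-class] whose \code{seqinfo} records the full sequence lengths
#' (N bases included) used as denominators for per-Mb statistics.
#'
#' @param fasta path to a (multi-)FASTA file, or a \code{DNAStringSet}.
#' @inheritParams findPerfectSSRs
#' @return an [SSRSet-class].
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
#' mineGenome(seqs)
#' @export
mineGenome <- function(fasta, thresholds = miningThresholds()) {
    if (is.character(fasta)) {
        if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
        seqs <- Biostrings::readDNAStringSet(fasta)
        names(seqs) <- sub("\\s.*$", "", names(seqs))
    } else {
        seqs <- Biostrings::DNAStringSet(fasta)
    }
    if (length(seqs) == 0L) stop("assembly contains no sequences")
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
        stop("all sequences must be named")
    if (anyDuplicated(names(seqs)))
        stop("duplicate sequence ids: ",
             paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

    hits <- lapply(seq_along(seqs), function(i) {
        df <- findPerfectSSRs(seqs[[i]], thresholds)
        if (nrow(df)) df$seq_id <- names(seqs)[i]
        df
    })
    hits <- hits[vapply(hits, nrow, integer(1)) > 0L]
    si <- GenomeInfoDb::Seqinfo(seqnames = names(seqs),
                                seqlengths = Biostrings::width(seqs))
    if (length(hits)) {
        df <- do.call(rbind, hits)
        gr <- GRanges(df$seq_id, IRanges(df$start, df$end), seqinfo = si)
        mcols(gr) <- DataFrame(observedUnit = df$observed_unit,
                               canonical = df$canonical,
                               unitLength = df$unit_length,
                               repeatCount = df$repeat_count)
    } else {
        gr <- GRanges(seqinfo = si)
        mcols(gr) <- DataFrame(observedUnit = character(),
                               canonical = character(),
                               unitLength = integer(),
                               repeatCount = integer())
    }
    new("SSRSet", ranges = BiocGenerics::sort(gr, ignore.strand = TRUE),
        thresholds = thresholds)
}

#' Merge nearby microsatellites into compound SSRs
#'
#' Consecutive SSRs on the same sequence separated by strictly fewer than
#' \code{maxGap} bases are chained (transitively) into one compound locus:
#' a 99 bp gap merges, a 100 bp gap does not, under the default.
#'
#' @param ssrs an [SSRSet-class], or a data.frame as returned by
#'   [findPerfectSSRs()] (with or without a seq_id column), sorted by
#'   position and non-overlapping.
#' @param maxGap integer bp; the strict upper bound on merged gaps.
#' @return list with elements \code{compounds} (data.frame of compound
#'   members carrying compound_id, member_rank and gap_before_bp) and
#'   \code{standalone} (data.frame of unmerged SSRs). Every input SSR appears
#'   in exactly one of the two.
#' @export
mergeCompound <- function(ssrs, maxGap = 100L) {
    df <- if (is(ssrs, "SSRSet")) as.data.frame(ssrs) else as.data.frame(ssrs)
    if (is.null(df$seq_id)) df$seq_id <- "."
    if (nrow(df) == 0L)
        return(list(compounds = cbind(df, compound_id = character(0)),
                    standalone = df))
    byseq <- split(seq_len(nrow(df)), df$seq_id)
    compounds <- list(); standalone <- list()
    for (sq in names(byseq)) {
        idx <- byseq[[sq]]
        d <- df[idx, , drop = FALSE]
        if (is.unsorted(d$start, strictly = FALSE))
            stop("SSRs must be sorted by start within each sequence")
        if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
            stop("SSRs must be non-overlapping within each sequence")
        gaps <- if (nrow(d) > 1L) d$start[-1L] - d$end[-nrow(d)] - 1L else integer()
        grp <- cumsum(c(TRUE, gaps >= maxGap))
        d$gap_before_bp <- c(NA_integer_, gaps)
        for (g in split(seq_len(nrow(d)), grp)) {
            if (length(g) >= 2L) {
                m <- d[g, , drop = FALSE]
                m$compound_id <- sprintf("%s_c%d_%d", sq, m$start[1L],
                                         m$end[nrow(m)])
                m$member_rank <- seq_len(nrow(m))
                m$gap_before_bp[1L] <- NA_integer_
                compounds[[length(compounds) + 1L]] <- m
            } else {
                st <- d[g, , drop = FALSE]
                st$gap_before_bp <- NULL
                standalone[[length(standalone) + 1L]] <- st
            }
        }
    }
    list(
        compounds = if (length(compounds)) do.call(rbind, compounds) else NULL,
        standalone = if (length(standalone)) do.call(rbind, standalone)
                     else df[0, , drop = FALSE])
}

#' Write mined SSRs as a MISA-style TSV
#'
#' Columns ID, SSR nr., SSR type (p1..p6), SSR (e.g. (AAG)5), size, start,
#' end; coordinates 1-based inclusive. Canonical class and observed unit are
#' appended as extra columns.
#'
#' @param ssrset an [SSRSet-class]
#' @param path output file path
#' @return the path, invisibly.
#' @export
writeMisaTSV <- function(ssrset, path) {
    df <- as.data.frame(ssrset)
    out <- data.frame(
        ID = df$seq_id,
        `SSR nr.` = if (nrow(df)) stats::ave(seq_len(nrow(df)), df$seq_id,
                                             FUN = seq_along) else integer(),
        `SSR type` = sprintf("p%d", df$unit_length),
        SSR = sprintf("(%s)%d", df$observed_unit, df$repeat_count),
        size = df$length, start = df$start, end = df$end,
        canonical = df$canonical, observed_unit = df$observed_unit,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write mined SSRs as GFF3 microsatellite features
#'
#' @inheritParams writeMisaTSV
#' @return the path, invisibly.
#' @export
writeSSRGff3 <- function(ssrset, path) {
    gr <- ssrRanges(ssrset)
    if (length(gr) == 0L) {            # rtracklayer balks at 0 features
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    mc <- mcols(gr)
    out <- gr
    mcols(out) <- DataFrame(
        source = rep("ssrscape", length(gr)),
        type = rep("microsatellite", length(gr)),
        ID = sprintf("SSR%06d", seq_along(gr)),
        repeat_unit = mc$observedUnit, canonical_class = mc$canonical,
        repeat_count = mc$repeatCount)
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Read SSR records from a MISA-style TSV written by [writeMisaTSV()]
#'
#' @param path TSV path
#' @param seqlengths named integer vector of assembly sequence lengths
#'   (required to rebuild per-Mb denominators).
#' @param thresholds the [MiningThresholds-class] the file was mined under.
#' @return an [SSRSet-class].
#' @export
readMisaTSV <- function(path, seqlengths, thresholds = miningThresholds()) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    si <- GenomeInfoDb::Seqinfo(seqnames = names(seqlengths),
                                seqlengths = unname(seqlengths))
    unit <- df$observed_unit
    gr <- GRanges(df$ID, IRanges(df$start, df$end), seqinfo = si)
    mcols(gr) <- DataFrame(observedUnit = unit,
                           canonical = df$canonical,
                           unitLength = nchar(unit),
                           repeatCount = (df$end - df$start + 1L) %/% nchar(unit))
    new("SSRSet", ranges = BiocGenerics::sort(gr, ignore.strand = TRUE),
        thresholds = thresholds)
}
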