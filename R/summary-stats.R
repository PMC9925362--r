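## Survey-table statistics. Two senses of "frequency" are kept apart:
## frequency_of_total (a unit-length category's share of all SSRs, the
## Table-1 sense) and frequency_within_unit (a motif class's share of its
## unit-length category, the Table-2 sense). Abundance (also called
## diversity) is SSRs per Mb of the sequence analysed; SSR content is summed
## SSR length as a percentage of genome length. Display rounding is half-up
## to 2 decimals; everything internal stays at full precision.

#' Round half-up
#'
#' Fixed-point rounding with ties away from zero (for non-negative input),
#' the convention used for all displayed percentages and densities.
#'
#' @param x numeric
#' @param digits decimal places (default 2)
#' @return numeric
#' @examples
#' roundHalfUp(2.345)  # 2.35 (not banker's 2.34)
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

.ULS_LEVELS <- c("1", "2", "3", "4", "5", "6", "total")

.summarizeUnitCounts <- function(counts, lengthsBp, genomeLength) {
    if (genomeLength <= 0) stop("genomeLength must be positive")
    cnt <- numeric(6); len <- numeric(6)
    cnt[as.integer(names(counts))] <- counts
    len[as.integer(names(lengthsBp))] <- lengthsBp
    total <- sum(cnt)
    df <- data.frame(
        unit_length = .ULS_LEVELS,
        count = c(cnt, total),
        total_length_bp = c(len, sum(len)),
        stringsAsFactors = FALSE)
    df$abundance_ssrs_per_mb <- df$count / (genomeLength / 1e6)
    df$frequency_of_total <- if (total > 0) df$count / total * 100 else 0
    attr(df, "genome_length_bp") <- genomeLength
    attr(df, "ssr_content_pct") <- sum(len) / genomeLength * 100
    class(df) <- c("unit_length_summary", "data.frame")
    df
}

#' Per-unit-length SSR summary (counts, abundance, frequency, content)
#'
#' For each unit length 1-6 and in total: SSR count, summed SSR length,
#' abundance (SSRs per Mb of genome, N bases included in the denominator) and
#' frequency (percentage of all SSRs). The genome-wide SSR content (summed
#' SSR length / genome length, %) is attached as attribute
#' \code{ssr_content_pct}.
#'
#' @param ssrs an [SSRSet-class], or a data.frame with columns
#'   \code{unit_length}, \code{count} and \code{total_length_bp} (e.g.
#'   published survey counts), in which case \code{genomeLength} is required.
#' @param genomeLength assembly length in bp; taken from the
#'   \code{SSRSet}'s seqinfo when omitted.
#' @return data.frame (one row per unit length plus a total row) with
#'   attributes \code{genome_length_bp} and \code{ssr_content_pct}. Values are
#'   full precision; apply [roundHalfUp()] for display.
#' @examples
#' counts <- data.frame(unit_length = 1:2, count = c(10, 5),
#'                      total_length_bp = c(140, 70))
#' unitLengthSummary(counts, genomeLength = 1e6)
#' @export
unitLengthSummary <- function(ssrs, genomeLength = NULL) {
    gl <- genomeLength
    if (is(ssrs, "SSRSet")) {
        if (is.null(gl)) gl <- genomeLength(ssrs)
        df <- as.data.frame(ssrs)
        counts <- tapply(rep(1L, nrow(df)), df$unit_length, sum)
        lens <- tapply(df$length, df$unit_length, sum)
        if (nrow(df) == 0L) counts <- lens <- stats::setNames(numeric(), character())
    } else {
        if (is.null(gl))
            stop("genomeLength is required for count-table input")
        counts <- stats::setNames(as.numeric(ssrs$count),
                                  as.character(ssrs$unit_length))
        lens <- stats::setNames(as.numeric(ssrs$total_length_bp),
                                as.character(ssrs$unit_length))
    }
    .summarizeUnitCounts(counts, lens, as.numeric(gl))
}

#' Per-motif-class SSR summary (Table-2-shaped)
#'
#' Counts per motif class and the class's percentage share of its unit-length
#' category, ranked within unit length (descending count, ties by canonical
#' label). For mined input each class additionally carries an \code{alias}:
#' the observed spelling most frequent at the loci (published tables often
#' label a class by such a representative, e.g. CT for the AG class).
#'
#' @param ssrs an [SSRSet-class], or a data.frame of published counts with
#'   columns \code{unit} (any member spelling) and \code{count}.
#' @param unitTotals optional named numeric (names = unit lengths) overriding
#'   the per-unit-length denominators. Needed when \code{ssrs} lists only the
#'   top motifs of each unit length but the percentages refer to the full
#'   category totals, as in published survey tables.
#' @return data.frame with columns unit_length, canonical, alias, count,
#'   frequency_within_unit, rank.
#' @export
motifClassSummary <- function(ssrs, unitTotals = NULL) {
    if (is(ssrs, "SSRSet")) {
        df <- as.data.frame(ssrs)
        units <- df$observed_unit
        canon <- df$canonical
        w <- rep(1, length(units))
    } else {
        units <- toupper(ssrs$unit)
        canon <- vapply(units, canonicalMotif, character(1), USE.NAMES = FALSE)
        w <- as.numeric(ssrs$count)
    }
    if (!length(units))
        return(data.frame(unit_length = integer(), canonical = character(),
                          alias = character(), count = numeric(),
                          frequency_within_unit = numeric(), rank = integer(),
                          stringsAsFactors = FALSE))
    cnt <- tapply(w, canon, sum)
    alias <- vapply(names(cnt), function(cc) {
        sel <- canon == cc
        byUnit <- tapply(w[sel], units[sel], sum)
        byUnit <- byUnit[order(-byUnit, names(byUnit))]
        names(byUnit)[1L]
    }, character(1))
    out <- data.frame(unit_length = nchar(names(cnt)),
                      canonical = names(cnt), alias = unname(alias),
                      count = as.numeric(cnt), stringsAsFactors = FALSE)
    totals <- tapply(out$count, out$unit_length, sum)
    if (!is.null(unitTotals))
        totals[names(unitTotals)] <- unitTotals
    out$frequency_within_unit <-
        out$count / as.numeric(totals[as.character(out$unit_length)]) * 100
    out <- out[order(out$unit_length, -out$count, out$canonical), ]
    out$rank <- stats::ave(seq_len(nrow(out)), out$unit_length, FUN = seq_along)
    rownames(out) <- NULL
    out
}

#' Top-k motif classes with cumulative share of all SSRs
#'
#' @param classSummary result of [motifClassSummary()].
#' @param k number of classes (across all unit lengths), by descending count;
#'   ties broken by canonical label.
#' @param totalSSRs denominator for the cumulative percentage; defaults to
#'   the summary's own total.
#' @return data.frame of the top k rows with \code{cumulative_pct} appended.
#' @export
topKClasses <- function(classSummary, k, totalSSRs = sum(classSummary$count)) {
    if (k < 1L) stop("k must be >= 1")
    o <- order(-classSummary$count, classSummary$canonical)
    out <- classSummary[o[seq_len(min(k, nrow(classSummary)))], , drop = FALSE]
    out$cumulative_pct <- cumsum(out$count) / totalSSRs * 100
    rownames(out) <- NULL
    out
}

#' Compare the SSR landscapes of two genomes
#'
#' Side-by-side unit-length tables plus, per unit length, the motif classes
#' shared between the two genomes' top-\code{topN} lists and the classes
#' unique to each.
#'
#' @param a,b lists with elements \code{name} (genome label), \code{unit}
#'   (from [unitLengthSummary()]) and \code{motif} (from
#'   [motifClassSummary()]).
#' @param topN how many top classes per unit length enter the shared/unique
#'   comparison (default 4, the convention of published survey tables).
#' @param thresholds optional pair of [MiningThresholds-class]; when given
#'   they must be identical between genomes.
#' @return list with \code{unit} (merged unit-length table), \code{shared},
#'   \code{unique_a}, \code{unique_b} (data.frames of unit_length/canonical),
#'   plus \code{all_shared}/\code{all_unique_a}/\code{all_unique_b} over the
#'   complete observed class lists.
#' @export
compareGenomes <- function(a, b, topN = 4L, thresholds = NULL) {
    if (!is.null(thresholds)) {
        stopifnot(length(thresholds) == 2L)
        if (!identical(minRepeats(thresholds[[1L]]), minRepeats(thresholds[[2L]])) ||
            !identical(compoundMaxGap(thresholds[[1L]]), compoundMaxGap(thresholds[[2L]])))
            stop("the two genomes were mined under different thresholds")
    }
    ua <- a$unit; ub <- b$unit
    unit <- merge(ua, ub, by = "unit_length", suffixes =
                  paste0(".", c(a$name, b$name)), sort = FALSE)
    topPer <- function(m) {
        do.call(rbind, lapply(split(m, m$unit_length), function(d)
            d[order(-d$count, d$canonical), ][seq_len(min(topN, nrow(d))),
                                              c("unit_length", "canonical")]))
    }
    ta <- topPer(a$motif); tb <- topPer(b$motif)
    keyA <- paste(ta$unit_length, ta$canonical)
    keyB <- paste(tb$unit_length, tb$canonical)
    mk <- function(d) { rownames(d) <- NULL; d }
    allA <- paste(a$motif$unit_length, a$motif$canonical)
    allB <- paste(b$motif$unit_length, b$motif$canonical)
    list(unit = unit,
         shared = mk(ta[keyA %in% keyB, ]),
         unique_a = mk(ta[!keyA %in% keyB, ]),
         unique_b = mk(tb[!keyB %in% keyA, ]),
         all_shared = mk(a$motif[allA %in% allB, c("unit_length", "canonical")]),
         all_unique_a = mk(a$motif[!allA %in% allB, c("unit_length", "canonical")]),
         all_unique_b = mk(b$motif[!allB %in% allA, c("unit_length", "canonical")]))
}
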