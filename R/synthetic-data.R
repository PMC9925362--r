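## Seeded synthetic assemblies with planted microsatellites. The generator
## owns its own interval bookkeeping (gene spans, exons, introns, CDS, UTR,
## element windows) written independently of the annotation/profiling
## modules, so recovering the truth table genuinely exercises those modules.
##
## Construction: a uniform-random background is laid down, N runs and repeat
## units are written over it at planned coordinates, single flanking bases
## are adjusted so every planted run is maximal (cannot be extended or
## left-shifted), and remaining accidental repeats are broken by
## substitution-and-recheck until the miner finds exactly the planted set.

.BASES <- c("A", "C", "G", "T")

## unit pool cycled over plants; covers all six unit lengths, all primitive
.UNIT_POOL <- c("A", "AC", "AAG", "AAAC", "AACAA", "AAACAA",
                "C", "AG", "AAT", "AATG", "AATAC", "ACGTAT",
                "A", "AT", "AAC", "ACAT", "AACTC", "AACCGT",
                "C", "AC", "ACT", "AAGG", "AACAA", "AAACAA")

.pickOther <- function(avoid) .BASES[!(.BASES %in% avoid)][1L]

## break every threshold-passing run whose (start,end,unit) key is not in
## truthKeys, by substituting one base per run per round; protectedPos marks
## positions that must not be touched (planted spans plus one flanking base)
.sterilizeChars <- function(chars, thresholds, truthKeys = character(),
                            protected = logical(length(chars))) {
    for (round in seq_len(100L)) {
        found <- findPerfectSSRs(paste(chars, collapse = ""), thresholds)
        keys <- sprintf("%d:%d:%s", found$start, found$end, found$observed_unit)
        bad <- found[!(keys %in% truthKeys), , drop = FALSE]
        if (nrow(bad) == 0L) return(chars)
        for (i in seq_len(nrow(bad))) {
            span <- bad$start[i]:bad$end[i]
            mid <- span[ceiling(length(span) / 2)]
            cand <- span[order(abs(span - mid))]
            pos <- cand[!protected[cand]][1L]
            if (is.na(pos))
                stop("cannot sterilize run at ", bad$start[i],
                     "-", bad$end[i], ": all positions protected")
            left <- if (pos > 1L) chars[pos - 1L] else ""
            right <- if (pos < length(chars)) chars[pos + 1L] else ""
            chars[pos] <- .pickOther(c(chars[pos], left, right))
        }
    }
    stop("sterilization did not converge")
}

#' Generate an SSR-free random background sequence
#'
#' Uniform-random A/C/G/T post-processed so that [findPerfectSSRs()] returns
#' nothing under the given thresholds: detected runs are broken by single
#' substitutions and re-checked to a fixed point.
#'
#' @param length sequence length in bp (0 allowed).
#' @param thresholds a [MiningThresholds-class].
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the same call yields the identical string.
#' @return a character string of the requested length.
#' @export
generateBackground <- function(length, thresholds = miningThresholds(),
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (length == 0L) return("")
    chars <- sample(.BASES, length, replace = TRUE)
    paste(.sterilizeChars(chars, thresholds), collapse = "")
}

## 5'->3' element windows of one planned gene, computed with generator-side
## arithmetic (deliberately not a call into partitionGeneElements)
.planElements <- function(exons, strand, flank, seqLen) {
    n <- nrow(exons)
    introns <- data.frame(start = exons$end[-n] + 1L,
                          end = exons$start[-1L] - 1L)
    m <- n - 4L
    nLeft <- (m + 1L) %/% 2L
    exLab5 <- c("exon1", "exon2", rep("middle_left_exon", nLeft),
                rep("middle_right_exon", m - nLeft), "last2_exon", "last_exon")
    ni <- n - 1L
    inLab5 <- c("intron1", "intron2", rep("middle_intron", ni - 4L),
                "last2_intron", "last_intron")
    exLab <- if (strand == "-") rev(exLab5) else exLab5   # genomic order
    inLab <- if (strand == "-") rev(inLab5) else inLab5
    up <- data.frame(start = max(1L, exons$start[1L] - flank),
                     end = exons$start[1L] - 1L)
    down <- data.frame(start = exons$end[n] + 1L,
                       end = min(seqLen, exons$end[n] + flank))
    lab5 <- if (strand == "-") c("downstream500", "upstream500") else
                               c("upstream500", "downstream500")
    rbind(
        data.frame(label = lab5[1L], start = up$start, end = up$end),
        data.frame(label = exLab, start = exons$start, end = exons$end),
        data.frame(label = inLab, start = introns$start, end = introns$end),
        data.frame(label = lab5[2L], start = down$start, end = down$end))
}

.relBin <- function(offset, L, l) {
    v <- if (L == l) 0.5 else offset / (L - l)
    v <- min(1, max(0, v))
    idx <- max(1L, as.integer(ceiling(round(v * 10, 9))))
    list(value = v, bin = sprintf("P%.1f", idx / 10))
}

#' Simulate a genome assembly with planted microsatellites
#'
#' Generates a seeded multi-sequence assembly (with N runs), gene models with
#' 7-9 exons on alternating strands (gene -> mRNA -> exon/CDS), and perfect
#' SSRs of all six unit lengths planted into every one of the 13 gene
#' elements of every gene, into intergenic space, and into UTR and CDS
#' portions of exons. Planted repeats are mutually separated by more than the
#' compound gap (so none merge), except for one explicitly requested compound
#' pair. Every output is a pure function of the arguments.
#'
#' @param seed integer seed; the simulation is bitwise reproducible from it.
#' @param nSeqs number of assembly sequences.
#' @param seqLength length of each sequence, bp.
#' @param genesPerSeq genes per sequence (7/8/9-exon models cycling).
#' @param intergenicPerSeq SSRs planted in gene-free space per sequence.
#' @param elementPlantCounts named integer vector over [elementLabels()]:
#'   SSRs planted per element per gene (default 1 each). Use larger values at
#'   exon1/last_exon (with a wider \code{exonWidthRange}) to emulate
#'   end-enriched, U-shaped exon profiles.
#' @param plantCompound logical; plant one pair of SSRs 50 bp apart in
#'   intergenic space (a compound locus under the default 100 bp rule).
#' @param nRunsPerSeq number of N runs (50-150 bp) per sequence.
#' @param exonWidthRange,intronWidthRange integer ranges exon and intron
#'   widths are drawn from.
#' @param flank flank width for the upstream/downstream elements (500 bp).
#' @param thresholds a [MiningThresholds-class].
#' @return a [SyntheticGenome-class]; see [planted()], [writeSimulation()].
#' @examples
#' sim <- simulateSSRGenome(seed = 1, nSeqs = 1, seqLength = 60000,
#'                          genesPerSeq = 2)
#' nrow(planted(sim))
#' @export
simulateSSRGenome <- function(seed, nSeqs = 2L, seqLength = 5e5L,
                              genesPerSeq = 8L, intergenicPerSeq = 4L,
                              elementPlantCounts = NULL,
                              plantCompound = TRUE, nRunsPerSeq = 2L,
                              exonWidthRange = c(180L, 300L),
                              intronWidthRange = c(400L, 700L),
                              flank = 500L,
                              thresholds = miningThresholds()) {
    set.seed(as.integer(seed))
    seqLength <- as.integer(seqLength)
    labels <- elementLabels()
    if (is.null(elementPlantCounts))
        elementPlantCounts <- stats::setNames(rep(1L, 13L), labels)
    stopifnot(all(names(elementPlantCounts) %in% labels))
    cnts <- stats::setNames(rep(0L, 13L), labels)
    cnts[names(elementPlantCounts)] <- as.integer(elementPlantCounts)

    seqs <- stats::setNames(vector("list", nSeqs),
                            sprintf("chr%d", seq_len(nSeqs)))
    truth <- list(); geneTruth <- list(); featRows <- list()
    regionTally <- stats::setNames(rep(0, 6), .REGION_CATEGORIES)
    poolIdx <- 0L; geneIdx <- 0L
    minRep <- minRepeats(thresholds)

    nextUnit <- function() {
        poolIdx <<- poolIdx + 1L
        .UNIT_POOL[(poolIdx - 1L) %% length(.UNIT_POOL) + 1L]
    }

    for (sqi in seq_len(nSeqs)) {
        sq <- names(seqs)[sqi]
        ## --- plan gene geometry -------------------------------------------
        genes <- vector("list", genesPerSeq)
        spans <- integer(genesPerSeq)
        for (g in seq_len(genesPerSeq)) {
            geneIdx <- geneIdx + 1L
            nEx <- c(7L, 8L, 9L)[(geneIdx - 1L) %% 3L + 1L]
            exW <- sample(exonWidthRange[1L]:exonWidthRange[2L], nEx,
                          replace = TRUE)
            inW <- sample(intronWidthRange[1L]:intronWidthRange[2L], nEx - 1L,
                          replace = TRUE)
            genes[[g]] <- list(id = sprintf("gene%03d", geneIdx),
                               nEx = nEx, exW = exW, inW = inW,
                               strand = if (geneIdx %% 2L) "+" else "-")
            spans[g] <- sum(exW) + sum(inW)
        }
        margin <- 3000L
        leftover <- seqLength - sum(spans) - 2L * margin
        gap <- leftover %/% genesPerSeq
        if (gap < 2L * flank + 1500L)
            stop("seqLength too small for the requested gene count")
        cursor <- margin
        midgaps <- list()
        for (g in seq_len(genesPerSeq)) {
            gn <- genes[[g]]
            exStart <- cursor + cumsum(c(0L, gn$exW[-gn$nEx] + gn$inW))
            exons <- data.frame(start = exStart, end = exStart + gn$exW - 1L)
            gn$exons <- exons
            gn$span <- c(exons$start[1L], exons$end[gn$nEx])
            ## CDS trims 120 bp off the 5'-most and 3'-most exon ends;
            ## genomically that is always the far left and far right
            gn$cdsBounds <- c(exons$start[1L] + 120L, exons$end[gn$nEx] - 120L)
            gn$elements <- .planElements(exons, gn$strand, flank, seqLength)
            genes[[g]] <- gn
            midgaps[[g]] <- c(cursor - gap + flank + 300L,
                              gn$span[1L] - flank - 300L)
            cursor <- gn$span[2L] + gap
        }
        midgaps[[genesPerSeq + 1L]] <- c(cursor - gap + flank + 300L,
                                         seqLength - 1500L)
        midgaps[[1L]][1L] <- 1500L

        ## --- plan items (plants, N runs, compound) ------------------------
        items <- list()
        addItem <- function(kind, wS, wE, desired, len, meta) {
            items[[length(items) + 1L]] <<- list(kind = kind, wS = wS, wE = wE,
                                                 desired = desired, len = len,
                                                 meta = meta)
        }
        for (g in seq_len(genesPerSeq)) {
            gn <- genes[[g]]
            el <- gn$elements
            for (lab in labels) {
                nPlant <- cnts[[lab]]
                if (nPlant == 0L) next
                ivs <- el[el$label == lab, , drop = FALSE]
                for (j in seq_len(nPlant)) {
                    iv <- ivs[(g + j - 1L) %% nrow(ivs) + 1L, ]
                    unit <- nextUnit()
                    if (gn$strand == "-") unit <- revCompMotif(unit)
                    k <- nchar(unit)
                    r <- minRep[[k]] + (poolIdx %% 3L)
                    len <- k * r
                    wS <- iv$start; wE <- iv$end
                    ## route the first exon1/last_exon plant through the UTR
                    ## window so the UTR category is exercised
                    if (j == 1L && nPlant == 1L &&
                        lab %in% c("exon1", "last_exon")) {
                        utr5 <- (lab == "exon1") == (gn$strand == "+")
                        if (utr5) wE <- min(wE, gn$span[1L] + 119L)
                        else wS <- max(wS, gn$span[2L] - 119L)
                    }
                    rv <- ((poolIdx %% 10L) + 0.5) / 10
                    if (nPlant > 1L) rv <- (j - 0.5) / nPlant
                    desired <- wS + round(rv * (wE - wS + 1L - len))
                    addItem("ssr", wS, wE, desired, len,
                            list(unit = unit, r = r, gene = gn$id,
                                 element = lab, elemStart = iv$start,
                                 elemEnd = iv$end, strand = gn$strand))
                }
            }
        }
        for (j in seq_len(intergenicPerSeq)) {
            mg <- midgaps[[(j - 1L) %% length(midgaps) + 1L]]
            unit <- nextUnit(); k <- nchar(unit)
            r <- minRep[[k]] + (poolIdx %% 3L)
            len <- k * r
            desired <- mg[1L] + round((j / (intergenicPerSeq + 1)) *
                                      (mg[2L] - mg[1L] + 1L - len))
            addItem("ssr", mg[1L], mg[2L], desired, len,
                    list(unit = unit, r = r, gene = NA_character_,
                         element = NA_character_, elemStart = NA_integer_,
                         elemEnd = NA_integer_, strand = "+"))
        }
        for (j in seq_len(nRunsPerSeq)) {
            mg <- midgaps[[(j + 1L) %% length(midgaps) + 1L]]
            len <- 50L + 25L * j
            desired <- mg[1L] + round(0.15 * (mg[2L] - mg[1L]))
            addItem("nrun", mg[1L], mg[2L], desired, len, list())
        }
        if (plantCompound && sqi == 1L) {
            mg <- midgaps[[length(midgaps)]]
            u1 <- "A"; r1 <- minRep[["1"]]; u2 <- "AC"; r2 <- minRep[["2"]]
            len <- r1 + 50L + 2L * r2
            desired <- mg[1L] + round(0.7 * (mg[2L] - mg[1L] + 1L - len))
            addItem("compound", mg[1L], mg[2L], desired, len,
                    list(u1 = u1, r1 = r1, u2 = u2, r2 = r2, spacer = 50L))
        }

        ## --- sequential placement with >= 100 bp separation --------------
        ord <- order(vapply(items, `[[`, numeric(1), "wS"),
                     vapply(items, `[[`, numeric(1), "desired"))
        items <- items[ord]
        prevEnd <- 0L
        for (i in seq_along(items)) {
            it <- items[[i]]
            s <- max(it$desired, prevEnd + 101L, it$wS)
            if (s + it$len - 1L > it$wE) s <- max(it$wS, prevEnd + 101L)
            if (s + it$len - 1L > it$wE)
                stop("infeasible placement in ", sq, " (", it$kind, ")")
            items[[i]]$start <- s
            items[[i]]$end <- s + it$len - 1L
            prevEnd <- items[[i]]$end
        }

        ## --- build the sequence -------------------------------------------
        chars <- sample(.BASES, seqLength, replace = TRUE)
        protected <- logical(seqLength)
        truthKeys <- character()
        fixJunctions <- function(chars, s, e, k) {
            if (s > 1L && chars[s - 1L] == chars[s + k - 1L]) {
                nb <- c(chars[s + k - 1L], chars[s],
                        if (s > 2L) chars[s - 2L])
                chars[s - 1L] <- .pickOther(nb)
            }
            if (e < length(chars) && chars[e + 1L] == chars[e + 1L - k]) {
                nb <- c(chars[e + 1L - k], chars[e],
                        if (e + 2L <= length(chars)) chars[e + 2L])
                chars[e + 1L] <- .pickOther(nb)
            }
            chars
        }
        writeRun <- function(s, unit, r) {
            e <- s + nchar(unit) * r - 1L
            chars[s:e] <<- strsplit(strrep(unit, r), "")[[1L]]
            chars <<- fixJunctions(chars, s, e, nchar(unit))
            protected[max(1L, s - 1L):min(seqLength, e + 1L)] <<- TRUE
            truthKeys <<- c(truthKeys, sprintf("%d:%d:%s", s, e, unit))
            e
        }
        compoundCount <- 0L
        for (it in items) {
            if (it$kind == "nrun") {
                chars[it$start:it$end] <- "N"
            } else if (it$kind == "ssr") {
                writeRun(it$start, it$meta$unit, it$meta$r)
                m <- it$meta
                rp <- if (is.na(m$element)) list(value = NA_real_, bin = NA_character_)
                      else .relBin(
                          if (m$strand == "-") m$elemEnd - it$end
                          else it$start - m$elemStart,
                          m$elemEnd - m$elemStart + 1L, it$len)
                truth[[length(truth) + 1L]] <- data.frame(
                    seq_id = sq, start = it$start, end = it$end,
                    observed_unit = m$unit,
                    canonical = canonicalMotif(m$unit),
                    unit_length = nchar(m$unit), repeat_count = m$r,
                    gene_id = if (is.na(m$gene)) NA_character_ else m$gene,
                    element = m$element,
                    rel_value = rp$value, bin = rp$bin,
                    compound_id = NA_character_, stringsAsFactors = FALSE)
            } else {                                   # compound pair
                m <- it$meta
                compoundCount <- compoundCount + 1L
                cid <- sprintf("%s_compound%d", sq, compoundCount)
                e1 <- writeRun(it$start, m$u1, m$r1)
                s2 <- e1 + m$spacer + 1L
                writeRun(s2, m$u2, m$r2)
                for (mm in list(list(s = it$start, e = e1, u = m$u1, r = m$r1),
                                list(s = s2, e = s2 + 2L * m$r2 - 1L,
                                     u = m$u2, r = m$r2))) {
                    truth[[length(truth) + 1L]] <- data.frame(
                        seq_id = sq, start = mm$s, end = mm$e,
                        observed_unit = mm$u,
                        canonical = canonicalMotif(mm$u),
                        unit_length = nchar(mm$u), repeat_count = mm$r,
                        gene_id = NA_character_, element = NA_character_,
                        rel_value = NA_real_, bin = NA_character_,
                        compound_id = cid, stringsAsFactors = FALSE)
                }
            }
        }
        chars <- .sterilizeChars(chars, thresholds, truthKeys, protected)
        seqs[[sq]] <- paste(chars, collapse = "")

        ## --- annotation rows + region bookkeeping --------------------------
        exonTotal <- 0; intronTotal <- 0; cdsTotal <- 0; geneTotal <- 0
        for (g in seq_len(genesPerSeq)) {
            gn <- genes[[g]]
            txId <- paste0(gn$id, ".t1")
            featRows[[length(featRows) + 1L]] <- data.frame(
                seq_id = sq, start = gn$span[1L], end = gn$span[2L],
                strand = gn$strand, type = c("gene", "mRNA"),
                ID = c(gn$id, txId),
                Parent = c(NA_character_, gn$id), stringsAsFactors = FALSE)
            ex <- gn$exons
            cdsIv <- data.frame(start = pmax(ex$start, gn$cdsBounds[1L]),
                                end = pmin(ex$end, gn$cdsBounds[2L]))
            cdsIv <- cdsIv[cdsIv$start <= cdsIv$end, , drop = FALSE]
            featRows[[length(featRows) + 1L]] <- data.frame(
                seq_id = sq, start = c(ex$start, cdsIv$start),
                end = c(ex$end, cdsIv$end), strand = gn$strand,
                type = rep(c("exon", "CDS"), c(nrow(ex), nrow(cdsIv))),
                ID = NA_character_, Parent = txId, stringsAsFactors = FALSE)
            exonTotal <- exonTotal + sum(ex$end - ex$start + 1L)
            intronTotal <- intronTotal + sum(gn$inW)
            cdsTotal <- cdsTotal + sum(cdsIv$end - cdsIv$start + 1L)
            geneTotal <- geneTotal + (gn$span[2L] - gn$span[1L] + 1L)
            geneTruth[[length(geneTruth) + 1L]] <- data.frame(
                gene_id = gn$id, seq_id = sq, strand = gn$strand,
                n_exons = gn$nEx, span_start = gn$span[1L],
                span_end = gn$span[2L], stringsAsFactors = FALSE)
        }
        regionTally["gene"] <- regionTally["gene"] + geneTotal
        regionTally["intergenic"] <- regionTally["intergenic"] +
            (seqLength - geneTotal)
        regionTally["exon"] <- regionTally["exon"] + exonTotal
        regionTally["intron"] <- regionTally["intron"] + intronTotal
        regionTally["CDS"] <- regionTally["CDS"] + cdsTotal
        regionTally["UTR"] <- regionTally["UTR"] + (exonTotal - cdsTotal)
    }

    truthDf <- do.call(rbind, truth)
    truthDf <- truthDf[order(truthDf$seq_id, truthDf$start), ]
    rownames(truthDf) <- NULL
    truthDf$categories <- .truthCategories(truthDf, do.call(rbind, featRows))

    feats <- do.call(rbind, featRows)
    gr <- GRanges(feats$seq_id, IRanges(feats$start, feats$end),
                  strand = feats$strand)
    mcols(gr) <- DataFrame(
        source = "ssrscape_sim", type = feats$type, ID = feats$ID,
        Parent = ifelse(is.na(feats$Parent), NA_character_, feats$Parent),
        phase = ifelse(feats$type == "CDS", 0L, NA_integer_))
    GenomeInfoDb::seqlevels(gr) <- names(seqs)
    GenomeInfoDb::seqlengths(gr) <- rep(seqLength, nSeqs)

    new("SyntheticGenome",
        sequences = Biostrings::DNAStringSet(unlist(seqs)),
        features = gr, truth = truthDf,
        regionTruth = data.frame(category = names(regionTally),
                                 total_length_bp = as.numeric(regionTally),
                                 stringsAsFactors = FALSE),
        geneTruth = do.call(rbind, geneTruth), seed = as.integer(seed))
}

## region categories of each planted SSR from the generator's feature rows;
## an SSR belongs to every category it overlaps by >= 1 bp
.truthCategories <- function(truthDf, feats) {
    out <- character(nrow(truthDf))
    for (sq in unique(truthDf$seq_id)) {
        f <- feats[feats$seq_id == sq, , drop = FALSE]
        iv <- function(type) {
            d <- f[f$type == type, , drop = FALSE]
            IRanges::reduce(IRanges(d$start, d$end))
        }
        geneIv <- iv("gene"); exonIv <- iv("exon"); cdsIv <- iv("CDS")
        utrIv <- IRanges::setdiff(exonIv, cdsIv)
        intronIv <- IRanges::setdiff(geneIv, exonIv)
        sets <- list(gene = geneIv, exon = exonIv, intron = intronIv,
                     CDS = cdsIv, UTR = utrIv)
        rows <- which(truthDf$seq_id == sq)
        ssrIv <- IRanges(truthDf$start[rows], truthDf$end[rows])
        hit <- vapply(sets, function(x) IRanges::overlapsAny(ssrIv, x),
                      logical(length(rows)))
        hit <- matrix(hit, nrow = length(rows),
                      dimnames = list(NULL, names(sets)))
        out[rows] <- vapply(seq_along(rows), function(j) {
            cats <- colnames(hit)[hit[j, ]]
            if (!hit[j, "gene"]) cats <- c("intergenic", cats)
            paste(cats, collapse = ",")
        }, character(1))
    }
    out
}

#' Write a simulated genome to FASTA + GFF3 + truth TSV
#'
#' @param sim a [SyntheticGenome-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default "sim").
#' @return named character vector of the three paths (fasta, gff3, truth).
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
    stopifnot(is(sim, "SyntheticGenome"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, paste0(prefix, ".fa"))
    gff <- file.path(dir, paste0(prefix, ".gff3"))
    tsv <- file.path(dir, paste0(prefix, ".truth.tsv"))
    Biostrings::writeXStringSet(sim@sequences, fa)
    rtracklayer::export(sim@features, gff, format = "gff3")
    utils::write.table(sim@truth, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(fasta = fa, gff3 = gff, truth = tsv)
}
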