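## End-to-end orchestration: mine -> regions -> profile -> report over one or
## two genomes. Every stage writes files, so each is independently
## re-runnable, and the manifest records content digests: identical inputs
## and config give identical digests.

#' Assemble a pipeline run configuration
#'
#' @param genomes character vector (length 1 or 2) of FASTA paths.
#' @param annotations GFF3 paths matching \code{genomes}.
#' @param names genome labels used in output file names; defaults to the
#'   FASTA base names.
#' @param thresholds a [MiningThresholds-class].
#' @param flank flank width for the element profile (default 500 bp).
#' @param minExons gene filter for the element profile (default 7).
#' @param outDir output directory.
#' @return a named list (class \code{ssr_run_config}).
#' @export
runConfig <- function(genomes, annotations, names = NULL,
                      thresholds = miningThresholds(), flank = 500L,
                      minExons = 7L, outDir = "ssrscape_out") {
    if (!length(genomes) %in% 1:2)
        stop("1 or 2 genomes are supported")
    if (length(annotations) != length(genomes))
        stop("one annotation per genome is required")
    if (is.null(names))
        names <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(genomes))
    structure(list(genomes = genomes, annotations = annotations,
                   names = names, thresholds = thresholds,
                   flank = as.integer(flank), minExons = as.integer(minExons),
                   outDir = outDir),
              class = "ssr_run_config")
}

#' Run the full SSR characterization pipeline
#'
#' For each genome: mine SSRs (MISA-style TSV + GFF3), build region sets and
#' region statistics, profile the 13 gene elements, and write
#' unit-length/motif-class reports (TSV + JSON). With two genomes a
#' comparative report is added. A manifest (JSON) lists every artifact with
#' its md5 digest.
#'
#' @param config a list from [runConfig()].
#' @return the manifest as a named list, invisibly; files under
#'   \code{config$outDir}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "ssr_run_config"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    artifacts <- character()
    add <- function(p) artifacts <<- c(artifacts, p)
    perGenome <- list()

    for (i in seq_along(config$genomes)) {
        nm <- config$names[i]
        message("[", nm, "] mining")
        ssrset <- mineGenome(config$genomes[i], config$thresholds)
        pre <- file.path(config$outDir, nm)
        add(writeMisaTSV(ssrset, paste0(pre, ".ssrs.tsv")))
        add(writeSSRGff3(ssrset, paste0(pre, ".ssrs.gff3")))

        message("[", nm, "] regions")
        annot <- readGeneAnnotation(config$annotations[i])
        sl <- GenomeInfoDb::seqlengths(ssrRanges(ssrset))
        regions <- buildRegionSets(annot, sl)
        regTab <- assignSSRs(ssrset, regions)
        utils::write.table(regTab, paste0(pre, ".regions.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        add(paste0(pre, ".regions.tsv"))

        message("[", nm, "] element profile")
        models <- selectMultiexonGenes(geneModels(annot), config$minExons)
        prof <- NULL
        if (length(models)) {
            parts <- partitionGenes(models, flank = config$flank,
                                    seqlengths = sl)
            prof <- elementProfile(ssrset, parts)
            utils::write.table(prof$profile, paste0(pre, ".profile.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(prof$bins, paste0(pre, ".profile_bins.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            add(paste0(pre, ".profile.tsv"))
            add(paste0(pre, ".profile_bins.tsv"))
        }

        message("[", nm, "] report")
        uls <- unitLengthSummary(ssrset)
        mcs <- motifClassSummary(ssrset)
        utils::write.table(uls, paste0(pre, ".report_unit.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(mcs, paste0(pre, ".report_motif.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(genome = nm, genome_length_bp = genomeLength(ssrset),
                 n_ssrs = ssrCount(ssrset),
                 ssr_content_pct = attr(uls, "ssr_content_pct"),
                 unit_length_summary = uls, n_profiled_genes = length(models)),
            paste0(pre, ".report.json"), auto_unbox = TRUE, digits = NA)
        add(paste0(pre, ".report_unit.tsv"))
        add(paste0(pre, ".report_motif.tsv"))
        add(paste0(pre, ".report.json"))
        perGenome[[nm]] <- list(unit = uls, motif = mcs, name = nm)
    }

    if (length(perGenome) == 2L) {
        cmp <- compareGenomes(perGenome[[1L]], perGenome[[2L]])
        cp <- file.path(config$outDir, "comparison.json")
        jsonlite::write_json(cmp, cp, auto_unbox = TRUE, digits = NA)
        add(cp)
    }

    manifest <- list(
        config = list(genomes = config$genomes,
                      annotations = config$annotations,
                      names = config$names,
                      min_repeats = as.list(minRepeats(config$thresholds)),
                      compound_max_gap = compoundMaxGap(config$thresholds),
                      flank = config$flank, min_exons = config$minExons),
        artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                           function(p) list(path = p,
                                            md5 = unname(tools::md5sum(p)))))
    mp <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
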