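# End-to-end orchestration: call -> QC (contaminant exclusion, rerun) ->
# shared-position filter -> integrate -> artifact flags -> reports.

#' Run the full cross-mutant analysis
#'
#' Executes the whole pipeline on one experiment: per-line SNV calling,
#' cohort QC with contaminant exclusion (the ranking is computed without
#' any flagged line, mirroring how a cultivar contaminant must be dropped
#' before the overlap count is meaningful), the shared-position filter,
#' cross-mutant integration, wild-type artifact flagging, and the ranked
#' candidate report.  When \code{outDir} is given, the report files are
#' written as TSV alongside a manifest echoing every threshold; rerunning
#' on the same inputs overwrites them byte-identically.
#'
#' @param assembly a \linkS4class{ReferenceAssembly} or FASTA path.
#' @param pileups named list of per-line pileup tables or mpileup paths;
#'   names are the line ids.
#' @param wtPileup optional wild-type self-mapping pileup table or path
#'   (enables the assembly-artifact check).
#' @param config a \linkS4class{FilterConfig}.
#' @param contaminantRatioThreshold see \code{\link{flagContaminants}}.
#' @param artifactPerKbThreshold see \code{\link{wildtypeSelfCheck}}.
#' @param outDir optional output directory for the TSV reports.
#' @return a list with elements \code{callsets} (all lines),
#'   \code{summaries} (QC table with contaminant flags),
#'   \code{excludedLines}, \code{ranking} (a
#'   \linkS4class{ContigRanking} over the retained lines),
#'   \code{candidates} (data.frame), \code{artifactContigs}.
#' @examples
#' sim <- simulateExperiment(SimulationConfig(seed = 11L, nContigs = 15L,
#'     contigLengthMedian = 1500, nMutants = 3L, backgroundDensity = 2e-4,
#'     causalLength = 2000L))
#' res <- runPipeline(sim@assembly, sim@pileups,
#'                    config = FilterConfig(minMutantsPerContig = 3L))
#' res$candidates
#' @seealso \code{\link{simulateExperiment}}, \code{\link{callMutantSnvs}}
#' @export
runPipeline <- function(assembly, pileups, wtPileup = NULL,
                        config = FilterConfig(),
                        contaminantRatioThreshold = 20,
                        artifactPerKbThreshold = 0.5, outDir = NULL) {
    if (is.character(assembly) && length(assembly) == 1L)
        assembly <- readFasta(assembly)
    stopifnot(is(assembly, "ReferenceAssembly"))
    validObject(config)
    if (!is.list(pileups) || is.null(names(pileups)) ||
        any(!nzchar(names(pileups))))
        .configError("pileups must be a named list (names = line ids)")
    isPath <- vapply(pileups, is.character, logical(1))
    if (any(isPath)) {
        paths <- unlist(pileups[isPath], use.names = FALSE)
        if (any(!file.exists(paths)))
            .configError("pileup file not found: %s",
                         paths[!file.exists(paths)][1L])
    }
    if (is.character(wtPileup) && !file.exists(wtPileup))
        .configError("wild-type pileup file not found: %s", wtPileup)

    callsets <- lapply(names(pileups), function(id)
        callMutantSnvs(pileups[[id]], assembly, config, id))
    names(callsets) <- names(pileups)

    summaries <- do.call(rbind, lapply(callsets, summarizeMutant))
    rownames(summaries) <- NULL
    summaries <- flagContaminants(summaries, contaminantRatioThreshold)
    excluded <- summaries$mutantId[summaries$contaminantFlag]
    retained <- callsets[setdiff(names(callsets), excluded)]
    if (length(retained) == 0L)
        .configError("all lines were flagged as contaminants")

    filtered <- sharedPositionFilter(retained, config)
    ranking <- integrateCallSets(filtered, assembly, config)

    artifacts <- if (!is.null(wtPileup))
        wildtypeSelfCheck(wtPileup, assembly, config,
                          artifactPerKbThreshold)
    else character(0)
    ranking <- setArtifactFlags(ranking, artifacts)
    candidates <- reportCandidates(ranking)

    res <- list(callsets = callsets, summaries = summaries,
                excludedLines = excluded, ranking = ranking,
                candidates = candidates, artifactContigs = artifacts)
    if (!is.null(outDir))
        .writeReports(res, config, contaminantRatioThreshold,
                      artifactPerKbThreshold, outDir)
    res
}

.writeReports <- function(res, config, contamRatio, artifactThresh,
                          outDir) {
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                           showWarnings = FALSE)
    if (!ok || file.access(outDir, 2L) != 0L)
        .ioError("cannot write to directory '%s'", outDir)
    tsv <- function(x, f)
        write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)

    cand <- res$candidates
    detail <- describeContigCalls(res$ranking, cand$contig)
    if (nrow(detail)) {
        byctg <- vapply(split(sprintf("%s: %s", detail$mutantId,
                                      detail$snvs),
                              detail$contig), paste, character(1),
                        collapse = " | ")
        cand$perMutantSnvs <- unname(byctg[cand$contig])
    } else if (nrow(cand)) {
        cand$perMutantSnvs <- ""
    }
    tsv(cand, "candidates.tsv")
    tsv(contigHistogram(res$ranking), "histogram.tsv")
    tsv(res$summaries, "qc_mutants.tsv")
    tsv(data.frame(contig = res$artifactContigs), "artifact_contigs.tsv")
    for (cs in res$callsets)
        writeCallSet(cs, file.path(outDir,
                                   paste0("calls_", mutantId(cs), ".tsv")))
    kv <- c(min_coverage = config@minCoverage,
            min_allele_frequency = config@minAlleleFrequency,
            max_mutants_sharing_position = config@maxMutantsSharingPosition,
            min_mutants_per_contig = config@minMutantsPerContig,
            contaminant_ratio_threshold = contamRatio,
            artifact_per_kb_threshold = artifactThresh,
            excluded_lines = paste(res$excludedLines, collapse = ","),
            artifact_contigs = paste(res$artifactContigs, collapse = ","))
    writeLines(paste(names(kv), unname(kv), sep = "="),
               file.path(outDir, "run_manifest.txt"))
    invisible(outDir)
}
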