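# Accessor and show methods.

#' @rdname ReferenceAssembly-class
#' @export
setMethod("contigIds", "ReferenceAssembly", function(x) names(x@sequences))

#' @rdname ReferenceAssembly-class
#' @export
setMethod("contigLengths", "ReferenceAssembly", function(x) {
    stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

#' @rdname ReferenceAssembly-class
#' @export
setMethod("gcUnmasked", "ReferenceAssembly", function(x) {
    m <- Biostrings::letterFrequency(x@sequences, letters = c("G", "C"))
    stats::setNames(as.integer(rowSums(m)), names(x@sequences))
})

#' @rdname ReferenceAssembly-class
#' @export
setMethod("unmaskedLengths", "ReferenceAssembly", function(x) {
    m <- Biostrings::letterFrequency(x@sequences, letters = BASES)
    stats::setNames(as.integer(rowSums(m)), names(x@sequences))
})

#' @rdname ReferenceAssembly-class
#' @param id a single contig id.
#' @export
contigSequence <- function(x, id) {
    stopifnot(is(x, "ReferenceAssembly"))
    if (!id %in% names(x@sequences))
        .integrityError("unknown contig id '%s'", id)
    as.character(x@sequences[[id]])
}

#' @rdname ReferenceAssembly-class
#' @export
setMethod("length", "ReferenceAssembly", function(x) length(x@sequences))

setMethod("show", "ReferenceAssembly", function(object) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("ReferenceAssembly: %d contigs, %.3f Mb total (%.3f Mb unmasked)\n",
                length(w), sum(as.numeric(w)) / 1e6,
                sum(as.numeric(unmaskedLengths(object))) / 1e6))
})

setMethod("show", "FilterConfig", function(object) {
    cat(sprintf(paste0("FilterConfig: minCoverage=%d, minAlleleFrequency=%g,\n",
                       "  maxMutantsSharingPosition=%d, minMutantsPerContig=%d\n"),
                object@minCoverage, object@minAlleleFrequency,
                object@maxMutantsSharingPosition, object@minMutantsPerContig))
})

#' @rdname MutantCallSet-class
#' @export
setMethod("mutantId", "MutantCallSet", function(x) x@mutantId)

#' @rdname MutantCallSet-class
#' @export
setMethod("snvCalls", "MutantCallSet", function(x) x@calls)

#' @rdname MutantCallSet-class
#' @export
setMethod("nCalls", "MutantCallSet", function(x) nrow(x@calls))

#' @rdname MutantCallSet-class
#' @export
setMethod("callableBases", "MutantCallSet", function(x) x@callableBases)

#' @rdname MutantCallSet-class
#' @export
setMethod("callableGcBases", "MutantCallSet", function(x) x@callableGcBases)

#' @rdname canonicalFraction
#' @export
setMethod("canonicalFraction", "MutantCallSet", function(x) {
    if (nrow(x@calls) == 0L) return(NA_real_)
    mean(x@calls$canonical)
})

setMethod("show", "MutantCallSet", function(object) {
    cf <- canonicalFraction(object)
    cat(sprintf("MutantCallSet '%s': %d SNVs over %.0f callable bases",
                object@mutantId, nrow(object@calls), object@callableBases))
    if (!is.na(cf)) cat(sprintf(" (%.1f%% canonical)", 100 * cf))
    cat("\n")
})

#' @rdname ContigRanking-class
#' @export
setMethod("contigReports", "ContigRanking", function(x) x@reports)

#' @rdname ContigRanking-class
#' @export
setMethod("contigHistogram", "ContigRanking", function(x) x@histogram)

setMethod("show", "ContigRanking", function(object) {
    cat(sprintf("ContigRanking: %d contigs x %d lines, %d candidate(s)\n",
                nrow(object@reports), length(object@lineIds),
                sum(object@reports$isCandidate)))
    top <- utils::head(object@reports, 3L)
    for (i in seq_len(nrow(top)))
        cat(sprintf("  #%d %s: mutated in %d line(s), %d SNV(s)%s\n",
                    top$rank[i], top$contig[i], top$nMutantsMutated[i],
                    top$totalSnvs[i],
                    if (top$artifactFlag[i]) " [artifact]" else ""))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: seed=%d, %d contigs ",
                       "(lognormal median %.0f bp, sigma %.2f, floor %d bp),\n",
                       "  GC %.2f, masked %.2f, causal %d bp, %d mutant(s), ",
                       "density %.3g/bp,\n  contaminant %.3g/bp, ",
                       "coverage lambda %.1f, error %.3g, artifact=%s\n"),
                object@seed, object@nContigs, object@contigLengthMedian,
                object@contigLengthSigma, object@minContigLength,
                object@gcContent, object@maskedFraction, object@causalLength,
                object@nMutants, object@backgroundDensity,
                object@contaminantDensity, object@coverageLambda,
                object@errorRate, object@artifactScenario))
})

#' @rdname SimulatedExperiment-class
#' @export
setMethod("causalContig", "SimulatedExperiment", function(x) x@causalContig)

#' @rdname SimulatedExperiment-class
#' @export
setMethod("truthTable", "SimulatedExperiment", function(x) x@truth)

setMethod("show", "SimulatedExperiment", function(object) {
    cat(sprintf(paste0("SimulatedExperiment: %d line(s) over %d contig(s); ",
                       "causal contig '%s';\n  %d planted substitution(s), ",
                       "%d contaminant line(s), %d artifact contig(s)\n"),
                length(object@lineIds), length(object@assembly),
                object@causalContig, nrow(object@truth),
                length(object@contaminantIds), length(object@artifactContigs)))
})
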