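#' @import methods
#' @importClassesFrom Biostrings BStringSet
NULL

# ---------------------------------------------------------------- FilterConfig

#' SNV filter configuration
#'
#' Holds the thresholds of the cross-mutant SNV analysis: the per-column
#' coverage and allele-frequency filters applied when calling near-fixed
#' variants in each mutant line, the shared-position filter that discards
#' positions mutated in more than a small number of independent lines
#' (independent EMS hits essentially never coincide, so shared positions
#' indicate pre-existing variation or mapping error), and the contig-level
#' reporting threshold (minimum number of mutated lines for a contig to be
#' reported as a candidate).
#'
#' @slot minCoverage minimum read depth for a column to be callable
#'   (default 15).
#' @slot minAlleleFrequency minimum fraction of substitution-supporting
#'   reads carrying the alternate base (default 0.9999, i.e. near-fixed).
#' @slot maxMutantsSharingPosition positions carried by more than this many
#'   distinct lines are discarded from all lines (default 2).
#' @slot minMutantsPerContig minimum number of independently mutated lines
#'   for a candidate contig (default 3).
#'
#' @examples
#' FilterConfig()
#' FilterConfig(minCoverage = 20L)
#' @name FilterConfig-class
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig",
    representation(minCoverage = "integer",
                   minAlleleFrequency = "numeric",
                   maxMutantsSharingPosition = "integer",
                   minMutantsPerContig = "integer"),
    validity = function(object) {
        msg <- character(0)
        if (length(object@minCoverage) != 1L || is.na(object@minCoverage) ||
            object@minCoverage < 1L)
            msg <- c(msg, "minCoverage must be a single integer >= 1")
        f <- object@minAlleleFrequency
        if (length(f) != 1L || is.na(f) || f <= 0 || f > 1)
            msg <- c(msg, "minAlleleFrequency must be in (0, 1]")
        if (length(object@maxMutantsSharingPosition) != 1L ||
            is.na(object@maxMutantsSharingPosition) ||
            object@maxMutantsSharingPosition < 1L)
            msg <- c(msg, "maxMutantsSharingPosition must be >= 1")
        if (length(object@minMutantsPerContig) != 1L ||
            is.na(object@minMutantsPerContig) ||
            object@minMutantsPerContig < 1L)
            msg <- c(msg, "minMutantsPerContig must be >= 1")
        if (length(msg)) msg else TRUE
    })

#' @rdname FilterConfig-class
#' @param minCoverage,minAlleleFrequency,maxMutantsSharingPosition,minMutantsPerContig
#'   see the slot descriptions.
#' @return \code{FilterConfig()} returns a validated \code{FilterConfig}
#'   object.
#' @export
FilterConfig <- function(minCoverage = 15L, minAlleleFrequency = 0.9999,
                         maxMutantsSharingPosition = 2L,
                         minMutantsPerContig = 3L) {
    obj <- tryCatch(
        new("FilterConfig",
            minCoverage = as.integer(minCoverage),
            minAlleleFrequency = as.numeric(minAlleleFrequency),
            maxMutantsSharingPosition = as.integer(maxMutantsSharingPosition),
            minMutantsPerContig = as.integer(minMutantsPerContig)),
        error = function(e) .configError("%s", conditionMessage(e)))
    obj
}

# ----------------------------------------------------------- ReferenceAssembly

#' Repeat-masked reference assembly
#'
#' A set of assembly contigs with soft-masking preserved: lower-case bases
#' and Ns are masked and excluded from SNV calling, GC accounting and
#' callable-base counts.  Backed by a \linkS4class{BStringSet} so case
#' survives round trips through FASTA.
#'
#' @slot sequences named \code{BStringSet} over \{A,C,G,T,N,a,c,g,t,n\};
#'   names are the contig ids and must be unique.
#'
#' @seealso \code{\link{readFasta}}, \code{\link{makeReference}}
#' @name ReferenceAssembly-class
#' @aliases ReferenceAssembly-class
#' @exportClass ReferenceAssembly
setClass("ReferenceAssembly",
    representation(sequences = "BStringSet", cache = "environment"),
    validity = function(object) {
        nm <- names(object@sequences)
        if (is.null(nm) || any(!nzchar(nm)))
            return("all contigs must be named")
        if (anyDuplicated(nm))
            return(sprintf("duplicate contig id '%s'", nm[anyDuplicated(nm)]))
        bad <- Biostrings::letterFrequency(
            object@sequences, letters = "ACGTNacgtn") !=
            Biostrings::width(object@sequences)
        if (any(bad))
            return(sprintf("contig '%s' contains characters outside {A,C,G,T,N,a,c,g,t,n}",
                           nm[which(bad)[1L]]))
        TRUE
    })

# each assembly carries a private memo environment for derived per-position
# code vectors (never user-visible; R-level copy-on-write keeps it safe)
setMethod("initialize", "ReferenceAssembly", function(.Object, ...) {
    .Object <- callNextMethod(.Object, ...)
    .Object@cache <- new.env(parent = emptyenv())
    .Object
})

#' @rdname ReferenceAssembly-class
#' @param sequences a named character vector or named \code{BStringSet} of
#'   contig sequences.
#' @return \code{ReferenceAssembly()} returns a validated assembly object.
#' @export
ReferenceAssembly <- function(sequences) {
    if (is.character(sequences))
        sequences <- Biostrings::BStringSet(sequences)
    if (!is(sequences, "BStringSet"))
        .configError("sequences must be a named character vector or BStringSet")
    new("ReferenceAssembly", sequences = sequences)
}

# --------------------------------------------------------------- MutantCallSet

#' Per-mutant SNV call set
#'
#' The near-fixed single-nucleotide variants called in one mutant line,
#' together with the callable-base denominators used for SNV-density and
#' mutation-rate estimates.  The \code{calls} table has columns
#' \code{contig}, \code{pos} (1-based), \code{ref}, \code{alt},
#' \code{frequency}, \code{depth} and \code{canonical} (\code{TRUE} for the
#' canonical EMS changes G>A and C>T), sorted by (contig, pos).
#'
#' @slot mutantId identifier of the mutant line.
#' @slot calls data.frame of surviving SNV calls (layout above).
#' @slot callableBases number of unmasked positions with depth at or above
#'   the coverage threshold.
#' @slot callableGcBases the G/C subset of \code{callableBases}, the
#'   denominator of the canonical per-site mutation rate.
#'
#' @seealso \code{\link{callMutantSnvs}}, \code{\link{canonicalFraction}}
#' @name MutantCallSet-class
#' @aliases MutantCallSet-class
#' @exportClass MutantCallSet
setClass("MutantCallSet",
    representation(mutantId = "character", calls = "data.frame",
                   callableBases = "numeric", callableGcBases = "numeric"),
    validity = function(object) {
        need <- c("contig", "pos", "ref", "alt", "frequency", "depth",
                  "canonical")
        if (!all(need %in% names(object@calls)))
            return(sprintf("calls must have columns %s",
                           paste(need, collapse = ", ")))
        if (length(object@mutantId) != 1L || !nzchar(object@mutantId))
            return("mutantId must be a single non-empty string")
        if (object@callableBases < nrow(object@calls))
            return("callableBases cannot be smaller than the number of calls")
        cl <- object@calls
        if (nrow(cl) > 1L) {
            o <- order(cl$contig, cl$pos, method = "radix")
            if (!identical(o, seq_len(nrow(cl))))
                return("calls must be sorted by (contig, pos)")
        }
        if (any(cl$ref == cl$alt))
            return("alt base must differ from ref base")
        TRUE
    })

#' @rdname MutantCallSet-class
#' @param mutantId,calls,callableBases,callableGcBases see the slot
#'   descriptions.
#' @return \code{MutantCallSet()} returns a validated call-set object.
#' @export
MutantCallSet <- function(mutantId, calls = .emptyCalls(),
                          callableBases = 0, callableGcBases = 0) {
    new("MutantCallSet", mutantId = as.character(mutantId), calls = calls,
        callableBases = as.numeric(callableBases),
        callableGcBases = as.numeric(callableGcBases))
}

# ---------------------------------------------------------------- ContigRanking

#' Cross-mutant contig ranking
#'
#' Result of integrating SNV call sets across mutant lines: one report row
#' per assembly contig (contigs without any SNV included), the histogram of
#' contigs by number of mutated lines, and the underlying per-line calls.
#' Reports are sorted by number of mutated lines (descending), total SNVs
#' (descending), then contig id -- a deterministic ranking.
#'
#' @slot reports data.frame with columns \code{rank}, \code{contig},
#'   \code{nMutantsMutated}, \code{totalSnvs}, \code{artifactFlag},
#'   \code{isCandidate}.
#' @slot histogram data.frame with columns \code{nLinesMutated} (0..number
#'   of integrated lines) and \code{nContigs}; counts sum to the number of
#'   assembly contigs.
#' @slot calls combined call table with a \code{mutantId} column.
#' @slot lineIds ids of the integrated mutant lines.
#' @slot minMutantsPerContig the candidate threshold used.
#'
#' @seealso \code{\link{integrateCallSets}}, \code{\link{reportCandidates}}
#' @name ContigRanking-class
#' @aliases ContigRanking-class
#' @exportClass ContigRanking
setClass("ContigRanking",
    representation(reports = "data.frame", histogram = "data.frame",
                   calls = "data.frame", lineIds = "character",
                   minMutantsPerContig = "integer"),
    validity = function(object) {
        if (sum(object@histogram$nContigs) != nrow(object@reports))
            return("histogram counts must sum to the number of contigs")
        TRUE
    })

# ------------------------------------------------------------ SimulationConfig

#' Synthetic EMS-experiment configuration
#'
#' Parameters of the synthetic-experiment generator.  Defaults state a
#' realistic flow-sorted chromosome experiment: ~5 Mb of assembly in 600
#' contigs with log-normal lengths (median 6 kb, sigma 0.8, truncated at
#' 500 bp), GC content 0.44, 10\% of bases soft-masked in contiguous
#' blocks, six EMS mutant lines at a background density of one canonical
#' mutation per 500 kb, a 10-kb causal contig carrying one lesion per
#' mutant, Poisson read depth with mean 30 and error-free reads.
#'
#' @slot seed master RNG seed; per-line streams are derived from it.
#' @slot nContigs number of assembly contigs (including the causal one).
#' @slot contigLengthMedian,contigLengthSigma log-normal length parameters
#'   (median in bp; sigma on the log scale).
#' @slot minContigLength truncation floor of the length distribution (bp).
#' @slot gcContent target GC fraction of simulated sequence.
#' @slot maskedFraction fraction of bases emitted lower-case, in blocks.
#' @slot causalLength length of the planted causal contig (bp).
#' @slot nMutants number of EMS mutant lines.
#' @slot backgroundDensity canonical mutations per unmasked bp per line.
#' @slot contaminantDensity if positive, one extra line carrying
#'   all-spectrum natural variation at this density (per bp) is appended.
#' @slot coverageLambda mean Poisson read depth.
#' @slot errorRate per-read-base miscall probability.
#' @slot artifactScenario if \code{TRUE}, append a chimeric contig whose
#'   second half diverges 1\% from the genome the reads derive from, and
#'   emit a wild-type self-mapping pileup exposing it.
#'
#' @seealso \code{\link{simulateExperiment}}
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(seed = "integer", nContigs = "integer",
                   contigLengthMedian = "numeric",
                   contigLengthSigma = "numeric",
                   minContigLength = "integer", gcContent = "numeric",
                   maskedFraction = "numeric", causalLength = "integer",
                   nMutants = "integer", backgroundDensity = "numeric",
                   contaminantDensity = "numeric",
                   coverageLambda = "numeric", errorRate = "numeric",
                   artifactScenario = "logical"),
    validity = function(object) {
        msg <- character(0)
        frac <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
        if (!frac(object@gcContent)) msg <- c(msg, "gcContent must be in [0,1]")
        if (!frac(object@maskedFraction))
            msg <- c(msg, "maskedFraction must be in [0,1]")
        if (!frac(object@errorRate)) msg <- c(msg, "errorRate must be in [0,1]")
        if (object@causalLength < 1000L)
            msg <- c(msg, "causalLength must be >= 1000 bp")
        if (object@nMutants < 1L) msg <- c(msg, "nMutants must be >= 1")
        if (object@nContigs < 1L) msg <- c(msg, "nContigs must be >= 1")
        if (object@backgroundDensity < 0)
            msg <- c(msg, "backgroundDensity must be >= 0")
        if (object@contaminantDensity < 0)
            msg <- c(msg, "contaminantDensity must be >= 0")
        if (object@coverageLambda <= 0)
            msg <- c(msg, "coverageLambda must be > 0")
        if (is.na(object@seed) || abs(object@seed) > 2^30 - 2000)
            msg <- c(msg, "seed must be an integer within +/- 2^30")
        if (length(msg)) msg else TRUE
    })

#' @rdname SimulationConfig-class
#' @param seed,nContigs,contigLengthMedian,contigLengthSigma,minContigLength
#'   see the slot descriptions.
#' @param gcContent,maskedFraction,causalLength,nMutants,backgroundDensity
#'   see the slot descriptions.
#' @param contaminantDensity,coverageLambda,errorRate,artifactScenario see
#'   the slot descriptions.
#' @return \code{SimulationConfig()} returns a validated configuration.
#' @export
SimulationConfig <- function(seed = 1L, nContigs = 600L,
                             contigLengthMedian = 6000,
                             contigLengthSigma = 0.8,
                             minContigLength = 500L, gcContent = 0.44,
                             maskedFraction = 0.1, causalLength = 10000L,
                             nMutants = 6L, backgroundDensity = 1 / 500000,
                             contaminantDensity = 0,
                             coverageLambda = 30, errorRate = 0,
                             artifactScenario = FALSE) {
    tryCatch(
        new("SimulationConfig", seed = as.integer(seed),
            nContigs = as.integer(nContigs),
            contigLengthMedian = as.numeric(contigLengthMedian),
            contigLengthSigma = as.numeric(contigLengthSigma),
            minContigLength = as.integer(minContigLength),
            gcContent = as.numeric(gcContent),
            maskedFraction = as.numeric(maskedFraction),
            causalLength = as.integer(causalLength),
            nMutants = as.integer(nMutants),
            backgroundDensity = as.numeric(backgroundDensity),
            contaminantDensity = as.numeric(contaminantDensity),
            coverageLambda = as.numeric(coverageLambda),
            errorRate = as.numeric(errorRate),
            artifactScenario = as.logical(artifactScenario)),
        error = function(e) .configError("%s", conditionMessage(e)))
}

# --------------------------------------------------------- SimulatedExperiment

#' A complete synthetic experiment
#'
#' Container returned by \code{\link{simulateExperiment}}: the reference
#' assembly, the id of the planted causal contig, per-line pileup tables
#' (when kept in memory) or file paths, the machine-readable truth table of
#' planted substitutions, and the ids of planted contaminant lines and
#' artifact contigs.
#'
#' @slot assembly the \linkS4class{ReferenceAssembly}.
#' @slot causalContig id of the planted causal contig.
#' @slot truth data.frame: \code{lineId}, \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class} (causal / background / natural).
#' @slot pileups named list of in-memory pileup tables (possibly empty).
#' @slot pileupPaths named character vector of written mpileup paths
#'   (possibly empty).
#' @slot wtPileup wild-type self-mapping pileup table, or a zero-row table
#'   when the artifact scenario is off.
#' @slot lineIds all simulated line ids (EMS mutants, then contaminants).
#' @slot contaminantIds ids of planted contaminant lines.
#' @slot artifactContigs ids of planted chimeric-artifact contigs.
#' @slot config the \linkS4class{SimulationConfig} used.
#'
#' @name SimulatedExperiment-class
#' @aliases SimulatedExperiment-class
#' @exportClass SimulatedExperiment
setClass("SimulatedExperiment",
    representation(assembly = "ReferenceAssembly", causalContig = "character",
                   truth = "data.frame", pileups = "list",
                   pileupPaths = "character", wtPileup = "data.frame",
                   lineIds = "character", contaminantIds = "character",
                   artifactContigs = "character", config = "SimulationConfig"))
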