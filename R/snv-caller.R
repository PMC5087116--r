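# Per-mutant SNV calling: the coverage + near-fixed allele-frequency
# filters applied to each pileup column.

#' Call near-fixed SNVs for one mutant line
#'
#' Applies the per-column filters of the cross-mutant analysis to one
#' mutant's pileup.  A call is emitted at a position iff
#' \enumerate{
#'   \item the assembly base there is upper-case A/C/G/T (soft-masked and
#'     N positions are skipped entirely);
#'   \item the column depth is at least \code{minCoverage} (default 15);
#'   \item the unique highest-count non-reference base reaches
#'     \code{minAlleleFrequency} (default 99.99\%) of the
#'     substitution-supporting reads, i.e. of A+C+G+T counts.  Deletion
#'     and "other" symbols are excluded from the denominator: the filter
#'     targets substitutions, and \code{*} columns reflect alignment
#'     artifacts.  A tie among non-reference bases yields no call (neither
#'     can be near-fixed).
#' }
#' At the default 99.99\% threshold and depths below 10,000 this amounts
#' to requiring that \emph{zero} reads support any base other than the
#' alternate.  \code{callableBases} counts every position satisfying (1)
#' and (2) -- the coverage-robust denominator used for SNV densities.
#'
#' @param pileup a pileup table as returned by \code{\link{readMpileup}}
#'   or \code{\link{simulatePileup}}, or a path to an mpileup file.  Must
#'   be sorted by (contig, position).
#' @param assembly the \linkS4class{ReferenceAssembly}, which provides the
#'   masking status of every position.
#' @param config a \linkS4class{FilterConfig}.
#' @param mutantId identifier recorded in the returned call set.
#' @return a \linkS4class{MutantCallSet}.
#' @examples
#' asm <- ReferenceAssembly(c(c1 = strrep("G", 30)))
#' pu <- data.frame(contig = "c1", pos = 10L, ref = "G", depth = 20L,
#'                  A = 20L, C = 0L, G = 0L, T = 0L, del = 0L, other = 0L)
#' cs <- callMutantSnvs(pu, asm, FilterConfig(), "m1")
#' snvCalls(cs)   # one G>A call, frequency 1
#' @seealso \code{\link{sharedPositionFilter}},
#'   \code{\link{integrateCallSets}}
#' @export
callMutantSnvs <- function(pileup, assembly, config = FilterConfig(),
                           mutantId) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    if (!is(config, "FilterConfig"))
        .configError("config must be a FilterConfig")
    validObject(config)
    if (is.character(pileup) && length(pileup) == 1L)
        pileup <- readMpileup(pileup, assembly)
    .checkPileupTable(pileup)
    runs <- .checkPileupSorted(pileup)

    callable <- 0
    callableGc <- 0
    calls <- .emptyCalls()
    n <- nrow(pileup)
    if (n > 0L) {
        codes <- .assemblyCodes(assembly)
        unknown <- !(runs$values %in% names(codes$lens))
        if (any(unknown))
            .integrityError("pileup references unknown contig '%s'",
                            runs$values[unknown][1L])
        toolong <- pileup$pos[runs$ends] > codes$lens[runs$values]
        if (any(toolong))
            .integrityError("pileup position beyond end of contig '%s'",
                            runs$values[toolong][1L])
        # row-aligned reference codes via the memoised global code vector;
        # a pileup covering every position of every contig in assembly
        # order aligns with it directly
        if (n == length(codes$call) &&
            identical(runs$values, names(codes$lens)) &&
            identical(runs$ends, unname(cumsum(as.numeric(codes$lens))))) {
            refCode <- codes$call
        } else {
            rowOffset <- rep(codes$offsets[runs$values],
                             runs$ends - runs$starts + 1L)
            refCode <- codes$call[rowOffset + pileup$pos]
        }
        res <- .snv_filter(refCode, pileup$depth, pileup$A, pileup$C,
                           pileup$G, pileup$T, config@minCoverage,
                           config@minAlleleFrequency)
        callable <- res$callable
        callableGc <- res$callable_gc
        if (length(res$idx)) {
            hit <- res$idx
            ref <- BASES[refCode[hit] + 1L]
            alt <- BASES[res$alt + 1L]
            blk <- findInterval(hit, runs$starts)
            calls <- data.frame(
                contig = runs$values[blk], pos = pileup$pos[hit],
                ref = ref, alt = alt, frequency = res$freq,
                depth = pileup$depth[hit],
                canonical = .isCanonical(ref, alt),
                stringsAsFactors = FALSE)
            calls <- calls[order(calls$contig, calls$pos,
                                 method = "radix"), , drop = FALSE]
            rownames(calls) <- NULL
        }
    }
    MutantCallSet(mutantId = mutantId, calls = calls,
                  callableBases = callable, callableGcBases = callableGc)
}

#' Write a per-mutant call TSV
#'
#' @param callset a \linkS4class{MutantCallSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCallSet <- function(callset, path) {
    stopifnot(is(callset, "MutantCallSet"))
    out <- cbind(mutant_id = callset@mutantId, snvCalls(callset))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
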