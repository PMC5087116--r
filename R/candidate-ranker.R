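# Cross-mutant integration: shared-position filtering, per-contig mutant
# counts, the contig-by-mutant-count histogram and the ranked candidates.

#' Remove positions mutated in too many independent lines
#'
#' Independent EMS hits essentially never strike the same base in several
#' independently mutagenised lines, so a position carried by more than
#' \code{maxMutantsSharingPosition} distinct lines (default 2) indicates
#' pre-existing variation between the parent and the reference, or mapping
#' error.  Such positions are removed from \emph{all} call sets; every
#' other call passes unchanged.  Callable-base counts are untouched.
#'
#' @param callsets a list of \linkS4class{MutantCallSet} objects.
#' @param config a \linkS4class{FilterConfig}.
#' @return the filtered list of call sets, same order and ids.
#' @seealso \code{\link{integrateCallSets}}
#' @export
sharedPositionFilter <- function(callsets, config = FilterConfig()) {
    .checkCallsetList(callsets)
    validObject(config)
    if (length(callsets) == 0L)
        .configError("at least one call set is required")
    keys <- lapply(callsets, function(cs) {
        cl <- snvCalls(cs)
        paste(cl$contig, cl$pos, sep = "\r")
    })
    # each line contributes a position at most once, so counting keys over
    # the concatenation counts distinct lines per position
    tab <- table(unlist(keys, use.names = FALSE))
    banned <- names(tab)[tab > config@maxMutantsSharingPosition]
    if (length(banned) == 0L) return(callsets)
    lapply(seq_along(callsets), function(i) {
        cs <- callsets[[i]]
        keep <- !(keys[[i]] %in% banned)
        cl <- snvCalls(cs)[keep, , drop = FALSE]
        rownames(cl) <- NULL
        MutantCallSet(mutantId(cs), cl, callableBases(cs),
                      callableGcBases(cs))
    })
}

.checkCallsetList <- function(callsets) {
    if (!is.list(callsets) ||
        !all(vapply(callsets, is, logical(1), "MutantCallSet")))
        .configError("callsets must be a list of MutantCallSet objects")
    ids <- vapply(callsets, mutantId, character(1))
    if (anyDuplicated(ids))
        .configError("duplicate mutant id '%s' in call sets",
                     ids[anyDuplicated(ids)])
    invisible(ids)
}

#' Integrate call sets across mutant lines
#'
#' Counts, for every assembly contig, the number of mutant lines carrying
#' at least one surviving SNV on it, and tabulates the histogram of
#' contigs by that count (contigs with no SNV populate bin 0).  Reports
#' are ranked by number of mutated lines (descending), total SNVs
#' (descending), then contig id (ascending) -- a deterministic order.  A
#' contig is a candidate when it is mutated in at least
#' \code{minMutantsPerContig} lines and is not flagged as an assembly
#' artifact (see \code{\link{setArtifactFlags}}).
#'
#' @param callsets a list of \linkS4class{MutantCallSet} objects, already
#'   passed through \code{\link{sharedPositionFilter}}.
#' @param assembly the \linkS4class{ReferenceAssembly}.
#' @param config a \linkS4class{FilterConfig}.
#' @return a \linkS4class{ContigRanking}.
#' @examples
#' asm <- ReferenceAssembly(c(c1 = strrep("G", 50), c2 = strrep("C", 50)))
#' mk <- function(id, ctg, p) MutantCallSet(id, data.frame(
#'     contig = ctg, pos = p, ref = "G", alt = "A", frequency = 1,
#'     depth = 30L, canonical = TRUE), callableBases = 100)
#' rk <- integrateCallSets(list(mk("m1", "c1", 5L), mk("m2", "c1", 9L)),
#'                         asm, FilterConfig(minMutantsPerContig = 2L))
#' contigReports(rk)
#' @seealso \code{\link{reportCandidates}}, \code{\link{contigHistogram}}
#' @export
integrateCallSets <- function(callsets, assembly, config = FilterConfig()) {
    ids <- .checkCallsetList(callsets)
    stopifnot(is(assembly, "ReferenceAssembly"))
    validObject(config)
    all_contigs <- contigIds(assembly)
    calls <- data.table::rbindlist(lapply(callsets, function(cs) {
        cl <- snvCalls(cs)
        if (nrow(cl) == 0L) return(NULL)
        cbind(mutantId = mutantId(cs), cl)
    }))
    if (nrow(calls)) {
        missing <- setdiff(unique(calls$contig), all_contigs)
        if (length(missing))
            .integrityError("call set references contig '%s' absent from the assembly",
                            missing[1L])
        agg <- calls[, list(nMutantsMutated = length(unique(mutantId)),
                            totalSnvs = .N), by = "contig"]
    } else {
        agg <- data.table::data.table(contig = character(0),
                                      nMutantsMutated = integer(0),
                                      totalSnvs = integer(0))
    }
    reports <- data.frame(contig = all_contigs, stringsAsFactors = FALSE)
    i <- match(reports$contig, agg$contig)
    reports$nMutantsMutated <- ifelse(is.na(i), 0L, agg$nMutantsMutated[i])
    reports$totalSnvs <- ifelse(is.na(i), 0L, agg$totalSnvs[i])
    reports <- reports[order(-reports$nMutantsMutated, -reports$totalSnvs,
                             reports$contig, method = "radix"), ,
                       drop = FALSE]
    reports$rank <- seq_len(nrow(reports))
    reports$artifactFlag <- FALSE
    reports$isCandidate <- reports$nMutantsMutated >=
        config@minMutantsPerContig
    reports <- reports[, c("rank", "contig", "nMutantsMutated", "totalSnvs",
                           "artifactFlag", "isCandidate")]
    rownames(reports) <- NULL
    hist <- data.frame(
        nLinesMutated = 0:length(callsets),
        nContigs = as.integer(tabulate(reports$nMutantsMutated + 1L,
                                       nbins = length(callsets) + 1L)))
    new("ContigRanking", reports = reports, histogram = hist,
        calls = data.table::setDF(data.table::copy(calls)), lineIds = ids,
        minMutantsPerContig = config@minMutantsPerContig)
}

#' Propagate assembly-artifact flags into a ranking
#'
#' Marks the given contigs as artifacts (typically the output of
#' \code{\link{wildtypeSelfCheck}}) and recomputes candidacy: a flagged
#' contig is never reported as a candidate, whatever its mutant count.
#'
#' @param ranking a \linkS4class{ContigRanking}.
#' @param artifactContigs character vector of contig ids to flag.
#' @return the updated \linkS4class{ContigRanking}.
#' @export
setArtifactFlags <- function(ranking, artifactContigs) {
    stopifnot(is(ranking, "ContigRanking"))
    rep <- ranking@reports
    rep$artifactFlag <- rep$contig %in% artifactContigs
    rep$isCandidate <- rep$nMutantsMutated >= ranking@minMutantsPerContig &
        !rep$artifactFlag
    ranking@reports <- rep
    ranking
}

#' Ranked candidate contigs
#'
#' Returns the report rows with \code{isCandidate == TRUE}, in rank order:
#' contigs independently mutated in at least the configured number of
#' lines and not flagged as artifacts.
#'
#' @param ranking a \linkS4class{ContigRanking}.
#' @return a data.frame of candidate report rows.
#' @seealso \code{\link{integrateCallSets}}
#' @export
reportCandidates <- function(ranking) {
    stopifnot(is(ranking, "ContigRanking"))
    out <- ranking@reports[ranking@reports$isCandidate, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-contig, per-line SNV detail for reporting
#'
#' For each contig in \code{contigs}, a compact "pos ref>alt" listing per
#' mutant line, used in the candidate report TSV.
#'
#' @param ranking a \linkS4class{ContigRanking}.
#' @param contigs contig ids to describe.
#' @return a data.frame with columns \code{contig}, \code{mutantId},
#'   \code{snvs}.
#' @export
describeContigCalls <- function(ranking, contigs) {
    stopifnot(is(ranking, "ContigRanking"))
    cl <- ranking@calls
    cl <- cl[cl$contig %in% contigs, , drop = FALSE]
    if (nrow(cl) == 0L)
        return(data.frame(contig = character(0), mutantId = character(0),
                          snvs = character(0), stringsAsFactors = FALSE))
    cl <- cl[order(match(cl$contig, contigs), cl$mutantId, cl$pos), ,
             drop = FALSE]
    dt <- data.table::as.data.table(cl)
    out <- dt[, list(snvs = paste(sprintf("%d %s>%s", pos, ref, alt),
                                  collapse = "; ")),
              by = c("contig", "mutantId")]
    data.table::setDF(out)
}
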