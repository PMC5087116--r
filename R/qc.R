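# Cohort QC: contaminant flagging by SNV density, EMS spectrum summary,
# and assembly-artifact detection via the wild-type self-check.

#' Summarise one mutant line
#'
#' Computes the line's SNV count, callable bases, SNV density expressed as
#' callable bases per SNV, and the canonical (G>A / C>T) fraction of its
#' calls.  EMS-derived lines show densities on the order of one SNV per
#' several hundred kb and a canonical fraction near 1; a cultivar
#' contaminant shows an orders-of-magnitude denser, mixed-spectrum
#' profile.  With zero SNVs the density is reported as \code{NA}, never
#' infinite.
#'
#' @param callset a \linkS4class{MutantCallSet}.
#' @return a one-row data.frame with columns \code{mutantId},
#'   \code{nSnvs}, \code{callableBases}, \code{basesPerSnv},
#'   \code{canonicalFraction}, \code{contaminantFlag} (initially
#'   \code{FALSE}).
#' @seealso \code{\link{flagContaminants}}
#' @export
summarizeMutant <- function(callset) {
    stopifnot(is(callset, "MutantCallSet"))
    n <- nCalls(callset)
    data.frame(mutantId = mutantId(callset), nSnvs = n,
               callableBases = callableBases(callset),
               basesPerSnv = if (n > 0) callableBases(callset) / n
                             else NA_real_,
               canonicalFraction = canonicalFraction(callset),
               contaminantFlag = FALSE, stringsAsFactors = FALSE)
}

#' Flag cultivar contaminants by SNV density
#'
#' A line is flagged as a contaminant when its callable bases per SNV fall
#' below the cohort median divided by \code{ratioThreshold}.  The default
#' ratio of 20 sits far inside the observed contrast between genuine EMS
#' lines (one SNV per hundreds of kb) and a cultivar contaminant (one SNV
#' per ~1.6 kb, a ~240-fold difference), leaving wide margin on both
#' sides.  Lines with no SNVs (density \code{NA}) are never flagged and
#' are excluded from the median.  Flagging is scale-invariant: multiplying
#' every count and denominator by a constant leaves the flags unchanged.
#'
#' @param summaries a data.frame of rows from
#'   \code{\link{summarizeMutant}} (at least 3 rows; with fewer the check
#'   is skipped with a warning, flags left unset).
#' @param ratioThreshold flag densities this many times below the cohort
#'   median (default 20).
#' @return \code{summaries} with \code{contaminantFlag} updated.
#' @export
flagContaminants <- function(summaries, ratioThreshold = 20) {
    stopifnot(is.data.frame(summaries),
              all(c("mutantId", "basesPerSnv") %in% names(summaries)))
    if (ratioThreshold <= 1)
        .configError("ratioThreshold must be > 1")
    summaries$contaminantFlag <- FALSE
    if (nrow(summaries) < 3L) {
        warning("fewer than 3 lines: contaminant QC skipped",
                call. = FALSE)
        return(summaries)
    }
    med <- median(summaries$basesPerSnv, na.rm = TRUE)
    if (is.na(med)) {
        warning("no line has any SNV: contaminant QC skipped", call. = FALSE)
        return(summaries)
    }
    summaries$contaminantFlag <- !is.na(summaries$basesPerSnv) &
        summaries$basesPerSnv < med / ratioThreshold
    summaries
}

#' Flag assembly artifacts with a wild-type self-mapping check
#'
#' When wild-type reads are mapped back to their own assembly, a correctly
#' assembled contig shows essentially no fixed disagreements; a chimeric
#' or misassembled contig shows many.  For each contig this counts
#' positions that pass the coverage filter and carry a near-fixed
#' non-reference base (the same predicates as SNV calling), and flags
#' contigs whose count per unmasked kb exceeds
#' \code{disagreementPerKbThreshold}.  The default 0.5/kb is far above
#' sequencing-error expectation at the 99.99\% frequency filter while far
#' below the hundreds/kb a diverged haplotype produces.
#'
#' @param wtPileup wild-type self-mapping pileup table or mpileup path.
#' @param assembly the \linkS4class{ReferenceAssembly}.
#' @param config a \linkS4class{FilterConfig} (coverage and frequency
#'   thresholds reused).
#' @param disagreementPerKbThreshold flag contigs above this many fixed
#'   disagreements per unmasked kb (default 0.5).
#' @return character vector of flagged contig ids (possibly empty).  With
#'   \code{wtPileup = NULL} the check is skipped with a warning and an
#'   empty vector returned.
#' @seealso \code{\link{setArtifactFlags}}
#' @export
wildtypeSelfCheck <- function(wtPileup, assembly, config = FilterConfig(),
                              disagreementPerKbThreshold = 0.5) {
    if (is.null(wtPileup)) {
        warning("no wild-type self-mapping pileup: artifact check skipped",
                call. = FALSE)
        return(character(0))
    }
    cs <- callMutantSnvs(wtPileup, assembly, config, "wildtype_self")
    cl <- snvCalls(cs)
    if (nrow(cl) == 0L) return(character(0))
    counts <- table(cl$contig)
    kb <- unmaskedLengths(assembly)[names(counts)] / 1000
    flagged <- names(counts)[as.vector(counts) / kb >
                             disagreementPerKbThreshold]
    sort(flagged)
}
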