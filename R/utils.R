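# Internal helpers: classed conditions, base-code lookups, seeded evaluation.

BASES <- c("A", "C", "G", "T")

.stopCondition <- function(class, msg, ...) {
    stop(errorCondition(sprintf(msg, ...),
                        class = c(class, "emsHunter_error")))
}
.configError    <- function(msg, ...) .stopCondition("emsHunter_config_error", msg, ...)
.parseError     <- function(msg, ...) .stopCondition("emsHunter_parse_error", msg, ...)
.integrityError <- function(msg, ...) .stopCondition("emsHunter_integrity_error", msg, ...)
.ioError        <- function(msg, ...) .stopCondition("emsHunter_io_error", msg, ...)

# Lookup tables indexed by raw byte value + 1.
.CALL_CODE <- local({
    lut <- rep.int(-1L, 256L)
    lut[utf8ToInt("A") + 1L] <- 0L
    lut[utf8ToInt("C") + 1L] <- 1L
    lut[utf8ToInt("G") + 1L] <- 2L
    lut[utf8ToInt("T") + 1L] <- 3L
    lut
})
.FOLD_CODE <- local({
    lut <- rep.int(NA_integer_, 256L)
    for (b in c("A", "C", "G", "T")) {
        code <- match(b, BASES) - 1L
        lut[utf8ToInt(b) + 1L] <- code
        lut[utf8ToInt(tolower(b)) + 1L] <- code
    }
    lut[utf8ToInt("N") + 1L] <- 4L
    lut[utf8ToInt("n") + 1L] <- 4L
    lut
})

# Codes for the SNV caller: 0..3 for unmasked upper-case A/C/G/T, -1 for
# masked (lower-case) or N positions.
.callCodes <- function(seq) {
    .CALL_CODE[as.integer(charToRaw(seq)) + 1L]
}

# Case-folded codes for read simulation: reads report the genome base
# regardless of soft-masking.  0..3 = A,C,G,T; 4 = N.
.foldCodes <- function(seq) {
    codes <- .FOLD_CODE[as.integer(charToRaw(seq)) + 1L]
    if (anyNA(codes))
        .integrityError("sequence contains characters outside {A,C,G,T,N,a,c,g,t,n}")
    codes
}

# Memoised per-position code vectors over the concatenation of all
# contigs, plus offsets for (contig, pos) -> global index lookups.
.assemblyCodes <- function(assembly) {
    env <- assembly@cache
    if (is.null(env$codes)) {
        seqs <- as.character(assembly@sequences)
        lens <- Biostrings::width(assembly@sequences)
        env$codes <- list(
            call = unlist(lapply(seqs, .callCodes), use.names = FALSE),
            fold = unlist(lapply(seqs, .foldCodes), use.names = FALSE),
            lens = setNames(lens, names(seqs)),
            offsets = setNames(cumsum(c(0, head(as.numeric(lens), -1L))),
                               names(seqs)))
    }
    env$codes
}

# Memoised position-invariant pileup columns for whole-assembly
# simulation; shared across lines (copy-on-write makes that safe).
.assemblyStaticCols <- function(assembly) {
    env <- assembly@cache
    if (is.null(env$staticCols)) {
        codes <- .assemblyCodes(assembly)
        lens <- codes$lens
        n <- sum(as.numeric(lens))
        env$staticCols <- list(
            contig = rep(names(lens), lens),
            pos = as.integer(sequence(lens)),
            ref = c(BASES, "N")[codes$fold + 1L],
            del = integer(n))
    }
    env$staticCols
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
withSeed <- function(seed, expr) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has.seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Empty SNV call table with the canonical column layout.
.emptyCalls <- function() {
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               frequency = numeric(0), depth = integer(0),
               canonical = logical(0), stringsAsFactors = FALSE)
}

.isCanonical <- function(ref, alt) {
    (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

# Required columns of an in-memory pileup table.
.PILEUP_COLS <- c("contig", "pos", "ref", "depth", "A", "C", "G", "T",
                  "del", "other")

.checkPileupTable <- function(pileup) {
    if (!is.data.frame(pileup) || !all(.PILEUP_COLS %in% names(pileup)))
        .configError("pileup must be a data.frame with columns %s",
                     paste(.PILEUP_COLS, collapse = ", "))
    invisible(pileup)
}

# Contiguous contig blocks of a pileup table, detected on an integer
# recoding (rle on millions of strings is too slow).
.contigRuns <- function(contig) {
    n <- length(contig)
    if (n == 0L)
        return(list(values = character(0), starts = integer(0),
                    ends = integer(0)))
    f <- match(contig, unique(contig))
    change <- which(f[-1L] != f[-n])
    starts <- c(1L, change + 1L)
    list(values = contig[starts], starts = starts, ends = c(change, n))
}

# Pileup tables must be sorted by contig block then position, with each
# contig appearing in one contiguous block.  Tables built by
# simulatePileup() carry a provenance attribute so the O(n) re-scan is
# skipped; externally read tables are always scanned.
.checkPileupSorted <- function(pileup, runs = NULL) {
    if (isTRUE(attr(pileup, "emsHunterSorted"))) {
        runs <- attr(pileup, "emsHunterRuns")
        if (!is.null(runs)) return(invisible(runs))
        return(invisible(.contigRuns(pileup$contig)))
    }
    if (is.null(runs)) runs <- .contigRuns(pileup$contig)
    if (nrow(pileup) < 2L) return(invisible(runs))
    if (anyDuplicated(runs$values))
        .integrityError("pileup not sorted: contig '%s' appears in more than one block",
                        runs$values[anyDuplicated(runs$values)])
    noninc <- which(diff(pileup$pos) <= 0L)
    # position may only reset at a block boundary
    bad <- setdiff(noninc, runs$ends[-length(runs$ends)])
    if (length(bad))
        .integrityError("pileup not sorted by position within contig '%s'",
                        pileup$contig[bad[1L]])
    invisible(runs)
}
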