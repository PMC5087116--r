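# FASTA and samtools-mpileup text I/O -- the only code that touches raw
# formats.  Reading is gzip-transparent (gzfile() also accepts plain text).

#' Read a (repeat-masked) FASTA assembly
#'
#' Reads a FASTA file into a \linkS4class{ReferenceAssembly}, preserving
#' soft-masking case.  Lower-case bases and Ns count as masked; the GC and
#' unmasked-length accounting used throughout the package is computed over
#' upper-case bases only.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a \linkS4class{ReferenceAssembly}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGTacgt"), fa)
#' asm <- readFasta(fa)
#' gcUnmasked(asm)   # c1 = 2: only the upper-case G and C count
#' @seealso \code{\link{writeFasta}}
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        .ioError("FASTA file not found: %s", path)
    x <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                      .parseError("malformed FASTA '%s': %s", path,
                                  conditionMessage(e)))
    nm <- sub("\\s.*$", "", names(x))
    if (any(!nzchar(nm)))
        .parseError("malformed FASTA header at line %d of %s",
                    .fastaLineOfRecord(path, which(!nzchar(nm))[1L]), path)
    names(x) <- nm
    if (anyDuplicated(nm))
        .parseError("duplicate contig id '%s' in %s", nm[anyDuplicated(nm)],
                    path)
    ok <- Biostrings::letterFrequency(x, letters = "ACGTNacgtn") ==
        Biostrings::width(x)
    if (any(!ok)) {
        bad <- which(!ok)[1L]
        .parseError("illegal sequence character in record '%s' (near line %d) of %s",
                    nm[bad], .fastaBadLine(path), path)
    }
    new("ReferenceAssembly", sequences = x)
}

# Line number of the k-th header in a FASTA file.
.fastaLineOfRecord <- function(path, k) {
    lines <- readLines(gzfile(path), warn = FALSE)
    which(startsWith(lines, ">"))[k]
}

# First sequence line containing a character outside the legal alphabet.
.fastaBadLine <- function(path) {
    lines <- readLines(gzfile(path), warn = FALSE)
    seqline <- !startsWith(lines, ">")
    bad <- seqline & grepl("[^ACGTNacgtn]", lines)
    if (any(bad)) which(bad)[1L] else NA_integer_
}

#' Write an assembly to FASTA
#'
#' Writes contigs in order, headers from the contig ids, sequence wrapped
#' at 80 columns, masking case preserved.  \code{readFasta(writeFasta(x))}
#' reproduces ids and sequences byte-for-byte.
#'
#' @param assembly a \linkS4class{ReferenceAssembly}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readFasta}}
#' @export
writeFasta <- function(assembly, path) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    validObject(assembly)
    Biostrings::writeXStringSet(assembly@sequences, path, width = 80L)
    invisible(path)
}

#' Read a samtools mpileup file
#'
#' Parses six-column samtools mpileup text (contig, 1-based position,
#' reference base, depth, read bases, base qualities) into a per-column
#' base-count table.  The read-base string is decoded per the standard
#' mpileup grammar: \code{.}/\code{,} count as the reference base,
#' A/C/G/T (either case) as that base, \code{*} as a deletion,
#' \code{>}/\code{<}/N as "other"; \code{^} (plus the following mapping
#' quality), \code{$} and \code{+n}/\code{-n} indel suffixes are consumed
#' without being counted.  Decoded counts must sum to the stated depth.
#' Base and mapping qualities are parsed but ignored: all downstream
#' filters operate on counts (the mapping pipeline this format comes from
#' disables BAQ).
#'
#' @param path path to an mpileup file (optionally gzip-compressed).
#' @param assembly the \linkS4class{ReferenceAssembly} the reads were
#'   mapped to; used to validate contig ids and positions.
#' @return a data.frame with columns \code{contig}, \code{pos},
#'   \code{ref} (upper-cased), \code{depth}, \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{del}, \code{other}.  Positions absent from the file
#'   have zero depth and are simply not represented.
#' @examples
#' asm <- ReferenceAssembly(c(c1 = strrep("G", 20)))
#' mp <- tempfile(fileext = ".mpileup")
#' writeLines("c1\t10\tG\t5\t,,AA.\tIIIII", mp)
#' readMpileup(mp, asm)   # counts G = 3, A = 2
#' @seealso \code{\link{writeMpileup}}, \code{\link{callMutantSnvs}}
#' @export
readMpileup <- function(path, assembly) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    if (!file.exists(path))
        .ioError("mpileup file not found: %s", path)
    lines <- readLines(gzfile(path), warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(.emptyPileupTable())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 6L))
        .parseError("line %d of %s has %d fields (expected 6)",
                    which(nf != 6L)[1L], path, nf[which(nf != 6L)[1L]])
    m <- matrix(unlist(parts, use.names = FALSE), ncol = 6L, byrow = TRUE)
    contig <- m[, 1L]
    pos <- suppressWarnings(as.integer(m[, 2L]))
    depth <- suppressWarnings(as.integer(m[, 4L]))
    if (anyNA(pos) || any(pos < 1L))
        .parseError("non-numeric or non-positive position at line %d of %s",
                    which(is.na(pos) | pos < 1L)[1L], path)
    if (anyNA(depth) || any(depth < 0L))
        .parseError("invalid depth at line %d of %s",
                    which(is.na(depth) | depth < 0L)[1L], path)
    lens <- contigLengths(assembly)
    unknown <- !(contig %in% names(lens))
    if (any(unknown))
        .integrityError("unknown contig id '%s' at line %d of %s",
                        contig[unknown][1L], which(unknown)[1L], path)
    toolong <- pos > lens[contig]
    if (any(toolong))
        .integrityError("position %d beyond end of contig '%s' in %s",
                        pos[toolong][1L], contig[toolong][1L], path)
    counts <- tryCatch(
        .decode_read_bases(m[, 5L], m[, 3L], depth, contig, pos),
        error = function(e) .parseError("in %s: %s", path,
                                        conditionMessage(e)))
    data.frame(contig = contig, pos = pos, ref = toupper(m[, 3L]),
               depth = depth, A = counts[, 1L], C = counts[, 2L],
               G = counts[, 3L], T = counts[, 4L], del = counts[, 5L],
               other = counts[, 6L], stringsAsFactors = FALSE)
}

.emptyPileupTable <- function() {
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               depth = integer(0), A = integer(0), C = integer(0),
               G = integer(0), T = integer(0), del = integer(0),
               other = integer(0), stringsAsFactors = FALSE)
}

#' Write pileup columns as samtools mpileup text
#'
#' Emits one canonical mpileup dialect: reference reads as \code{.},
#' alternate reads as upper-case bases, deletions as \code{*}, "other"
#' reads as \code{>}, a constant base quality \code{I}.  Columns must be
#' sorted by (contig, position) with each contig contiguous; zero-depth
#' columns are omitted, as samtools does.
#' \code{readMpileup(writeMpileup(x))} reproduces identical counts.
#'
#' @param pileup a pileup table (layout as \code{\link{readMpileup}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readMpileup}}
#' @export
writeMpileup <- function(pileup, path) {
    .checkPileupTable(pileup)
    .checkPileupSorted(pileup)
    keep <- pileup$depth > 0L
    pileup <- pileup[keep, , drop = FALSE]
    n <- nrow(pileup)
    if (n == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    total <- pileup$A + pileup$C + pileup$G + pileup$T + pileup$del +
        pileup$other
    if (any(total != pileup$depth))
        .integrityError("column counts do not sum to depth at %s:%d",
                        pileup$contig[which(total != pileup$depth)[1L]],
                        pileup$pos[which(total != pileup$depth)[1L]])
    ref <- toupper(pileup$ref)
    # reference reads first, then alternates in A,C,G,T order
    refCnt <- integer(n)
    for (b in BASES) refCnt[ref == b] <- pileup[[b]][ref == b]
    bases <- strrep(".", refCnt)
    for (b in BASES) {
        cnt <- ifelse(ref == b, 0L, pileup[[b]])
        bases <- paste0(bases, strrep(b, cnt))
    }
    bases <- paste0(bases, strrep("*", pileup$del),
                    strrep(">", pileup$other))
    quals <- strrep("I", pileup$depth)
    writeLines(paste(pileup$contig, pileup$pos, ref, pileup$depth, bases,
                     quals, sep = "\t"), path)
    invisible(path)
}
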