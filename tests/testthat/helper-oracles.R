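# Independent brute-force oracles and fixture builders.  These re-derive
# expected results by the most literal possible route, character by
# character and column by column, deliberately sharing no code with the
# package internals they check.

# --- mpileup read-base decoder: a plain character machine -------------------
oracleDecodeBases <- function(s, ref) {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L, other = 0L)
    chars <- strsplit(s, "")[[1]]
    refU <- toupper(ref)
    i <- 1L
    while (i <= length(chars)) {
        ch <- chars[i]
        if (ch == "^") { i <- i + 2L; next }
        if (ch == "$") { i <- i + 1L; next }
        if (ch %in% c("+", "-")) {
            j <- i + 1L
            num <- ""
            while (j <= length(chars) && chars[j] %in% as.character(0:9)) {
                num <- paste0(num, chars[j])
                j <- j + 1L
            }
            i <- j + as.integer(num)
            next
        }
        b <- if (ch %in% c(".", ",")) refU else toupper(ch)
        if (b %in% c("A", "C", "G", "T")) counts[b] <- counts[b] + 1L
        else if (ch == "*") counts["del"] <- counts["del"] + 1L
        else counts["other"] <- counts["other"] + 1L
        i <- i + 1L
    }
    counts
}

# Random legal read-base string; returns the string and its depth (number
# of counted symbols).
randomReadBaseString <- function() {
    n <- sample(1:40, 1)
    syms <- sample(c(".", ",", "A", "C", "G", "T", "a", "c", "g", "t",
                     "*", ">", "<", "N", "n"), n, replace = TRUE,
                   prob = c(20, 20, rep(2, 8), 1, 0.5, 0.5, 0.5, 0.5))
    out <- character(0)
    for (s in syms) {
        if (runif(1) < 0.05)   # start-of-read marker + mapping quality
            out <- c(out, paste0("^", rawToChar(as.raw(sample(33:120, 1)))))
        out <- c(out, s)
        if (runif(1) < 0.05) out <- c(out, "$")
        if (runif(1) < 0.05) { # indel suffix, consumed but not counted
            len <- sample(1:12, 1)
            out <- c(out, paste0(sample(c("+", "-"), 1), len,
                                 paste(sample(c("A", "C", "G", "T"), len,
                                              replace = TRUE),
                                       collapse = "")))
        }
    }
    list(string = paste(out, collapse = ""), depth = n)
}

# --- per-column SNV filter, applied literally -------------------------------
# asmChar: the assembly character at the position (case preserved).
oracleCallColumn <- function(asmChar, counts, depth, minCov, minAF) {
    if (!asmChar %in% c("A", "C", "G", "T")) return(NULL)   # masked or N
    if (depth < minCov) return(NULL)
    sub <- counts[c("A", "C", "G", "T")]
    denom <- sum(sub)
    if (denom == 0) return(NULL)
    nonref <- sub[setdiff(names(sub), asmChar)]
    best <- max(nonref)
    if (best == 0 || sum(nonref == best) > 1) return(NULL)
    alt <- names(nonref)[which.max(nonref)]
    if (best / denom < minAF) return(NULL)
    list(ref = asmChar, alt = alt, frequency = best / denom)
}

# Run the oracle over a whole pileup table against an assembly given as a
# named character vector of sequences.
oracleCallTable <- function(pileup, seqs, minCov, minAF) {
    out <- list()
    callable <- 0L
    for (i in seq_len(nrow(pileup))) {
        ctg <- pileup$contig[i]
        asmChar <- substr(seqs[[ctg]], pileup$pos[i], pileup$pos[i])
        if (asmChar %in% c("A", "C", "G", "T") &&
            pileup$depth[i] >= minCov)
            callable <- callable + 1L
        cl <- oracleCallColumn(asmChar,
                               c(A = pileup$A[i], C = pileup$C[i],
                                 G = pileup$G[i], T = pileup$T[i]),
                               pileup$depth[i], minCov, minAF)
        if (!is.null(cl))
            out[[length(out) + 1L]] <- data.frame(
                contig = ctg, pos = pileup$pos[i], ref = cl$ref,
                alt = cl$alt, stringsAsFactors = FALSE)
    }
    list(calls = if (length(out)) do.call(rbind, out) else
             data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0)),
         callable = callable)
}

# --- shared-position filter by position multiset counting -------------------
oracleSharedFilter <- function(callTables, maxShared) {
    all <- do.call(rbind, lapply(names(callTables), function(id)
        cbind(mutant = id, callTables[[id]][, c("contig", "pos")])))
    if (is.null(all) || nrow(all) == 0L) return(callTables)
    key <- paste(all$contig, all$pos)
    nMut <- tapply(all$mutant, key, function(m) length(unique(m)))
    banned <- names(nMut)[nMut > maxShared]
    lapply(callTables, function(tab) {
        tab[!(paste(tab$contig, tab$pos) %in% banned), , drop = FALSE]
    })
}

# --- fixture builders -------------------------------------------------------
# A one-row pileup table.
pileupRow <- function(contig, pos, ref, A = 0L, C = 0L, G = 0L, T = 0L,
                      del = 0L, other = 0L,
                      depth = A + C + G + T + del + other) {
    data.frame(contig = contig, pos = as.integer(pos), ref = ref,
               depth = as.integer(depth), A = as.integer(A),
               C = as.integer(C), G = as.integer(G), T = as.integer(T),
               del = as.integer(del), other = as.integer(other),
               stringsAsFactors = FALSE)
}

# A MutantCallSet built directly from (contig, pos) pairs.
makeCallSet <- function(id, contig, pos, ref = "G", alt = "A",
                        callable = 1e6) {
    n <- length(pos)
    calls <- data.frame(contig = contig, pos = as.integer(pos),
                        ref = rep_len(ref, n), alt = rep_len(alt, n),
                        frequency = rep(1, n), depth = rep(30L, n),
                        stringsAsFactors = FALSE)
    calls$canonical <- (calls$ref == "G" & calls$alt == "A") |
        (calls$ref == "C" & calls$alt == "T")
    calls <- calls[order(calls$contig, calls$pos, method = "radix"), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    MutantCallSet(id, calls, callableBases = callable)
}

# Random assembly of short contigs as a plain named character vector.
randomSeqs <- function(nContigs, minLen = 30, maxLen = 120) {
    lens <- sample(minLen:maxLen, nContigs, replace = TRUE)
    seqs <- vapply(lens, function(l)
        paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"), l,
                     replace = TRUE,
                     prob = c(rep(0.22, 4), rep(0.025, 4), 0.02)),
              collapse = ""), character(1))
    names(seqs) <- sprintf("ctg%03d", seq_len(nContigs))
    seqs
}
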