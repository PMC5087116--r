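# Synthetic EMS-experiment generator: reference assembly, per-line mutant
# genomes (as substitution tables), pileup columns, and a truth table.
# Pileups are synthesized directly from the genomes -- read simulation and
# mapping are deliberately out of scope, since the analysis consumes
# mpileup columns only.

.BASE_BYTES <- charToRaw("ACGT")

# Draw one contig sequence as an integer code vector (0..3) at the target
# GC content, then soft-mask `target` bases in contiguous blocks.
# Returns the sequence string with masked blocks lower-cased.
.drawContig <- function(len, gcContent, maskedFraction) {
    prob <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
              (1 - gcContent) / 2)
    codes <- sample.int(4L, len, replace = TRUE, prob = prob)
    bytes <- .BASE_BYTES[codes]
    target <- round(maskedFraction * len)
    if (target > 0) {
        ranges <- IRanges::IRanges()
        guard <- 0L
        while (TRUE) {
            covered <- sum(IRanges::width(ranges))
            if (covered >= target || guard > 50L) break
            need <- max(1L, ceiling((target - covered) / 300))
            bl <- pmax(50L, round(rlnorm(need, log(300), 0.5)))
            st <- sample.int(len, need, replace = TRUE)
            add <- IRanges::restrict(IRanges::IRanges(st, width = bl),
                                     1L, len)
            ranges <- IRanges::reduce(c(ranges, add))
            guard <- guard + 1L
        }
        if (length(ranges)) {
            idx <- unlist(Map(seq.int, IRanges::start(ranges),
                              IRanges::end(ranges)), use.names = FALSE)
            bytes[idx] <- as.raw(as.integer(bytes[idx]) + 32L)
        }
    }
    rawToChar(bytes)
}

.makeReferenceImpl <- function(config) {
    n <- config@nContigs
    len <- round(rlnorm(n, log(config@contigLengthMedian),
                        config@contigLengthSigma))
    for (it in 1:100) {
        short <- which(len < config@minContigLength)
        if (!length(short)) break
        len[short] <- round(rlnorm(length(short),
                                   log(config@contigLengthMedian),
                                   config@contigLengthSigma))
    }
    len[len < config@minContigLength] <- config@minContigLength
    ci <- sample.int(n, 1L)
    len[ci] <- config@causalLength
    ids <- sprintf("contig_%05d", seq_len(n))
    seqs <- vapply(len, .drawContig, character(1),
                   gcContent = config@gcContent,
                   maskedFraction = config@maskedFraction)
    names(seqs) <- ids
    list(assembly = ReferenceAssembly(seqs), causalContig = ids[ci])
}

#' Simulate a reference assembly
#'
#' Draws \code{nContigs} contigs with i.i.d. bases at the configured GC
#' content, lengths from a log-normal distribution truncated below at
#' \code{minContigLength}, and the configured fraction of bases
#' soft-masked (lower-cased) in contiguous blocks.  One randomly chosen
#' contig is designated causal and given length \code{causalLength}.
#' Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a list with elements \code{assembly}
#'   (a \linkS4class{ReferenceAssembly}) and \code{causalContig} (its id).
#' @examples
#' ref <- makeReference(SimulationConfig(seed = 7L, nContigs = 10L))
#' ref$causalContig
#' @seealso \code{\link{simulateExperiment}}
#' @export
makeReference <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(config@seed, .makeReferenceImpl(config))
}

#' Plant canonical EMS background mutations
#'
#' Mutates each unmasked G/C site independently with probability
#' \code{density / g}, where \code{g} is the unmasked G/C fraction of the
#' assembly, so the expected genome-wide count is \code{density} times the
#' unmasked length.  Only the canonical EMS changes are produced: G>A and
#' C>T.  Implemented as a single binomial draw of the total count followed
#' by uniform placement without replacement over G/C sites -- exactly
#' equivalent to independent per-site Bernoulli trials.  Consumes the
#' caller's RNG stream.
#'
#' @param assembly a \linkS4class{ReferenceAssembly}.
#' @param density canonical mutations per unmasked bp.
#' @return a data.frame of substitutions: \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @seealso \code{\link{mutagenizeNatural}}, \code{\link{plantCausal}}
#' @export
mutagenizeEms <- function(assembly, density) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    if (density < 0) .configError("density must be >= 0")
    gcPer <- gcUnmasked(assembly)
    gcTot <- sum(as.numeric(gcPer))
    unmTot <- sum(as.numeric(unmaskedLengths(assembly)))
    if (density == 0 || gcTot == 0) return(.emptySubs())
    g <- gcTot / unmTot
    p <- density / g
    if (p > 1)
        .configError("density/g = %.3g exceeds 1: no per-site probability exists",
                     p)
    count <- rbinom(1L, gcTot, p)
    if (count == 0L) return(.emptySubs())
    idx <- sort(sample.int(gcTot, count))
    .mapSiteIndices(assembly, idx, gcPer, gcSitesOnly = TRUE)
}

#' Plant all-spectrum natural variation (cultivar contaminant)
#'
#' Substitutes each unmasked site independently with probability
#' \code{density}, the alternate base drawn uniformly from the three
#' non-reference bases -- the mixed-spectrum, high-density profile of a
#' line that is not derived from the mutagenised parent.  Consumes the
#' caller's RNG stream.
#'
#' @inheritParams mutagenizeEms
#' @param density substitutions per unmasked bp.
#' @return a substitution data.frame (layout as
#'   \code{\link{mutagenizeEms}}).
#' @export
mutagenizeNatural <- function(assembly, density) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    if (density < 0 || density > 1)
        .configError("density must be in [0, 1]")
    unmPer <- unmaskedLengths(assembly)
    unmTot <- sum(as.numeric(unmPer))
    if (density == 0 || unmTot == 0) return(.emptySubs())
    count <- rbinom(1L, unmTot, density)
    if (count == 0L) return(.emptySubs())
    idx <- sort(sample.int(unmTot, count))
    subs <- .mapSiteIndices(assembly, idx, unmPer, gcSitesOnly = FALSE)
    refCode <- match(subs$ref, BASES) - 1L
    subs$alt <- BASES[((refCode + sample.int(3L, nrow(subs),
                                             replace = TRUE)) %% 4L) + 1L]
    subs
}

.emptySubs <- function() {
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
}

# Map sorted global site indices (over the concatenation of per-contig
# unmasked [G/C] sites) back to (contig, pos, ref) and apply the canonical
# alternate for G/C sites.
.mapSiteIndices <- function(assembly, idx, perContig, gcSitesOnly) {
    cum <- cumsum(as.numeric(perContig))
    k <- findInterval(idx - 0.5, c(0, cum))
    local <- idx - c(0, cum)[k]
    out <- vector("list", length(unique(k)))
    u <- unique(k)
    for (j in seq_along(u)) {
        ki <- u[j]
        ctg <- names(perContig)[ki]
        codes <- .callCodes(contigSequence(assembly, ctg))
        sites <- if (gcSitesOnly) which(codes == 1L | codes == 2L)
                 else which(codes >= 0L)
        pos <- sites[local[k == ki]]
        ref <- BASES[codes[pos] + 1L]
        alt <- ifelse(ref == "G", "A", ifelse(ref == "C", "T", NA))
        out[[j]] <- data.frame(contig = ctg, pos = pos, ref = ref,
                               alt = alt, stringsAsFactors = FALSE)
    }
    data.table::setDF(data.table::rbindlist(out))
}

#' Plant one causal lesion per mutant line
#'
#' Gives every mutant line exactly one additional canonical mutation at a
#' distinct unmasked G/C position of the causal contig, sampled without
#' replacement across lines.  Consumes the caller's RNG stream.
#'
#' @param assembly a \linkS4class{ReferenceAssembly}.
#' @param causalContig id of the causal contig.
#' @param lineIds ids of the mutant lines (one lesion each).
#' @return a data.frame: \code{lineId}, \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @export
plantCausal <- function(assembly, causalContig, lineIds) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    codes <- .callCodes(contigSequence(assembly, causalContig))
    sites <- which(codes == 1L | codes == 2L)
    if (length(sites) < length(lineIds))
        .configError("causal contig '%s' has only %d unmasked G/C sites for %d lines",
                     causalContig, length(sites), length(lineIds))
    pos <- sample(sites, length(lineIds))
    ref <- BASES[codes[pos] + 1L]
    data.frame(lineId = lineIds, contig = causalContig, pos = pos,
               ref = ref, alt = ifelse(ref == "G", "A", "T"),
               stringsAsFactors = FALSE)
}

#' Simulate pileup columns for one line
#'
#' Synthesizes per-position pileup columns for a mutant genome defined as
#' the reference plus a substitution table.  Depth is Poisson with mean
#' \code{coverageLambda}; each read reports the genome base with
#' probability \code{1 - errorRate}, otherwise one of the other three
#' bases uniformly.  Soft-masked positions are sequenced like any other
#' (masking is an annotation of the assembly, not of the reads); N
#' positions produce "other" counts.  Zero-depth positions are omitted,
#' as samtools does.  Consumes the caller's RNG stream.
#'
#' @param assembly a \linkS4class{ReferenceAssembly}.
#' @param substitutions a substitution data.frame (\code{contig},
#'   \code{pos}, \code{alt}; e.g. from \code{\link{mutagenizeEms}}), or
#'   \code{NULL} for wild-type reads.
#' @param contigs contig ids to simulate (default: all, in assembly
#'   order).
#' @param coverageLambda mean read depth.
#' @param errorRate per-read-base miscall probability.
#' @return a pileup table (layout as \code{\link{readMpileup}}).
#' @examples
#' asm <- ReferenceAssembly(c(c1 = strrep("ACGT", 25)))
#' set.seed(1)
#' pu <- simulatePileup(asm, NULL, coverageLambda = 20)
#' head(pu)
#' @export
simulatePileup <- function(assembly, substitutions = NULL, contigs = NULL,
                           coverageLambda = 30, errorRate = 0) {
    stopifnot(is(assembly, "ReferenceAssembly"))
    if (coverageLambda <= 0) .configError("coverageLambda must be > 0")
    if (errorRate < 0 || errorRate > 1)
        .configError("errorRate must be in [0, 1]")
    whole <- is.null(contigs)
    if (whole) contigs <- contigIds(assembly)
    lens <- contigLengths(assembly)[contigs]
    n <- sum(as.numeric(lens))
    if (n == 0) return(.emptyPileupTable())
    # one concatenated pass over all requested contigs; position-invariant
    # columns are memoised on the assembly for whole-assembly simulation
    if (whole) {
        codes <- .assemblyCodes(assembly)
        st <- .assemblyStaticCols(assembly)
        mutCode <- codes$fold
        offset <- codes$offsets
    } else {
        mutCode <- unlist(lapply(contigs, function(ctg)
            .foldCodes(contigSequence(assembly, ctg))), use.names = FALSE)
        offset <- setNames(cumsum(c(0, as.numeric(lens[-length(lens)]))),
                           contigs)
        st <- list(contig = rep(contigs, lens),
                   pos = as.integer(sequence(lens)),
                   ref = c(BASES, "N")[mutCode + 1L],
                   del = integer(n))
    }
    if (!is.null(substitutions) && nrow(substitutions)) {
        s <- substitutions[substitutions$contig %in% contigs, ,
                           drop = FALSE]
        if (nrow(s)) {
            if (any(s$pos < 1L | s$pos > lens[s$contig]))
                .integrityError("substitution outside contig bounds")
            mutCode[offset[s$contig] + s$pos] <- match(s$alt, BASES) - 1L
        }
    }
    depth <- rpois(n, coverageLambda)
    cols <- .fill_columns(mutCode, depth, errorRate)
    out <- list(contig = st$contig, pos = st$pos, ref = st$ref,
                depth = depth, A = cols$A, C = cols$C, G = cols$G,
                T = cols$T, del = st$del, other = cols$other)
    dropped <- any(depth == 0L)
    if (dropped) {                 # samtools omits zero-depth positions
        keep <- which(depth > 0L)
        out <- lapply(out, `[`, keep)
    }
    data.table::setDF(out)
    # provenance: sorted by construction, so downstream validation can
    # skip the O(n) re-scan
    attr(out, "emsHunterSorted") <- TRUE
    if (!dropped) {
        ends <- cumsum(as.numeric(lens))
        attr(out, "emsHunterRuns") <- list(
            values = contigs, starts = c(1, head(ends, -1L) + 1),
            ends = ends)
    }
    out
}

# At a chimeric (artifact) contig the mismapped second haplotype leaves
# divergent columns near -- but not at -- fixation, so each line calls an
# independent random subset of them and the shared-position filter cannot
# remove them all.  Emulated by re-drawing the divergent columns as a
# 97/3 alternate/reference read mixture (a column survives the zero-
# dissent filter with probability 0.97^depth, ~0.4 at 30x).
.ARTIFACT_ALT_FREQ <- 0.97

.applyMixtureColumns <- function(pileup, subs, freq = .ARTIFACT_ALT_FREQ) {
    if (nrow(subs) == 0L) return(pileup)
    for (ctg in unique(subs$contig)) {
        rows <- which(pileup$contig == ctg)
        s <- subs[subs$contig == ctg, , drop = FALSE]
        idx <- rows[match(s$pos, pileup$pos[rows])]
        ok <- !is.na(idx)
        idx <- idx[ok]; s <- s[ok, , drop = FALSE]
        d <- pileup$depth[idx]
        altN <- rbinom(length(idx), d, freq)
        for (b in BASES) {
            v <- pileup[[b]]
            v[idx] <- ifelse(s$alt == b, altN,
                             ifelse(s$ref == b, d - altN, 0L))
            pileup[[b]] <- as.integer(v)
        }
    }
    pileup
}

# Drop truth rows hit twice in the same line at the same position (e.g. a
# background mutation coinciding with the planted causal lesion); earlier
# rows win, so order causal rows first when it matters.
.dedupeTruth <- function(truth) {
    key <- paste(truth$lineId, truth$contig, truth$pos, sep = "\r")
    truth[!duplicated(key), , drop = FALSE]
}

#' Simulate a complete cross-mutant experiment
#'
#' Generates, deterministically from \code{config@seed}, a full synthetic
#' experiment: the reference assembly with a designated causal contig;
#' per-line canonical EMS background mutations plus exactly one causal
#' lesion per mutant; optionally one contaminant line with all-spectrum
#' natural variation and no causal lesion; optionally a chimeric artifact
#' contig (second half 1\% divergent from the genome the reads derive
#' from) together with a wild-type self-mapping pileup that exposes it;
#' and Poisson-coverage pileup columns for every line.  Per-line RNG
#' streams are derived from the master seed, so any one line is
#' reproducible in isolation.
#'
#' When \code{dir} is given, the experiment is also written out as plain
#' text: \code{reference.fasta}, one \code{<lineId>.mpileup} per line,
#' \code{wt_self.mpileup} under the artifact scenario, \code{truth.tsv}
#' and a \code{manifest.txt} echoing every configuration value.  Rerunning
#' with the same configuration reproduces the files byte for byte.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory (created if needed).
#' @param keepPileups keep per-line pileup tables in memory (default:
#'   yes when no \code{dir} is given).  For large simulations combine
#'   \code{dir} with \code{keepPileups = FALSE}.
#' @return a \linkS4class{SimulatedExperiment}.
#' @examples
#' sim <- simulateExperiment(SimulationConfig(seed = 3L, nContigs = 20L,
#'     contigLengthMedian = 1500, nMutants = 3L,
#'     backgroundDensity = 1e-4, causalLength = 2000L))
#' sim
#' head(truthTable(sim))
#' @export
simulateExperiment <- function(config, dir = NULL,
                               keepPileups = is.null(dir)) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    nMut <- config@nMutants
    mutantIds <- sprintf("mutant_%02d", seq_len(nMut))
    contamIds <- if (config@contaminantDensity > 0) "contaminant_01"
                 else character(0)
    lineIds <- c(mutantIds, contamIds)

    # master-seed draws: reference, causal placement, artifact divergence
    master <- withSeed(config@seed, {
        ref <- .makeReferenceImpl(config)
        causalTruth <- plantCausal(ref$assembly, ref$causalContig,
                                   mutantIds)
        artifact <- NULL
        if (config@artifactScenario) {
            aseq <- .drawContig(10000L, config@gcContent, 0)
            aid <- "artifact_00001"
            seqs <- c(as.character(ref$assembly@sequences),
                      setNames(aseq, aid))
            ref$assembly <- ReferenceAssembly(seqs)
            codes <- .foldCodes(aseq)
            half <- 5001:10000
            hit <- half[runif(length(half)) < 0.01]
            refb <- BASES[codes[hit] + 1L]
            altb <- BASES[((codes[hit] +
                            sample.int(3L, length(hit), replace = TRUE)) %%
                           4L) + 1L]
            artifact <- list(id = aid,
                             subs = data.frame(contig = aid, pos = hit,
                                               ref = refb, alt = altb,
                                               stringsAsFactors = FALSE))
        }
        list(ref = ref, causalTruth = causalTruth, artifact = artifact)
    })
    assembly <- master$ref$assembly
    causal <- master$ref$causalContig
    artifactSubs <- if (is.null(master$artifact)) .emptySubs()
                    else master$artifact$subs
    artifactIds <- if (is.null(master$artifact)) character(0)
                   else master$artifact$id

    # per-line mutation streams: seed + line index
    truthParts <- list()
    lineSubs <- vector("list", length(lineIds))
    names(lineSubs) <- lineIds
    for (i in seq_along(lineIds)) {
        id <- lineIds[i]
        subs <- withSeed(config@seed + i, {
            if (id %in% contamIds)
                mutagenizeNatural(assembly, config@contaminantDensity)
            else
                mutagenizeEms(assembly, config@backgroundDensity)
        })
        if (id %in% contamIds) {
            truth <- if (nrow(subs))
                cbind(lineId = id, subs, class = "natural",
                      stringsAsFactors = FALSE) else NULL
        } else {
            causalRow <- master$causalTruth[
                master$causalTruth$lineId == id, , drop = FALSE]
            truth <- rbind(
                cbind(causalRow[, c("contig", "pos", "ref", "alt")],
                      lineId = id, class = "causal",
                      stringsAsFactors = FALSE),
                if (nrow(subs)) cbind(subs, lineId = id,
                                      class = "background",
                                      stringsAsFactors = FALSE))
        }
        if (!is.null(truth)) {
            truth <- truth[, c("lineId", "contig", "pos", "ref", "alt",
                               "class")]
            truth <- .dedupeTruth(truth)
            truthParts[[length(truthParts) + 1L]] <- truth
            lineSubs[[id]] <- truth[, c("contig", "pos", "ref", "alt")]
        } else {
            lineSubs[[id]] <- .emptySubs()
        }
    }
    truth <- data.table::setDF(data.table::rbindlist(truthParts))

    # pileups: seed + 1000 + line index; wt self-mapping: seed + 999
    if (!is.null(dir)) {
        ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                            showWarnings = FALSE)
        if (!ok || file.access(dir, 2L) != 0L)
            .ioError("cannot write to directory '%s'", dir)
    }
    pileups <- list()
    paths <- character(0)
    for (i in seq_along(lineIds)) {
        id <- lineIds[i]
        subs <- rbind(lineSubs[[id]], artifactSubs)
        pu <- withSeed(config@seed + 1000L + i, {
            p <- simulatePileup(assembly, subs,
                                coverageLambda = config@coverageLambda,
                                errorRate = config@errorRate)
            .applyMixtureColumns(p, artifactSubs)
        })
        if (!is.null(dir)) {
            p <- file.path(dir, paste0(id, ".mpileup"))
            writeMpileup(pu, p)
            paths[id] <- p
        }
        if (keepPileups) pileups[[id]] <- pu
    }
    wtPileup <- .emptyPileupTable()
    if (config@artifactScenario) {
        wtPileup <- withSeed(config@seed + 999L, {
            p <- simulatePileup(assembly, artifactSubs,
                                coverageLambda = config@coverageLambda,
                                errorRate = config@errorRate)
            .applyMixtureColumns(p, artifactSubs)
        })
        if (!is.null(dir))
            writeMpileup(wtPileup, file.path(dir, "wt_self.mpileup"))
    }
    if (!is.null(dir)) {
        writeFasta(assembly, file.path(dir, "reference.fasta"))
        write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        .writeManifest(config, causal, lineIds, contamIds, artifactIds,
                       file.path(dir, "manifest.txt"))
    }
    new("SimulatedExperiment", assembly = assembly, causalContig = causal,
        truth = truth, pileups = pileups, pileupPaths = paths,
        wtPileup = wtPileup, lineIds = lineIds,
        contaminantIds = contamIds, artifactContigs = artifactIds,
        config = config)
}

.writeManifest <- function(config, causal, lineIds, contamIds, artifactIds,
                           path) {
    kv <- c(seed = config@seed, n_contigs = config@nContigs,
            contig_length_median = config@contigLengthMedian,
            contig_length_sigma = config@contigLengthSigma,
            min_contig_length = config@minContigLength,
            gc_content = config@gcContent,
            masked_fraction = config@maskedFraction,
            causal_length = config@causalLength,
            n_mutants = config@nMutants,
            background_density = config@backgroundDensity,
            contaminant_density = config@contaminantDensity,
            coverage_lambda = config@coverageLambda,
            error_rate = config@errorRate,
            artifact_scenario = config@artifactScenario,
            causal_contig = causal,
            lines = paste(lineIds, collapse = ","),
            contaminant_lines = paste(contamIds, collapse = ","),
            artifact_contigs = paste(artifactIds, collapse = ","))
    writeLines(paste(names(kv), unname(kv), sep = "="), path)
}
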