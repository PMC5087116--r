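# The synthetic-experiment generator.

test_that("reference simulation respects GC, masking and determinism", {
    cfg0 <- SimulationConfig(seed = 21L, nContigs = 10L,
                             contigLengthMedian = 2000, gcContent = 0,
                             causalLength = 2000L)
    ref <- makeReference(cfg0)
    expect_identical(sum(gcUnmasked(ref$assembly)), 0L)
    expect_match(as.character(ref$assembly@sequences[[1]]), "^[ATatn]+$")

    cfg <- SimulationConfig(seed = 22L, nContigs = 50L,
                            contigLengthMedian = 20000,
                            contigLengthSigma = 0, maskedFraction = 0,
                            causalLength = 20000L)   # ~1 Mb unmasked
    ref <- makeReference(cfg)
    n <- sum(as.numeric(contigLengths(ref$assembly)))
    gc <- sum(as.numeric(gcUnmasked(ref$assembly)))
    se <- sqrt(0.44 * 0.56 / n)
    expect_lt(abs(gc / n - 0.44), 3 * se)

    # same seed -> byte-identical FASTA; different seed -> different
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeFasta(makeReference(cfg)$assembly, f1)
    writeFasta(makeReference(cfg)$assembly, f2)
    expect_identical(readLines(f1), readLines(f2))
    cfg2 <- SimulationConfig(seed = 23L, nContigs = 50L,
                             contigLengthMedian = 20000,
                             contigLengthSigma = 0, maskedFraction = 0,
                             causalLength = 20000L)
    writeFasta(makeReference(cfg2)$assembly, f2)
    expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("contig lengths honour the truncation floor and masking level", {
    cfg <- SimulationConfig(seed = 31L, nContigs = 300L,
                            contigLengthMedian = 700,
                            contigLengthSigma = 1.2,
                            minContigLength = 500L, maskedFraction = 0.1)
    ref <- makeReference(cfg)
    lens <- contigLengths(ref$assembly)
    expect_true(all(lens >= 500L))
    expect_identical(unname(lens[ref$causalContig]), 10000L)
    tot <- sum(as.numeric(lens))
    maskedFrac <- 1 - sum(as.numeric(unmaskedLengths(ref$assembly))) / tot
    expect_gt(maskedFrac, 0.05)
    expect_lt(maskedFrac, 0.2)
})

test_that("EMS mutagenesis is canonical, unmasked-only and binomial", {
    cfg <- SimulationConfig(seed = 41L, nContigs = 10L,
                            contigLengthMedian = 50000,
                            contigLengthSigma = 0, causalLength = 50000L,
                            maskedFraction = 0.1)
    ref <- makeReference(cfg)
    asm <- ref$assembly
    expect_identical(nrow(withr::with_seed(1, mutagenizeEms(asm, 0))), 0L)

    density <- 1 / 500
    unm <- sum(as.numeric(unmaskedLengths(asm)))
    subs <- withr::with_seed(2, mutagenizeEms(asm, density))
    expect_true(all(subs$ref %in% c("G", "C")))
    expect_identical(subs$alt, ifelse(subs$ref == "G", "A", "T"))
    mean_n <- density * unm
    expect_lt(abs(nrow(subs) - mean_n), 3 * sqrt(mean_n))
    # only unmasked sites are ever hit, and the recorded ref matches
    for (i in sample(nrow(subs), 25)) {
        ch <- substr(contigSequence(asm, subs$contig[i]), subs$pos[i],
                     subs$pos[i])
        expect_identical(ch, subs$ref[i])
    }
    expect_error(mutagenizeEms(asm, 0.9),
                 class = "emsHunter_config_error")
})

test_that("natural (contaminant) mutagenesis covers the full spectrum", {
    cfg <- SimulationConfig(seed = 51L, nContigs = 4L,
                            contigLengthMedian = 500000,
                            contigLengthSigma = 0, maskedFraction = 0,
                            causalLength = 500000L)
    asm <- makeReference(cfg)$assembly
    expect_identical(nrow(withr::with_seed(1, mutagenizeNatural(asm, 0))),
                     0L)
    subs <- withr::with_seed(3, mutagenizeNatural(asm, 1 / 1580))
    mean_n <- 2e6 / 1580
    expect_lt(abs(nrow(subs) - mean_n), 3 * sqrt(mean_n))
    expect_true(all(subs$ref != subs$alt))
    # canonical changes should be a minority: expected fraction is
    # gc/3 ~ 0.147 of all substitutions
    canon <- (subs$ref == "G" & subs$alt == "A") |
        (subs$ref == "C" & subs$alt == "T")
    pExp <- 0.44 / 3
    expect_lt(abs(mean(canon) - pExp),
              3 * sqrt(pExp * (1 - pExp) / nrow(subs)))
    # all 12 substitution types occur at this scale
    expect_identical(nrow(unique(subs[, c("ref", "alt")])), 12L)
})

test_that("causal planting gives each line one distinct G/C lesion", {
    cfg <- SimulationConfig(seed = 61L, nContigs = 10L,
                            contigLengthMedian = 2000,
                            causalLength = 2000L)
    ref <- makeReference(cfg)
    ids <- sprintf("m%d", 1:6)
    tr <- withr::with_seed(4, plantCausal(ref$assembly, ref$causalContig,
                                          ids))
    expect_identical(tr$lineId, ids)
    expect_identical(anyDuplicated(tr$pos), 0L)
    expect_true(all(tr$pos >= 1 &
                    tr$pos <= contigLengths(ref$assembly)[ref$causalContig]))
    expect_true(all(tr$ref %in% c("G", "C")))
    expect_identical(tr$alt, ifelse(tr$ref == "G", "A", "T"))
    # too many lines for the available sites
    tiny <- ReferenceAssembly(c(c1 = "GATT"))
    expect_error(plantCausal(tiny, "c1", sprintf("m%d", 1:5)),
                 class = "emsHunter_config_error")
})

test_that("pileup simulation reports genome bases and error statistics", {
    asm <- ReferenceAssembly(c(c1 = strrep("ACGT", 250)))
    subs <- data.frame(contig = "c1", pos = 1L, ref = "A", alt = "G",
                       stringsAsFactors = FALSE)
    pu <- withr::with_seed(5, simulatePileup(asm, subs,
                                             coverageLambda = 30))
    # error-free: non-mutated positions are all-reference
    nonmut <- pu[pu$pos != 1L, ]
    agree <- mapply(function(r, i) nonmut[[r]][i],
                    nonmut$ref, seq_len(nrow(nonmut)))
    expect_identical(as.integer(agree), nonmut$depth)
    # error-free: the mutated position reports only the alternate
    mut <- pu[pu$pos == 1L, ]
    expect_identical(mut$G, mut$depth)
    # with errors: miscall fraction within 3 SE of the error rate
    big <- ReferenceAssembly(c(c1 = strrep("A", 40000)))   # ~1.2M reads
    pue <- withr::with_seed(6, simulatePileup(big, NULL,
                                              coverageLambda = 30,
                                              errorRate = 0.01))
    reads <- sum(pue$depth)
    miscalls <- sum(pue$C + pue$G + pue$T)
    se <- sqrt(0.01 * 0.99 / reads)
    expect_lt(abs(miscalls / reads - 0.01), 3 * se)
    # depth is Poisson with the configured mean
    expect_lt(abs(mean(pue$depth) - 30), 3 * sqrt(30 / nrow(pue)))
})

test_that("whole experiments are consistent, parseable and seeded", {
    cfg <- SimulationConfig(seed = 71L, nContigs = 20L,
                            contigLengthMedian = 1500, nMutants = 3L,
                            backgroundDensity = 1e-4, causalLength = 2000L,
                            contaminantDensity = 1 / 1580)
    d <- withr::local_tempdir()
    sim <- simulateExperiment(cfg, dir = d, keepPileups = TRUE)
    # files parse cleanly through the format layer
    asm <- readFasta(file.path(d, "reference.fasta"))
    expect_identical(contigIds(asm), contigIds(sim@assembly))
    for (p in sim@pileupPaths) {
        pu <- readMpileup(p, asm)
        expect_gt(nrow(pu), 0L)
    }
    truth <- read.table(file.path(d, "truth.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    expect_identical(nrow(truth), nrow(truthTable(sim)))
    # every mutant carries a causal lesion; the contaminant does not
    causal <- truth[truth$class == "causal", ]
    expect_setequal(causal$lineId, sprintf("mutant_%02d", 1:3))
    expect_true(all(causal$contig == causalContig(sim)))
    expect_false("contaminant_01" %in% causal$lineId)
    # EMS truth entries are exclusively canonical at unmasked sites
    ems <- truth[truth$class %in% c("causal", "background"), ]
    expect_true(all(ems$ref %in% c("G", "C")))
    expect_identical(ems$alt, ifelse(ems$ref == "G", "A", "T"))
    # in-memory pileups match the written files
    expect_identical(readMpileup(sim@pileupPaths[["mutant_01"]], asm)$A,
                     sim@pileups[["mutant_01"]]$A[
                         sim@pileups[["mutant_01"]]$depth > 0])
    # different seeds give different truth tables
    cfg2 <- SimulationConfig(seed = 72L, nContigs = 20L,
                             contigLengthMedian = 1500, nMutants = 3L,
                             backgroundDensity = 1e-4,
                             causalLength = 2000L,
                             contaminantDensity = 1 / 1580)
    sim2 <- simulateExperiment(cfg2)
    expect_false(identical(truthTable(sim), truthTable(sim2)))
})

test_that("rerunning a configuration reproduces every file byte-for-byte", {
    cfg <- SimulationConfig(seed = 81L, nContigs = 12L,
                            contigLengthMedian = 1200, nMutants = 2L,
                            backgroundDensity = 1e-4, causalLength = 1500L,
                            artifactScenario = TRUE)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    simulateExperiment(cfg, dir = d1, keepPileups = FALSE)
    simulateExperiment(cfg, dir = d2, keepPileups = FALSE)
    files <- list.files(d1)
    expect_setequal(files, list.files(d2))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
})

test_that("error-free calling reproduces the truth table exactly", {
    # coverage high enough that every position passes the depth filter
    cfg <- SimulationConfig(seed = 91L, nContigs = 60L,
                            contigLengthMedian = 4000, nMutants = 4L,
                            backgroundDensity = 1 / 50000,
                            causalLength = 5000L, coverageLambda = 60)
    sim <- simulateExperiment(cfg)
    truth <- truthTable(sim)
    for (id in sim@lineIds) {
        cs <- callMutantSnvs(sim@pileups[[id]], sim@assembly,
                             FilterConfig(), id)
        got <- snvCalls(cs)[, c("contig", "pos", "ref", "alt")]
        exp <- truth[truth$lineId == id, c("contig", "pos", "ref", "alt")]
        exp <- exp[order(exp$contig, exp$pos, method = "radix"), ,
                   drop = FALSE]
        rownames(got) <- rownames(exp) <- NULL
        expect_identical(got, exp, label = id)
        expect_identical(canonicalFraction(cs), 1)   # pure-EMS spectrum
    }
})
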