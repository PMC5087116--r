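# Per-mutant SNV calling: the coverage / allele-frequency / masking
# predicates.

asmG <- ReferenceAssembly(c(c1 = strrep("G", 100)))

test_that("the three filter predicates act as specified", {
    cfg <- FilterConfig()
    # unanimous alternate at good depth: called at frequency 1
    cs <- callMutantSnvs(pileupRow("c1", 10L, "G", A = 20L), asmG, cfg, "m")
    expect_identical(nCalls(cs), 1L)
    expect_identical(snvCalls(cs)$alt, "A")
    expect_identical(snvCalls(cs)$frequency, 1)
    expect_true(snvCalls(cs)$canonical)
    # coverage below 15: no call, position not callable
    cs <- callMutantSnvs(pileupRow("c1", 10L, "G", A = 14L), asmG, cfg, "m")
    expect_identical(nCalls(cs), 0L)
    expect_identical(callableBases(cs), 0)
    # allele frequency 19/20 = 0.95 < 0.9999: no call, but callable
    cs <- callMutantSnvs(pileupRow("c1", 10L, "G", A = 19L, G = 1L),
                         asmG, cfg, "m")
    expect_identical(nCalls(cs), 0L)
    expect_identical(callableBases(cs), 1)
})

test_that("masked and N reference positions are skipped entirely", {
    asm <- ReferenceAssembly(c(c1 = paste0("GG", "g", "N", "GG")))
    pu <- rbind(pileupRow("c1", 3L, "G", A = 20L),   # soft-masked g
                pileupRow("c1", 4L, "N", A = 20L),   # N
                pileupRow("c1", 5L, "G", A = 20L))   # unmasked G
    cs <- callMutantSnvs(pu, asm, FilterConfig(), "m")
    expect_identical(snvCalls(cs)$pos, 5L)
    expect_identical(callableBases(cs), 1)
    expect_identical(callableGcBases(cs), 1)
})

test_that("frequency denominator excludes deletions and other symbols", {
    # 15 A reads plus 5 deletions, ref G: frequency among substitutions
    # is 15/15 = 1, and total depth 20 passes coverage
    pu <- pileupRow("c1", 10L, "G", A = 15L, del = 5L)
    cs <- callMutantSnvs(pu, asmG, FilterConfig(), "m")
    expect_identical(nCalls(cs), 1L)
    expect_identical(snvCalls(cs)$frequency, 1)
    expect_identical(snvCalls(cs)$depth, 20L)
    # but 14 substitution reads + 6 deletions at depth 20: depth passes,
    # frequency 14/14 = 1 still calls (depth gate is on total reads)
    pu <- pileupRow("c1", 10L, "G", A = 14L, del = 6L)
    expect_identical(nCalls(callMutantSnvs(pu, asmG, FilterConfig(), "m")),
                     1L)
})

test_that("ties among non-reference bases never call", {
    pu <- pileupRow("c1", 10L, "G", A = 10L, T = 10L)
    expect_identical(nCalls(callMutantSnvs(pu, asmG, FilterConfig(), "m")),
                     0L)
})

test_that("at the 99.99% threshold one dissenting read kills the call", {
    # exhaustively for depths 15..100: unanimity calls, one dissent never
    cfg <- FilterConfig()
    for (d in 15:100) {
        unan <- callMutantSnvs(pileupRow("c1", 10L, "G", A = d), asmG,
                               cfg, "m")
        expect_identical(nCalls(unan), 1L)
        dis <- callMutantSnvs(pileupRow("c1", 10L, "G", A = d - 1L,
                                        G = 1L), asmG, cfg, "m")
        expect_identical(nCalls(dis), 0L)
    }
})

test_that("calls match a literal per-column oracle on random pileups", {
    set.seed(404)
    for (rep in 1:5) {
        seqs <- randomSeqs(8)
        asm <- ReferenceAssembly(seqs)
        rows <- list()
        for (ctg in names(seqs)) {
            len <- nchar(seqs[[ctg]])
            pos <- sort(sample(seq_len(len), min(len, 25)))
            for (p in pos) {
                cnt <- as.integer(rmultinom(1, sample(0:40, 1),
                                            prob = runif(6, 0, 2)))
                # bias towards near-fixed columns so calls actually occur
                if (runif(1) < 0.4) {
                    cnt <- integer(6)
                    cnt[sample(1:4, 1)] <- sample(10:40, 1)
                    if (runif(1) < 0.3) cnt[sample(1:4, 1)] <-
                        cnt[sample(1:4, 1)] + sample(0:2, 1)
                }
                rows[[length(rows) + 1L]] <- pileupRow(
                    ctg, p, toupper(substr(seqs[[ctg]], p, p)),
                    A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4],
                    del = cnt[5], other = cnt[6])
            }
        }
        pu <- do.call(rbind, rows)
        cfg <- FilterConfig()
        got <- callMutantSnvs(pu, asm, cfg, "m")
        exp <- oracleCallTable(pu, seqs, cfg@minCoverage,
                               cfg@minAlleleFrequency)
        expect_identical(callableBases(got), as.numeric(exp$callable))
        gotCalls <- snvCalls(got)[, c("contig", "pos", "ref", "alt")]
        expCalls <- exp$calls[order(exp$calls$contig, exp$calls$pos), ,
                              drop = FALSE]
        rownames(gotCalls) <- rownames(expCalls) <- NULL
        expect_identical(gotCalls, expCalls)
    }
})

test_that("raising thresholds never increases the number of calls", {
    set.seed(505)
    seqs <- randomSeqs(5)
    asm <- ReferenceAssembly(seqs)
    rows <- list()
    for (ctg in names(seqs)) {
        for (p in sort(sample(seq_len(nchar(seqs[[ctg]])), 15))) {
            cnt <- integer(4)
            cnt[sample(1:4, 1)] <- sample(5:40, 1)
            if (runif(1) < 0.5) cnt[sample(1:4, 1)] <-
                cnt[sample(1:4, 1)] + sample(0:3, 1)
            rows[[length(rows) + 1L]] <- pileupRow(
                ctg, p, toupper(substr(seqs[[ctg]], p, p)),
                A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4])
        }
    }
    pu <- do.call(rbind, rows)
    base <- nCalls(callMutantSnvs(pu, asm,
                                  FilterConfig(minCoverage = 5L,
                                               minAlleleFrequency = 0.9),
                                  "m"))
    for (cov in c(10L, 20L, 40L))
        expect_lte(nCalls(callMutantSnvs(
            pu, asm, FilterConfig(minCoverage = cov,
                                  minAlleleFrequency = 0.9), "m")), base)
    for (af in c(0.95, 0.9999, 1))
        expect_lte(nCalls(callMutantSnvs(
            pu, asm, FilterConfig(minCoverage = 5L,
                                  minAlleleFrequency = af), "m")), base)
})

test_that("unsorted pileups and bad configs are rejected", {
    pu <- rbind(pileupRow("c1", 10L, "G", A = 20L),
                pileupRow("c1", 5L, "G", A = 20L))
    expect_error(callMutantSnvs(pu, asmG, FilterConfig(), "m"),
                 class = "emsHunter_integrity_error")
    # contig appearing in two separate blocks
    pu <- rbind(pileupRow("c1", 1L, "G", A = 20L),
                pileupRow("c2", 1L, "G", A = 20L),
                pileupRow("c1", 2L, "G", A = 20L))
    expect_error(callMutantSnvs(pu, asmG, FilterConfig(), "m"),
                 class = "emsHunter_integrity_error")
    expect_error(FilterConfig(minAlleleFrequency = 1.5),
                 class = "emsHunter_config_error")
    expect_error(FilterConfig(minCoverage = 0L),
                 class = "emsHunter_config_error")
    expect_error(callMutantSnvs(pileupRow("cX", 1L, "G", A = 20L), asmG,
                                FilterConfig(), "m"),
                 class = "emsHunter_integrity_error")
})

test_that("canonicalFraction summarises the EMS spectrum", {
    expect_identical(canonicalFraction(makeCallSet("m", "c1", 1:2,
                                                   ref = c("G", "C"),
                                                   alt = c("A", "T"))), 1)
    expect_identical(canonicalFraction(makeCallSet("m", "c1", 1:2,
                                                   ref = c("G", "A"),
                                                   alt = c("A", "G"))),
                     0.5)
    expect_true(is.na(canonicalFraction(MutantCallSet("m"))))
})
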