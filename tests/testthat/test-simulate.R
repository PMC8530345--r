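test_that("simulated genomes hit the requested composition and masking", {
    g <- simulateGenome(20000, gc = 0.5, seed = 41)
    counts <- Biostrings::alphabetFrequency(g[[1]])[c("A", "C", "G", "T")]
    gcObs <- sum(counts[c("C", "G")]) / sum(counts)
    # 3-sigma binomial band at n = 20000
    expect_lt(abs(gcObs - 0.5), 3 * sqrt(0.25 / 20000))
    gm <- simulateGenome(20000, maskedFraction = 0.2, seed = 42)
    nFrac <- Biostrings::alphabetFrequency(gm[[1]])[["N"]] / 20000
    expect_lt(abs(nFrac - 0.2), 500 / 20000) # block granularity
    # byte-identical under the same seed
    expect_equal(
        as.character(simulateGenome(5000, seed = 7)),
        as.character(simulateGenome(5000, seed = 7))
    )
    expect_error(simulateGenome(100), ">= 1000")
    expect_error(simulateGenome(20000, gc = 1.2), "gc")
    expect_error(simulateGenome(20000, maskedFraction = 1), "masked")
})

test_that("enzyme libraries place only on usable fragments, truthfully", {
    g <- simulateGenome(50000, seed = 43)
    sim <- simulateEnzymeLibrary(g, "RsaI", 3000, beta = 1, seed = 44)
    # no placement on a fragment shorter than a footprint
    expect_true(all(sim$reads$fragEnd - sim$reads$fragStart + 1L >= 147L))
    # footprints stay inside their fragment
    expect_true(all(sim$reads$plantedDyad - 73L >= sim$reads$fragStart))
    expect_true(all(sim$reads$plantedDyad + 73L <= sim$reads$fragEnd))
    # reads are exact genomic substrings (plus) / reverse complements
    str <- as.character(strand(sim$reads))
    i <- which(str == "+")[1:25]
    expect_equal(
        unname(as.character(sim$sequences[i])),
        as.character(extractAt(
            g[[1]], IRanges(start(sim$reads)[i], width = 25)
        ))
    )
    j <- which(str == "-")[1:25]
    expect_equal(
        unname(as.character(sim$sequences[j])),
        as.character(reverseComplement(extractAt(
            g[[1]], IRanges(start(sim$reads)[j] - 24L, width = 25)
        )))
    )
    # deterministic under seed
    sim2 <- simulateEnzymeLibrary(g, "RsaI", 3000, beta = 1, seed = 44)
    expect_identical(as.character(sim$sequences),
        as.character(sim2$sequences))
    expect_equal(start(sim$reads), start(sim2$reads))
    # a genome with nothing to place on
    tiny <- DNAStringSet(c(c1 = strrep("GTAC", 25)))
    expect_error(
        simulateEnzymeLibrary(tiny, "RsaI", 10),
        "nothing can be reconstituted"
    )
})

test_that("terminal placement rate follows the two-level weight model", {
    g <- simulateGenome(200000, seed = 45)
    for (beta in c(1, 4)) {
        sim <- simulateEnzymeLibrary(g, "RsaI", 30000,
            beta = beta, biasWidth = 1, seed = 46
        )
        # expected terminal fraction: sum over fragments of beta*t / W
        # with per-fragment weight W = beta*t + (nStarts - t)
        ft <- sim$fragments
        L <- width(fragments(ft))
        nStarts <- L - 146L
        t <- pmin(2L, nStarts)
        w <- beta * t + (nStarts - t)
        pTerm <- sum(beta * t) / sum(w)
        obs <- mean(sim$reads$cause == "terminal")
        expect_lt(
            abs(obs - pTerm),
            4 * sqrt(pTerm * (1 - pTerm) / 30000)
        )
    }
})

test_that("sheared libraries honor the size selection and stay flat", {
    g <- simulateGenome(150000, seed = 47)
    sim <- simulateShearedLibrary(g, 5000, beta = 4, seed = 48)
    fragLen <- sim$reads$fragEnd - sim$reads$fragStart + 1L
    expect_true(all(fragLen >= 600L & fragLen <= 800L))
    expect_error(
        simulateShearedLibrary(g, 10, sizeRange = c(100L, 120L)),
        "infeasible"
    )
    sim2 <- simulateShearedLibrary(g, 5000, beta = 4, seed = 48)
    expect_equal(start(sim$reads), start(sim2$reads))
})

test_that("uniform libraries are exact substrings until errors are added", {
    g <- simulateGenome(50000, maskedFraction = 0.1, seed = 49)
    sim <- simulateUniformLibrary(g, 2000, errorRate = 0, seed = 50)
    str <- as.character(strand(sim$reads))
    i <- which(str == "+")[1:25]
    expect_equal(
        unname(as.character(sim$sequences[i])),
        as.character(extractAt(
            g[[1]], IRanges(start(sim$reads)[i], width = 25)
        ))
    )
    # no read 5' base on a masked position
    fiveBase <- substring(
        as.character(g[[1]]), start(sim$reads), start(sim$reads)
    )
    expect_false(any(fiveBase == "N"))
    # substitution rate within a binomial band
    simE <- simulateUniformLibrary(g, 2000, errorRate = 0.05, seed = 50)
    ref <- ifelse(str == "+",
        as.character(extractAt(
            g[[1]], IRanges(start(sim$reads), width = 25)
        )),
        as.character(reverseComplement(extractAt(
            g[[1]], IRanges(start(sim$reads) - 24L, width = 25)
        )))
    )
    mm <- mapply(function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, as.character(simE$sequences), ref)
    nBase <- 2000 * 25
    expect_lt(
        abs(sum(mm) / nBase - 0.05),
        4 * sqrt(0.05 * 0.95 / nBase)
    )
    expect_error(simulateUniformLibrary(g, 0), "positive")
})

test_that("truth files round-trip through the BED import path", {
    g <- simulateGenome(30000, seed = 51)
    sim <- simulateEnzymeLibrary(g, "RsaI", 500, beta = 2, seed = 52)
    pre <- tempfile()
    writeTruth(sim, pre)
    reads <- importReadStarts(paste0(pre, ".bed"))
    expect_equal(start(reads), start(sim$reads))
    expect_equal(
        as.character(strand(reads)), as.character(strand(sim$reads))
    )
    inv <- callDyads(reads,
        seqlengths = setNames(width(g), names(g))
    )
    expect_equal(inv$dyad, sim$reads$plantedDyad)
    fq <- tempfile(fileext = ".fastq")
    writeReadsFastq(sim, fq)
    back <- Biostrings::readDNAStringSet(fq, format = "fastq")
    expect_equal(as.character(back), as.character(sim$sequences),
        ignore_attr = TRUE
    )
})
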