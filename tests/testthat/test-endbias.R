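# single undigested 1000-bp chromosome: one retained fragment whose
# terminal bases are positions 1 and 1000
.oneFragTable <- function(len = 1000L) {
    buildFragmentTable(list(c1 = integer(0)), c(c1 = len),
        minLength = 147L, enzyme = "toy"
    )
}

.mkReads <- function(pos, strand, len = 1000L) {
    GRanges("c1", IRanges(pos, width = 1),
        strand = strand,
        seqinfo = Seqinfo("c1", len)
    )
}

test_that("start ratio divides terminal starts by all library starts", {
    ft <- .oneFragTable()
    reads <- .mkReads(
        c(1, 1, 1000, 1000, 400, 410, 420, 430, 440, 450),
        c("+", "+", "-", "-", "+", "+", "+", "+", "+", "+")
    )
    pr <- startRatioProfile(reads, ft, library = "toy")
    expect_equal(profileValues(pr)[1], 0.4)
    expect_equal(pr@nTotalStarts, 10L)
    # ratios are over ALL starts, so the window sums to <= 1
    expect_lte(sum(profileValues(pr)), 1)
    expect_error(startRatioProfile(reads[0], ft), "empty")
    # window larger than half the shortest retained fragment (1000 bp)
    expect_error(
        startRatioProfile(reads, ft, window = 501L),
        "shortest"
    )
})

test_that("left ends count plus starts and right ends minus starts", {
    ft <- .oneFragTable()
    # a minus read on the left terminal base belongs to a footprint
    # running further left: it must not create a position-1 spike
    reads <- .mkReads(c(1, 1, 500), c("-", "-", "+"))
    pr <- startRatioProfile(reads, ft)
    expect_equal(profileValues(pr)[1], 0)
    # occupancy is strand-agnostic coverage, so it does see them
    occ <- occupancyProfile(reads, ft)
    expect_gt(profileValues(occ)[1], 0)
})

test_that("the half-site offset shifts position 1 off the terminal base", {
    ft <- .oneFragTable()
    reads <- .mkReads(c(3, 3, 700), c("+", "+", "+"))
    pr0 <- startRatioProfile(reads, ft, offset = 0L)
    pr2 <- startRatioProfile(reads, ft, offset = 2L)
    expect_equal(profileValues(pr0)[3], 2 / 3)
    expect_equal(profileValues(pr2)[1], 2 / 3)
})

test_that("occupancy is mean-1 by construction and depth-invariant", {
    ft <- .oneFragTable()
    set.seed(31)
    reads <- .mkReads(
        sample(1000L, 400, replace = TRUE),
        sample(c("+", "-"), 400, replace = TRUE)
    )
    occ <- occupancyProfile(reads, ft, library = "toy")
    expect_equal(mean(profileValues(occ)), 1)
    doubled <- c(reads, reads)
    occ2 <- occupancyProfile(doubled, ft, library = "toy")
    expect_equal(profileValues(occ2), profileValues(occ))
    noCov <- .mkReads(c(500, 510), c("+", "+"))
    # starts exist but none inside either 73-bp end window
    expect_error(occupancyProfile(noCov, ft), "zero mean")
})

test_that("windows from the two ends of one fragment never double-count", {
    # 148-bp fragment: left window [1,73] and right window [76,148] are
    # disjoint at offset 0; with offset 2 they would overlap without the
    # midpoint precedence rule
    ft <- buildFragmentTable(list(c1 = 148L), c(c1 = 296L),
        minLength = 147L, enzyme = "toy"
    )
    reads <- .mkReads(seq(1L, 148L), rep("+", 148), len = 296L)
    occ <- occupancyProfile(reads, ft, offset = 2L)
    # every genomic base credited at most once across the 2 x 73 cells
    expect_lte(sum(occ@counts), 148)
})

test_that("terminal enrichment factor is recovered from simulation", {
    g <- simulateGenome(300000, gc = 0.36, seed = 101)
    sim <- simulateEnzymeLibrary(g, "HincII", 60000,
        beta = 4, biasWidth = 1, seed = 102
    )
    inv <- callDyads(sim$reads,
        seqlengths = setNames(width(g), names(g)), library = "HincII"
    )
    pr <- startRatioProfile(inv, sim$fragments, library = "HincII")
    v <- profileValues(pr)
    ratio <- v[1] / median(v[2:73])
    expect_gt(ratio, 3.2)
    expect_lt(ratio, 4.8)
    occ <- occupancyProfile(inv, sim$fragments, library = "HincII")
    vo <- profileValues(occ)
    expect_gt(vo[1] / median(vo[2:73]), 3.2)
    expect_lt(vo[1] / median(vo[2:73]), 4.8)
    # both metrics agree that the terminal base is the most occupied
    expect_equal(which.max(v), 1L)
    expect_equal(which.max(vo), 1L)
})

test_that("reciprocal enzyme control shows no position-1 spike", {
    g <- simulateGenome(300000, gc = 0.36, seed = 103)
    sim <- simulateEnzymeLibrary(g, "HincII", 60000,
        beta = 4, biasWidth = 1, seed = 104
    )
    inv <- callDyads(sim$reads,
        seqlengths = setNames(width(g), names(g)), library = "HincII"
    )
    rsaFt <- buildFragmentTable(findCutSites(g, "RsaI"))
    pr <- startRatioProfile(inv, rsaFt,
        library = "HincII", cutsiteSet = "RsaI"
    )
    v <- profileValues(pr)
    # position 1 within 4 sigma of the window mean: flat
    se <- sqrt(mean(v) * (1 - mean(v)) / pr@nTotalStarts)
    expect_lt(abs(v[1] - mean(v)), 4 * se)
})

test_that("position comparisons report both percent conventions", {
    mk <- function(lib, v1) {
        new("EndBiasProfile",
            library = lib, cutsiteSet = "RsaI", metric = "start_ratio",
            window = 73L, values = c(v1, rep(0.001, 72)),
            counts = numeric(73), nTotalStarts = 1000L, offset = 0L
        )
    }
    cmp <- enrichmentAtPosition(list(mk("A", 0.8), mk("B", 0.2)), 1)
    expect_equal(cmp$ratioToNextHighest, c(4, 0.25))
    expect_equal(cmp$ratioPct[1], 400)
    expect_equal(cmp$increasePct[1], 300)
    same <- enrichmentAtPosition(list(mk("A", 0.5), mk("B", 0.5)), 1)
    expect_equal(same$ratioToNextHighest, c(1, 1))
    mkOther <- mk("C", 0.3)
    mkOther@cutsiteSet <- "HincII"
    expect_error(
        enrichmentAtPosition(list(mk("A", 0.8), mkOther), 1),
        "different cut site sets"
    )
})
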