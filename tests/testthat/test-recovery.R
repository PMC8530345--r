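.mkInv <- function(dyads, chrom = "chrT", label = "unclassified",
                   lib = "toy", seqlen = 50000L) {
    GRanges(chrom, IRanges(dyads - 73L, dyads + 73L),
        strand = "+", dyad = as.integer(dyads), library = lib,
        label = label,
        seqinfo = Seqinfo(chrom, seqlen)
    )
}

test_that("suspect regions anchor at fragment termini and clip", {
    ft <- buildFragmentTable(list(c1 = integer(0)), c(c1 = 1000L),
        minLength = 147L
    )
    sr <- buildSuspectRanges(ft, 200)
    expect_equal(start(startRegions(sr)), 1L)
    expect_equal(end(startRegions(sr)), 200L)
    expect_equal(start(endRegions(sr)), 801L)
    expect_equal(end(endRegions(sr)), 1000L)
    sr2 <- buildSuspectRanges(ft, 1, offset = 2L)
    expect_equal(start(startRegions(sr2)), 3L)
    expect_equal(end(startRegions(sr2)), 3L)
    expect_equal(start(endRegions(sr2)), 998L)
    expect_equal(end(endRegions(sr2)), 998L)
    # short fragment: the two regions overlap and cover everything
    ft3 <- buildFragmentTable(list(c1 = integer(0)), c(c1 = 300L),
        minLength = 147L
    )
    sr3 <- buildSuspectRanges(ft3, 200)
    un <- reduce(c(startRegions(sr3), endRegions(sr3)))
    expect_equal(start(un), 1L)
    expect_equal(end(un), 300L)
    expect_error(buildSuspectRanges(ft, 0), ">= 1")
})

test_that("classification is innercut, then suspect, then passed", {
    b <- 1000L
    ft <- buildFragmentTable(list(chrT = b), c(chrT = 2000L),
        minLength = 147L
    )
    sr <- buildSuspectRanges(ft, 200)
    cs <- list(chrT = b)
    inv <- .mkInv(c(374, 174, 974), seqlen = 2000L)
    # footprints: [301,447] interior; [101,247] start in [1,200];
    # [901,1047] spans the cut at 1000 regardless of d
    got <- classifyInvitrosomes(inv, sr, cs)
    expect_equal(got$label, c("passed", "suspect", "innercut"))
    for (d in c(1L, 11L, 200L)) {
        g <- classifyInvitrosomes(inv, buildSuspectRanges(ft, d), cs)
        expect_equal(g$label[3], "innercut", info = paste("d =", d))
    }
    # flush-at-boundary footprints do not span the cut
    flush <- .mkInv(c(1000L - 73L, 1001L + 73L), seqlen = 2000L)
    gf <- classifyInvitrosomes(flush, buildSuspectRanges(ft, 1), cs)
    expect_false(any(gf$label == "innercut"))
    expect_error(
        classifyInvitrosomes(.mkInv(500, chrom = "chrZ"), sr, cs),
        "absent"
    )
})

test_that("classification matches the brute-force oracle", {
    for (seed in c(1, 2, 3)) {
        ri <- randomRecoveryInstance(seed)
        frs <- fragments(ri$fragmentTable)
        fragDf <- data.frame(
            chrom = as.character(seqnames(frs)),
            fs = start(frs), fe = end(frs)
        )
        invDf <- data.frame(
            chrom = as.character(seqnames(ri$inv)),
            start = start(ri$inv), end = end(ri$inv)
        )
        for (d in c(200L, 11L, 1L)) {
            got <- classifyInvitrosomes(
                ri$inv, buildSuspectRanges(ri$fragmentTable, d),
                ri$boundaries
            )$label
            want <- bruteClassify(invDf, fragDf, ri$boundaries, d)
            expect_equal(got, want, info = sprintf(
                "seed %d, d %d", seed, d
            ))
        }
    }
})

test_that("cross recovery matches dyads within tolerance", {
    sus <- .mkInv(c(5000, 5001), label = "suspect")
    comp <- .mkInv(5000, label = "passed", lib = "alt")
    r0 <- crossRecover(sus, comp, tolerance = 0)
    expect_equal(r0$label, c("recovered", "biased"))
    r5 <- crossRecover(sus, comp, tolerance = 5)
    expect_equal(r5$label, c("recovered", "recovered"))
    expect_error(crossRecover(sus, comp, tolerance = -1), ">= 0")
    # non-suspect labels pass through untouched
    mixed <- .mkInv(c(5000, 6000), label = c("passed", "suspect"))
    rm2 <- crossRecover(mixed, comp, tolerance = 0)
    expect_equal(rm2$label, c("passed", "biased"))
    # brute force on a random instance, including cross-chromosome traps
    set.seed(77)
    susD <- sample(1000:40000, 500, replace = TRUE)
    susC <- sample(c("chrT", "chrU"), 500, replace = TRUE)
    compD <- sample(1000:40000, 2000, replace = TRUE)
    compC <- sample(c("chrT", "chrU"), 2000, replace = TRUE)
    sus <- GRanges(susC, IRanges(susD - 73L, susD + 73L),
        dyad = susD, label = "suspect"
    )
    comp <- GRanges(compC, IRanges(compD - 73L, compD + 73L),
        dyad = compD, label = "passed"
    )
    for (tol in c(0L, 3L)) {
        got <- crossRecover(sus, comp, tol)$label == "recovered"
        want <- bruteRecover(susC, susD, compC, compD, tol)
        expect_equal(got, want, info = paste("tol", tol))
    }
})

test_that("sub-libraries partition by final label", {
    inv <- .mkInv(seq(1000, 5000, by = 1000),
        label = c("passed", "passed", "recovered", "biased", "innercut")
    )
    subs <- assembleSublibraries(inv)
    expect_length(subs$Raw, 5L)
    expect_length(subs$PreRecovery, 2L)
    expect_length(subs$PostRecovery, 4L)
    expect_false("biased" %in% subs$PostRecovery$label)
    expect_error(
        assembleSublibraries(.mkInv(1000, label = "suspect")),
        "final label"
    )
    # no suspects: Post = Raw
    clean <- .mkInv(c(1000, 2000),
        label = c("passed", "innercut")
    )
    subs2 <- assembleSublibraries(clean)
    expect_equal(length(subs2$PostRecovery), length(subs2$Raw))
})

test_that("recovery accounting derives every count and percentage", {
    lab <- c(
        rep("passed", 70), rep("innercut", 10),
        rep("recovered", 12), rep("biased", 8)
    )
    rep100 <- tabulateRecovery(lab,
        totalReads = 125, library = "toy", suspectRange = 200
    )
    cts <- reportCounts(rep100)
    expect_equal(cts[["allSuspect"]], 30)
    expect_equal(cts[["positionSuspect"]], 20)
    expect_equal(cts[["totalRecovered"]], 22)
    expect_equal(cts[["postRecovery"]], 92)
    expect_equal(cts[["remainingBiased"]], 8)
    pct <- reportPercentages(rep100)
    expect_equal(pct[["passed"]], 70.0)
    expect_equal(pct[["mapped"]], 80.0)
    allPassed <- tabulateRecovery(rep("passed", 50))
    expect_equal(reportPercentages(allPassed)[["passed"]], 100.0)
    expect_equal(reportCounts(allPassed)[["allSuspect"]], 0)
    expect_error(tabulateRecovery(lab, mappedReads = 1000), "match")
    # impossible counts rejected by the self-check
    expect_error(
        recoveryReport(
            passed = 90, innerCutSite = 20, recovered = 0,
            mappedReads = 100
        ),
        "negative"
    )
})

test_that("percentages round half up to one decimal", {
    expect_equal(roundHalfUp(0.25, 1), 0.3)
    expect_equal(roundHalfUp(84.0365, 1), 84.0)
    expect_equal(roundHalfUp(58.25, 1), 58.3)
    expect_equal(roundHalfUp(-0.25, 1), -0.3)
})

test_that("suspect counts shrink with d while innercut stays fixed", {
    for (seed in 4:8) {
        ri <- randomRecoveryInstance(seed)
        prev <- Inf
        innercuts <- integer(0)
        for (d in c(200L, 11L, 1L)) {
            lab <- classifyInvitrosomes(
                ri$inv, buildSuspectRanges(ri$fragmentTable, d),
                ri$boundaries
            )$label
            allSus <- sum(lab != "passed")
            expect_lte(allSus, prev)
            prev <- allSus
            innercuts <- c(innercuts, sum(lab == "innercut"))
            # exhaustive disjoint partition
            expect_equal(
                sum(lab == "passed") + allSus, length(ri$inv)
            )
        }
        expect_equal(length(unique(innercuts)), 1L)
    }
})

test_that("recovery is idempotent and rescues exactly planted positions", {
    # two enzymes with different boundaries; plant dyads present in both
    # libraries at positions suspect in A but passed in B
    chromLen <- 60000L
    bA <- seq(1000L, 59000L, by = 1000L)
    bB <- seq(1500L, 58500L, by = 1000L)
    ftA <- buildFragmentTable(list(chrT = bA), c(chrT = chromLen))
    ftB <- buildFragmentTable(list(chrT = bB), c(chrT = chromLen))
    srA <- buildSuspectRanges(ftA, 200)
    srB <- buildSuspectRanges(ftB, 200)
    planted <- c(2100L, 3100L, 4100L) # near A starts (2000,3000,...)
    farArm <- c(2600L, 3600L) # interior for A
    invA <- .mkInv(c(planted, farArm), lib = "A", seqlen = chromLen)
    invB <- .mkInv(c(planted, 9999L), lib = "B", seqlen = chromLen)
    clsA <- classifyInvitrosomes(invA, srA, list(chrT = bA))
    clsB <- classifyInvitrosomes(invB, srB, list(chrT = bB))
    expect_equal(
        clsA$label, c(rep("suspect", 3), rep("passed", 2))
    )
    expect_true(all(clsB$label[1:3] == "passed"))
    comp <- clsB[clsB$label %in% c("passed", "innercut")]
    rec <- crossRecover(clsA, comp, tolerance = 0)
    expect_equal(
        sort(rec$dyad[rec$label == "recovered"]), planted
    )
    # idempotence: recover the PostRecovery set again, nothing changes
    post <- assembleSublibraries(rec)$PostRecovery
    post2 <- post
    post2$label <- classifyInvitrosomes(post2, srA, list(chrT = bA))$label
    post2 <- crossRecover(post2, comp, tolerance = 0)
    expect_equal(
        sort(assembleSublibraries(post2)$PostRecovery$dyad),
        sort(post$dyad)
    )
    expect_false(any(post2$label == "biased"))
})
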