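#' @include kmer.R
NULL

#' Simulate a genome with optional hard-masking
#'
#' Draws i.i.d. bases at the requested GC fraction (default 0.36, a
#' nematode-like composition) and hard-masks approximately
#' \code{maskedFraction} of the sequence with contiguous N blocks, the
#' synthetic analogue of a repeat-masked reference. Masking replaces
#' whole non-overlapping tiles of \code{maskBlock} bp, so the realized
#' fraction matches the request up to block granularity. Identical
#' arguments and seed give byte-identical output.
#'
#' @param length genome length in bp (>= 1000; >= 10 kb recommended for
#'   meaningful digestion).
#' @param gc GC fraction in (0, 1).
#' @param maskedFraction fraction of bases to mask in \[0, 1).
#' @param seed optional RNG seed.
#' @param name chromosome name.
#' @param maskBlock mask block size in bp.
#' @return a single-sequence [Biostrings::DNAStringSet].
#' @export
simulateGenome <- function(length, gc = 0.36, maskedFraction = 0,
                           seed = NULL, name = "chrS", maskBlock = 500L) {
    .maybeSeed(seed)
    length <- as.integer(length)
    if (is.na(length) || length < 1000L) {
        stop("'length' must be >= 1000 bp")
    }
    if (gc <= 0 || gc >= 1) stop("'gc' must lie in (0, 1)")
    if (maskedFraction < 0 || maskedFraction >= 1) {
        stop("'maskedFraction' must lie in [0, 1)")
    }
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    if (maskedFraction > 0) {
        nTiles <- length %/% maskBlock
        nMask <- min(round(maskedFraction * length / maskBlock), nTiles)
        if (nMask > 0) {
            tiles <- sample.int(nTiles, nMask)
            at <- unlist(lapply(tiles, function(ti) {
                seq.int((ti - 1L) * maskBlock + 1L, ti * maskBlock)
            }))
            bases[at] <- "N"
        }
    }
    dss <- DNAStringSet(paste0(bases, collapse = ""))
    names(dss) <- name
    dss
}

# shared read emission: one 25-nt read from a uniformly chosen footprint
# end; plus reads run rightward from the footprint start, minus reads are
# the reverse complement ending at the footprint's right edge
.emitReads <- function(genome, chrom, fpStart, footprint, readLength) {
    n <- length(fpStart)
    plus <- runif(n) < 0.5
    five <- ifelse(plus, fpStart, fpStart + footprint - 1L)
    st <- ifelse(plus, five, five - readLength + 1L)
    seqs <- DNAStringSet(rep("", n))
    for (chr in unique(chrom)) {
        i <- which(chrom == chr)
        seqs[i] <- extractAt(
            genome[[chr]],
            IRanges(st[i], width = readLength)
        )
    }
    seqs[!plus] <- reverseComplement(seqs[!plus])
    list(plus = plus, five = five, seqs = seqs)
}

.simFromFragments <- function(genome, chrom, fs, fe, n, beta, biasWidth,
                              readLength, footprint, libraryType,
                              library, sampleFragments = TRUE) {
    L <- fe - fs + 1L
    nStarts <- L - footprint + 1L
    a <- pmin(biasWidth, nStarts)
    rightFirst <- pmax(nStarts - biasWidth + 1L, a + 1L)
    b <- pmax(nStarts - rightFirst + 1L, 0L)
    t <- a + b
    wSum <- beta * t + (nStarts - t)
    if (sampleFragments) {
        # placement-position-uniform at beta = 1: every candidate
        # footprint position across the digest is equally likely
        fi <- sample.int(length(fs), n, replace = TRUE, prob = wSum)
    } else {
        fi <- seq_len(n) # one pre-drawn fragment per molecule
    }
    nsI <- nStarts[fi]
    aI <- a[fi]
    rfI <- rightFirst[fi]
    tI <- t[fi]
    pTerm <- beta * tI / (beta * tI + (nsI - tI))
    isTerm <- runif(n) < pTerm
    j <- pmin(1L + as.integer(floor(runif(n) * tI)), tI)
    relTerm <- ifelse(j <= aI, j, rfI + (j - aI - 1L))
    nInt <- nsI - tI
    relInt <- aI + pmin(
        1L + as.integer(floor(runif(n) * pmax(nInt, 1L))), pmax(nInt, 1L)
    )
    rel <- ifelse(isTerm, relTerm, relInt)
    fpStart <- fs[fi] + rel - 1L
    dyad <- fpStart + (footprint - 1L) %/% 2L
    em <- .emitReads(genome, chrom[fi], fpStart, footprint, readLength)
    reads <- GRanges(chrom[fi], IRanges(em$five, width = 1L),
        strand = ifelse(em$plus, "+", "-"),
        plantedDyad = dyad,
        cause = ifelse(isTerm, "terminal", "interior"),
        fragStart = fs[fi],
        fragEnd = fe[fi],
        seqinfo = Seqinfo(names(genome), .genomeSeqlengths(genome))
    )
    names(em$seqs) <- sprintf("%s_read%06d", library, seq_len(n))
    list(
        reads = reads, sequences = em$seqs, library = library,
        config = list(
            libraryType = libraryType, n = n, beta = beta,
            biasWidth = biasWidth, readLength = readLength,
            footprint = footprint
        )
    )
}

#' Simulate an enzyme-digest invitrosome library
#'
#' Digests the genome in silico, keeps fragments long enough to carry a
#' footprint, and places \code{n} nucleosome footprints: candidate start
#' positions within \code{biasWidth} bp of either fragment terminus carry
#' weight \code{beta}, all others weight 1, and fragments are sampled in
#' proportion to their total placement weight (so at \code{beta = 1}
#' every candidate position in the digest is equally likely). One 25-nt
#' read is emitted from a uniformly chosen footprint end, on the strand
#' that puts its 5' base at that end -- exactly what single-end
#' sequencing of mononucleosome cores yields. The returned truth records
#' the planted dyad, the source fragment and whether the placement was
#' terminal or interior.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param enzyme an [EnzymeDef-class] or built-in name.
#' @param n number of molecules (reads).
#' @param beta terminal-placement enrichment factor (>= 1; 1 = no end
#'   bias).
#' @param biasWidth bp from a terminus counted as terminal (default 1:
#'   enrichment confined to the very ends).
#' @param readLength emitted read length, default 25.
#' @param footprint footprint length, default 147; fragments shorter than
#'   this carry no placements.
#' @param seed optional RNG seed; identical inputs and seed give
#'   byte-identical output.
#' @param library library name.
#' @return a list: \code{reads} (width-1 stranded
#'   [GenomicRanges::GRanges] of 5' positions with truth columns
#'   \code{plantedDyad}, \code{cause}, \code{fragStart}, \code{fragEnd}),
#'   \code{sequences} ([Biostrings::DNAStringSet]), \code{fragments}
#'   (the [FragmentTable-class] used), \code{library}, \code{config}.
#' @export
simulateEnzymeLibrary <- function(genome, enzyme, n, beta = 1,
                                  biasWidth = 1L, readLength = 25L,
                                  footprint = 147L, seed = NULL,
                                  library = NULL) {
    genome <- .checkGenome(genome)
    .maybeSeed(seed)
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be >= 1")
    if (beta < 1) stop("'beta' must be >= 1")
    enzyme <- .asEnzyme(enzyme)
    if (is.null(library)) library <- enzyme@name
    cs <- findCutSites(genome, enzyme)
    ft <- buildFragmentTable(cs,
        minLength = footprint, enzyme = enzyme@name
    )
    frs <- fragments(ft)
    if (!length(frs)) {
        stop(sprintf(
            "no %s fragment is >= %d bp; nothing can be reconstituted",
            enzyme@name, footprint
        ))
    }
    sim <- .simFromFragments(
        genome, as.character(seqnames(frs)), start(frs), end(frs),
        n, beta, as.integer(biasWidth), as.integer(readLength),
        as.integer(footprint), "enzyme_digest", library
    )
    sim$fragments <- ft
    sim$enzyme <- enzyme@name
    sim
}

#' Simulate an ultra-sonicated (sheared) invitrosome library
#'
#' Shear breakpoints are uniform at random: each molecule draws a
#' fragment length uniformly from \code{sizeRange} (the gel size
#' selection) and a uniform genomic start. Footprint placement within
#' each fragment uses the same terminal weighting as
#' [simulateEnzymeLibrary()], so the library is end-biased at its own
#' (random) ends -- but because those ends fall anywhere, no enrichment
#' appears at any fixed cut site set.
#'
#' @inheritParams simulateEnzymeLibrary
#' @param sizeRange fragment size selection window in bp, default
#'   \code{c(600, 800)}.
#' @return as [simulateEnzymeLibrary()] (without a fragment table).
#' @export
simulateShearedLibrary <- function(genome, n, sizeRange = c(600L, 800L),
                                   beta = 1, biasWidth = 1L,
                                   readLength = 25L, footprint = 147L,
                                   seed = NULL, library = "US") {
    genome <- .checkGenome(genome)
    .maybeSeed(seed)
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be >= 1")
    if (beta < 1) stop("'beta' must be >= 1")
    sizeRange <- as.integer(sizeRange)
    lens <- .genomeSeqlengths(genome)
    if (sizeRange[1] < footprint || sizeRange[1] > sizeRange[2] ||
        sizeRange[2] > max(lens)) {
        stop("'sizeRange' infeasible for this genome/footprint")
    }
    ok <- lens >= sizeRange[2]
    if (!any(ok)) stop("no sequence long enough for 'sizeRange'")
    lens <- lens[ok]
    fragLen <- sizeRange[1] +
        as.integer(floor(runif(n) * (sizeRange[2] - sizeRange[1] + 1L)))
    chromI <- sample(names(lens), n,
        replace = TRUE,
        prob = lens - sizeRange[2] + 1
    )
    fs <- 1L + as.integer(floor(runif(n) * (lens[chromI] - fragLen + 1L)))
    fe <- fs + fragLen - 1L
    .simFromFragments(
        genome, chromI, fs, fe, n, beta, as.integer(biasWidth),
        as.integer(readLength), as.integer(footprint), "sheared",
        library,
        sampleFragments = FALSE
    )
}

#' Simulate a uniform random read library
#'
#' Read 5' positions are uniform over the unmasked genome (positions
#' whose read would run off the chromosome, or start on an N, are
#' rejected and redrawn), strands uniform, with optional i.i.d.
#' substitution errors -- an in-silico read generator in the spirit of
#' ART, giving a non-nucleosomal baseline for any cut site set.
#'
#' @inheritParams simulateEnzymeLibrary
#' @param errorRate per-base substitution probability.
#' @return a list with \code{reads} (truth columns \code{cause} =
#'   \code{"uniform"}), \code{sequences}, \code{library}, \code{config}.
#' @export
simulateUniformLibrary <- function(genome, n, readLength = 25L,
                                   errorRate = 0, seed = NULL,
                                   library = "ART") {
    genome <- .checkGenome(genome)
    .maybeSeed(seed)
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be a positive count")
    if (errorRate < 0 || errorRate >= 1) {
        stop("'errorRate' must lie in [0, 1)")
    }
    readLength <- as.integer(readLength)
    lens <- .genomeSeqlengths(genome)
    chrom <- character(n)
    five <- integer(n)
    plus <- logical(n)
    todo <- seq_len(n)
    while (length(todo)) {
        m <- length(todo)
        chromT <- sample(names(lens), m, replace = TRUE, prob = lens)
        posT <- 1L + as.integer(floor(runif(m) * lens[chromT]))
        plusT <- runif(m) < 0.5
        st <- ifelse(plusT, posT, posT - readLength + 1L)
        en <- st + readLength - 1L
        keep <- st >= 1L & en <= lens[chromT]
        if (any(keep)) {
            base <- substring(
                as.character(genome)[chromT[keep]],
                posT[keep], posT[keep]
            )
            keep[keep] <- base != "N"
        }
        idx <- todo[keep]
        chrom[idx] <- chromT[keep]
        five[idx] <- posT[keep]
        plus[idx] <- plusT[keep]
        todo <- todo[!keep]
    }
    st <- ifelse(plus, five, five - readLength + 1L)
    seqs <- DNAStringSet(rep("", n))
    for (chr in unique(chrom)) {
        i <- which(chrom == chr)
        seqs[i] <- extractAt(genome[[chr]], IRanges(st[i], width = readLength))
    }
    seqs[!plus] <- reverseComplement(seqs[!plus])
    if (errorRate > 0) {
        m <- as.matrix(seqs)
        hit <- which(runif(length(m)) < errorRate & m != "N")
        if (length(hit)) {
            cur <- m[hit]
            alt <- vapply(cur, function(bb) {
                sample(setdiff(c("A", "C", "G", "T"), bb), 1L)
            }, character(1))
            m[hit] <- alt
            seqs <- DNAStringSet(apply(m, 1L, paste0, collapse = ""))
        }
    }
    names(seqs) <- sprintf("%s_read%06d", library, seq_len(n))
    reads <- GRanges(chrom, IRanges(five, width = 1L),
        strand = ifelse(plus, "+", "-"),
        plantedDyad = NA_integer_,
        cause = "uniform",
        fragStart = NA_integer_,
        fragEnd = NA_integer_,
        seqinfo = Seqinfo(names(genome), lens)
    )
    list(
        reads = reads, sequences = seqs, library = library,
        config = list(
            libraryType = "uniform", n = n, readLength = readLength,
            errorRate = errorRate
        )
    )
}

#' Write simulated reads as FASTQ
#'
#' Constant maximum base quality; the simulator's error model is the
#' substitution rate, not a quality-score profile.
#'
#' @param sim a simulated library list.
#' @param path output FASTQ (gzipped if the extension says so).
#' @return the path, invisibly.
#' @export
writeReadsFastq <- function(sim, path) {
    quals <- Biostrings::BStringSet(
        strrep("I", width(sim$sequences))
    )
    writeXStringSet(sim$sequences, path,
        format = "fastq",
        qualities = quals
    )
    invisible(path)
}

#' Write simulated read truth as BED6 and TSV
#'
#' The BED6 file holds the aligned read 5' positions (name = read id,
#' score = 0, strand), usable directly by [callDyads()] without any
#' aligner; the TSV holds the full truth table (fragment interval,
#' planted dyad, placement cause, strand).
#'
#' @param sim a simulated library list.
#' @param prefix output prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.truth.tsv}.
#' @return the two paths, invisibly.
#' @export
writeTruth <- function(sim, prefix) {
    r <- sim$reads
    bed <- paste0(prefix, ".bed")
    df <- data.frame(
        chrom = as.character(seqnames(r)),
        start = start(r) - 1L,
        end = start(r),
        name = names(sim$sequences),
        score = 0L,
        strand = as.character(strand(r))
    )
    write.table(df, bed,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    tsv <- paste0(prefix, ".truth.tsv")
    .writeTsv(data.frame(
        read = names(sim$sequences),
        chrom = as.character(seqnames(r)),
        fivePrime = start(r),
        strand = as.character(strand(r)),
        fragStart = r$fragStart,
        fragEnd = r$fragEnd,
        plantedDyad = r$plantedDyad,
        cause = r$cause
    ), tsv)
    invisible(c(bed, tsv))
}
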