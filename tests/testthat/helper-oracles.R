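# Independent brute-force oracles. These deliberately share no code with
# the package: position-by-position scans, all-pairs matching and
# substring hashing, used to freeze expected values for the fast
# implementations.

.iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# scan every offset of a character sequence against an IUPAC pattern;
# returns cut boundaries (bases left of the cut, 1..len-1)
bruteCutSites <- function(seq, recognition, cutOffset) {
    s <- strsplit(toupper(seq), "")[[1]]
    pat <- strsplit(recognition, "")[[1]]
    k <- length(pat)
    hits <- integer(0)
    if (length(s) >= k) {
        for (i in seq_len(length(s) - k + 1L)) {
            ok <- TRUE
            for (j in seq_len(k)) {
                if (!(s[i + j - 1L] %in% .iupac[[pat[j]]])) {
                    ok <- FALSE
                    break
                }
            }
            if (ok) hits <- c(hits, i - 1L + cutOffset)
        }
    }
    hits[hits >= 1L & hits <= length(s) - 1L]
}

# label every base of a fragment of width w as suspect (within d of an
# end) or not; used to check the capped suspect-fraction formula
bruteSuspectBases <- function(w, d) {
    pos <- seq_len(w)
    sum(pos <= d | pos > w - d)
}

# per-invitrosome loop version of the three-way classification
# fragDf: chrom/fs/fe of retained fragments; boundaries: named list
bruteClassify <- function(invDf, fragDf, boundaries, d, offset = 0L) {
    n <- nrow(invDf)
    out <- character(n)
    for (i in seq_len(n)) {
        chr <- invDf$chrom[i]
        a <- invDf$start[i]
        z <- invDf$end[i]
        b <- boundaries[[chr]]
        if (!is.null(b) && any(b >= a & b <= z - 1L)) {
            out[i] <- "innercut"
            next
        }
        f <- fragDf[fragDf$chrom == chr, , drop = FALSE]
        sus <- FALSE
        for (j in seq_len(nrow(f))) {
            fs <- f$fs[j]
            fe <- f$fe[j]
            inStart <- a >= fs + offset & a <= fs + offset + d - 1L &
                a >= fs & a <= fe
            inEnd <- z >= fe - offset - d + 1L & z <= fe - offset &
                z >= fs & z <= fe
            if (inStart || inEnd) {
                sus <- TRUE
                break
            }
        }
        out[i] <- if (sus) "suspect" else "passed"
    }
    out
}

# all-pairs dyad matching
bruteRecover <- function(susChrom, susDyad, compChrom, compDyad, tol) {
    vapply(seq_along(susDyad), function(i) {
        any(compChrom == susChrom[i] &
            abs(compDyad - susDyad[i]) <= tol)
    }, logical(1))
}

# substring hashing k-mer counter
bruteKmerFreq <- function(seqs, k = 4L) {
    seqs <- toupper(as.character(seqs))
    len <- nchar(seqs[1])
    nPos <- len - k + 1L
    bases <- c("A", "C", "G", "T")
    kmers <- do.call(paste0, rev(expand.grid(
        rep(list(bases), k), stringsAsFactors = FALSE
    ))[, seq_len(k)])
    kmers <- sort(kmers)
    freq <- matrix(NA_real_, nrow = length(kmers), ncol = nPos,
        dimnames = list(kmers, NULL))
    for (p in seq_len(nPos)) {
        w <- substr(seqs, p, p + k - 1L)
        w <- w[!grepl("[^ACGT]", w)]
        cnt <- table(factor(w, levels = kmers))
        if (sum(cnt) > 0) freq[, p] <- as.numeric(cnt) / sum(cnt)
    }
    freq
}

# textbook correlation formulas
handPearson <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    num / den
}

handSpearman <- function(x, y) {
    handPearson(rank(x), rank(y))
}

# random classification instance on a toy genome (no sequence needed)
randomRecoveryInstance <- function(seed, chromLen = 50000L, nCuts = 50L,
                                   nInv = 500L) {
    set.seed(seed)
    b <- sort(sample(seq(148L, chromLen - 148L), nCuts))
    b <- b[c(TRUE, diff(b) >= 1L)]
    ft <- buildFragmentTable(list(chrT = b), c(chrT = chromLen),
        minLength = 147L
    )
    dyad <- sample(seq(74L, chromLen - 73L), nInv, replace = TRUE)
    inv <- GRanges("chrT", IRanges(dyad - 73L, dyad + 73L),
        strand = sample(c("+", "-"), nInv, replace = TRUE),
        dyad = dyad, library = "toy", label = "unclassified",
        seqinfo = Seqinfo("chrT", chromLen)
    )
    list(boundaries = list(chrT = b), fragmentTable = ft, inv = inv)
}
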