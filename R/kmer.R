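#' @include recovery.R
NULL

# all k-mers over ACGT in index order (A=0 .. T=3, first base most
# significant), matching the integer encoding used for counting
.allKmers <- function(k) {
    bases <- c("A", "C", "G", "T")
    grid <- expand.grid(rev(replicate(k, bases, simplify = FALSE)),
        stringsAsFactors = FALSE
    )
    apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0,
        collapse = ""
    )
}

#' Position-specific k-mer frequency matrix
#'
#' Counts every k-mer at every start position along a set of equal-length
#' footprint sequences and normalizes per position. Windows containing a
#' non-ACGT base (N from masking) are excluded from both the numerator
#' and that position's denominator, so partially masked footprints still
#' contribute their unmasked positions.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or character vector) of
#'   equal-length sequences, typically 147-nt footprints from
#'   [extractFootprints()].
#' @param k k-mer length, default 4.
#' @param library name stored on the matrix.
#' @return a [KmerMatrix-class]: 4^k rows, \code{length - k + 1} columns
#'   (144 for 147-nt sequences and k = 4).
#' @examples
#' m <- positionKmerMatrix(rep(strrep("A", 147), 2))
#' kmerFrequencies(m)["AAAA", 1] # 1
#' @export
positionKmerMatrix <- function(sequences, k = 4L, library = "library") {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    if (is.character(sequences)) sequences <- DNAStringSet(sequences)
    if (!length(sequences)) stop("empty sequence set")
    w <- width(sequences)
    if (length(unique(w)) != 1L) {
        stop("all sequences must have the same length")
    }
    len <- w[1]
    if (len < k) stop("sequences shorter than k")
    nPos <- len - k + 1L
    chars <- as.matrix(sequences)
    code <- match(chars, c("A", "C", "G", "T")) - 1L
    dim(code) <- dim(chars)
    nK <- 4L^k
    counts <- matrix(0L, nrow = nK, ncol = nPos)
    for (p in seq_len(nPos)) {
        idx <- code[, p]
        for (j in seq_len(k - 1L)) {
            idx <- idx * 4L + code[, p + j]
        }
        counts[, p] <- tabulate(idx + 1L, nbins = nK)
    }
    tot <- colSums(counts)
    freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
    freq[, tot == 0L] <- NA_real_
    km <- .allKmers(k)
    dimnames(counts) <- dimnames(freq) <- list(
        kmer = km, position = seq_len(nPos)
    )
    new("KmerMatrix",
        k = k, library = library, counts = counts, freq = freq,
        nSequences = length(sequences)
    )
}

#' @describeIn positionKmerMatrix frequency matrix (columns sum to 1).
#' @param x a [KmerMatrix-class].
#' @export
setMethod("kmerFrequencies", "KmerMatrix", function(x) x@freq)

#' @describeIn positionKmerMatrix raw count matrix.
#' @export
setMethod("kmerCounts", "KmerMatrix", function(x) x@counts)

setMethod("show", "KmerMatrix", function(object) {
    cat(sprintf(
        "KmerMatrix: %s, k = %d, %d x %d (k-mers x positions), n = %d sequence(s)\n",
        object@library, object@k, nrow(object@freq), ncol(object@freq),
        object@nSequences
    ))
})

# column indices for the "ends" region: the first and last n k-mer start
# positions (7 + 7 of 144 by default for k = 4)
.endsColumns <- function(nPos, endsN) {
    if (2L * endsN > nPos) stop("'endsN' too large for this matrix")
    c(seq_len(endsN), seq(nPos - endsN + 1L, nPos))
}

#' Correlate two position-specific k-mer matrices
#'
#' Flattens the selected (k-mer, position) cells of both frequency
#' matrices into paired vectors and returns the requested correlation
#' coefficient. Region \code{"full"} uses every cell; \code{"ends"} uses
#' only the first and last \code{endsN} k-mer start positions, the
#' region where end-biased footprints would distort composition. Cells
#' undefined in either matrix (all-N columns) are dropped pairwise.
#'
#' @param m1,m2 [KmerMatrix-class] objects with equal k and dimensions.
#' @param method \code{"pearson"} or \code{"spearman"} (average ranks for
#'   ties).
#' @param region \code{"full"} or \code{"ends"}.
#' @param endsN positions taken from each end for \code{region = "ends"}.
#' @return the correlation coefficient.
#' @export
correlateKmerMatrices <- function(m1, m2,
                                  method = c("pearson", "spearman"),
                                  region = c("full", "ends"),
                                  endsN = 7L) {
    method <- match.arg(method)
    region <- match.arg(region)
    stopifnot(is(m1, "KmerMatrix"), is(m2, "KmerMatrix"))
    if (m1@k != m2@k || !identical(dim(m1@freq), dim(m2@freq))) {
        stop("matrices must share k and dimensions")
    }
    cols <- if (region == "ends") {
        .endsColumns(ncol(m1@freq), as.integer(endsN))
    } else {
        seq_len(ncol(m1@freq))
    }
    x <- as.vector(m1@freq[, cols])
    y <- as.vector(m2@freq[, cols])
    ok <- !(is.na(x) | is.na(y))
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
        stop("correlation undefined: zero variance or too few cells")
    }
    cor(x, y, method = method)
}

#' Correlation report across recovery sub-libraries
#'
#' Correlates each enzyme sub-library (Raw, Passed, PostRecovery) against
#' each end-free reference library, and all sub-library pairs within each
#' enzyme, for both correlation methods and both regions.
#'
#' @param subLibraries named list (one element per enzyme library) of
#'   named lists of [KmerMatrix-class] objects, e.g.
#'   \code{list(RsaI = list(Raw = ..., Passed = ..., PostRecovery = ...))}.
#' @param referenceLibraries named list of [KmerMatrix-class] objects
#'   for libraries without enzyme-defined ends (uniform/sheared).
#' @param methods,regions subsets of \code{c("pearson", "spearman")} and
#'   \code{c("full", "ends")}.
#' @param endsN positions per end for the \code{"ends"} region.
#' @return list of two data.frames: \code{betweenLibraries} (enzyme
#'   sub-library x reference) and \code{withinLibraries} (sub-library
#'   pairs within each enzyme).
#' @export
correlationReport <- function(subLibraries, referenceLibraries,
                              methods = c("pearson", "spearman"),
                              regions = c("full", "ends"),
                              endsN = 7L) {
    stopifnot(length(subLibraries) >= 1L)
    between <- list()
    within <- list()
    for (enz in names(subLibraries)) {
        subs <- subLibraries[[enz]]
        need <- c("Raw", "Passed", "PostRecovery")
        if (!all(need %in% names(subs))) {
            stop(sprintf(
                "sub-libraries for %s must include %s",
                enz, paste(need, collapse = ", ")
            ))
        }
        for (sub in names(subs)) {
            for (ref in names(referenceLibraries)) {
                for (meth in methods) {
                    for (reg in regions) {
                        between[[length(between) + 1L]] <- data.frame(
                            enzyme = enz, subLibrary = sub,
                            reference = ref, method = meth,
                            region = reg,
                            correlation = correlateKmerMatrices(
                                subs[[sub]],
                                referenceLibraries[[ref]],
                                method = meth, region = reg,
                                endsN = endsN
                            )
                        )
                    }
                }
            }
        }
        pairs <- expand.grid(
            a = names(subs), b = names(subs),
            stringsAsFactors = FALSE
        )
        for (i in seq_len(nrow(pairs))) {
            for (meth in methods) {
                for (reg in regions) {
                    within[[length(within) + 1L]] <- data.frame(
                        enzyme = enz,
                        subLibraryA = pairs$a[i],
                        subLibraryB = pairs$b[i],
                        method = meth, region = reg,
                        correlation = correlateKmerMatrices(
                            subs[[pairs$a[i]]], subs[[pairs$b[i]]],
                            method = meth, region = reg, endsN = endsN
                        )
                    )
                }
            }
        }
    }
    list(
        betweenLibraries = do.call(rbind, between),
        withinLibraries = do.call(rbind, within)
    )
}

#' Write a k-mer matrix as TSV (rows = k-mers, columns = positions)
#'
#' @param kmerMatrix a [KmerMatrix-class].
#' @param path output file.
#' @param what \code{"freq"} or \code{"counts"}.
#' @return the path, invisibly.
#' @export
writeKmerMatrixTsv <- function(kmerMatrix, path,
                               what = c("freq", "counts")) {
    what <- match.arg(what)
    m <- if (what == "freq") {
        kmerFrequencies(kmerMatrix)
    } else {
        kmerCounts(kmerMatrix)
    }
    df <- data.frame(kmer = rownames(m), m, check.names = FALSE)
    .writeTsv(df, path)
}
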