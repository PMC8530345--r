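#' @include enzymes.R
NULL

#' Build the fragment table from cut boundaries
#'
#' Consecutive boundaries, plus the chromosome termini, define fragments
#' that tile each chromosome exactly. An optional minimum-length filter
#' (147 bp by default: one nucleosome footprint) moves shorter fragments
#' to a side list -- they are excluded from end-bias and suspect-range
#' analyses but kept for reporting, because the recovery logic depends on
#' knowing these loci exist.
#'
#' @param cutSites an [IRanges::IntegerList] from [findCutSites()], or a
#'   plain named list of sorted integer boundaries.
#' @param seqlengths named integer vector of chromosome lengths; defaults
#'   to the lengths recorded by [findCutSites()].
#' @param minLength minimum retained fragment length in bp, or \code{NA}
#'   to keep everything.
#' @param enzyme optional enzyme name stored for bookkeeping.
#' @return a [FragmentTable-class].
#' @examples
#' ft <- buildFragmentTable(list(chr1 = 3L), c(chr1 = 10L), minLength = NA)
#' fragments(ft) # [1,3] and [4,10]
#' @export
buildFragmentTable <- function(cutSites, seqlengths = NULL,
                               minLength = 147L, enzyme = NA_character_) {
    if (is.null(seqlengths)) {
        seqlengths <- metadata(cutSites)$seqlengths
        if (is.null(seqlengths)) {
            stop("'seqlengths' required when cutSites carry no genome metadata")
        }
    }
    if (is.null(names(seqlengths))) stop("'seqlengths' must be named")
    if (is(cutSites, "List")) {
        if (is.na(enzyme) && !is.null(metadata(cutSites)$enzyme)) {
            enzyme <- metadata(cutSites)$enzyme
        }
        cutSites <- as.list(cutSites)
    }
    chroms <- names(seqlengths)
    parts <- lapply(chroms, function(chr) {
        len <- seqlengths[[chr]]
        b <- sort(unique(as.integer(cutSites[[chr]])))
        if (length(b) && (min(b) < 1L || max(b) > len - 1L)) {
            stop(sprintf(
                "cut boundary outside chromosome %s (length %d)", chr, len
            ))
        }
        data.frame(
            chrom = chr,
            start = c(1L, b + 1L),
            end = c(b, len)
        )
    })
    df <- do.call(rbind, parts)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
        seqinfo = Seqinfo(chroms, seqlengths)
    )
    minLength <- as.integer(minLength)
    if (!is.na(minLength)) {
        keep <- width(gr) >= minLength
        retained <- gr[keep]
        removed <- gr[!keep]
    } else {
        retained <- gr
        removed <- gr[0]
    }
    new("FragmentTable",
        fragments = retained, removed = removed,
        minLength = minLength, enzyme = as.character(enzyme)
    )
}

#' @describeIn buildFragmentTable retained fragments.
#' @param x a [FragmentTable-class].
#' @export
setMethod("fragments", "FragmentTable", function(x) x@fragments)

#' @describeIn buildFragmentTable fragments removed by the filter.
#' @export
setMethod("removedFragments", "FragmentTable", function(x) x@removed)

#' @describeIn buildFragmentTable all fragments in genomic order
#'   (the pre-filter tiling).
#' @export
setMethod("allFragments", "FragmentTable", function(x) {
    sort(c(x@fragments, x@removed))
})

setMethod("show", "FragmentTable", function(object) {
    cat(sprintf(
        "FragmentTable (%s): %d retained fragment(s)",
        ifelse(is.na(object@enzyme), "unnamed enzyme", object@enzyme),
        length(object@fragments)
    ))
    if (!is.na(object@minLength)) {
        cat(sprintf(
            ", %d removed (< %d bp)",
            length(object@removed), object@minLength
        ))
    }
    cat(sprintf(
        "; %d sequence(s)\n", length(seqlengths(object@fragments))
    ))
})

#' Digestion statistics and suspect genome fraction
#'
#' Computes, from the pre-filter fragment tiling, the mean fragment length
#' and the fraction of genomic bases lying within \code{suspectRange}
#' bases of a fragment end. Fragments shorter than twice the suspect range
#' are entirely suspect (the two end regions overlap and are capped at the
#' fragment length).
#'
#' @param fragmentTable a [FragmentTable-class].
#' @param suspectRange suspect distance d in bp (>= 0).
#' @return a list with \code{nFragments}, \code{nCutSites},
#'   \code{genomeLength}, \code{meanFragmentLength},
#'   \code{meanSiteSpacing} (genome length / cut sites, Inf when
#'   undigested), \code{suspectRange} and \code{genomeFractionSuspect}.
#' @examples
#' ft <- buildFragmentTable(list(chr1 = integer(0)), c(chr1 = 1000L),
#'     minLength = NA)
#' digestionStats(ft, 200)$genomeFractionSuspect # 0.4
#' @export
digestionStats <- function(fragmentTable, suspectRange) {
    stopifnot(is(fragmentTable, "FragmentTable"))
    d <- suspectRange
    if (length(d) != 1L || is.na(d) || d < 0) {
        stop("'suspectRange' must be a single non-negative number")
    }
    frs <- allFragments(fragmentTable)
    w <- width(frs)
    genomeLength <- sum(as.numeric(w))
    nCut <- sum(lengths(split(frs, seqnames(frs))) - 1L)
    list(
        nFragments = length(frs),
        nCutSites = as.integer(nCut),
        genomeLength = genomeLength,
        meanFragmentLength = mean(w),
        meanSiteSpacing = if (nCut > 0) genomeLength / nCut else Inf,
        suspectRange = d,
        genomeFractionSuspect = sum(pmin(as.numeric(w), 2 * d)) /
            genomeLength
    )
}

#' Export fragments as BED4 (name = fragment length) or TSV
#'
#' @param fragmentTable a [FragmentTable-class].
#' @param path output file.
#' @param format \code{"bed"} (0-based half-open, name column = length) or
#'   \code{"tsv"} (1-based inclusive with a \code{retained} flag).
#' @param which \code{"retained"}, \code{"removed"} or \code{"all"}.
#' @return the path, invisibly.
#' @export
exportFragments <- function(fragmentTable, path,
                            format = c("bed", "tsv"),
                            which = c("retained", "all", "removed")) {
    format <- match.arg(format)
    which <- match.arg(which)
    gr <- switch(which,
        retained = fragments(fragmentTable),
        removed = removedFragments(fragmentTable),
        all = allFragments(fragmentTable)
    )
    if (format == "bed") {
        df <- data.frame(
            chrom = as.character(seqnames(gr)),
            start = start(gr) - 1L,
            end = end(gr),
            name = width(gr)
        )
        write.table(df, path,
            sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE
        )
    } else {
        retained <- rep(TRUE, length(gr))
        if (which == "all" && length(removedFragments(fragmentTable))) {
            retained <- !overlapsAny(gr, removedFragments(fragmentTable),
                type = "equal"
            )
        }
        if (which == "removed") retained <- rep(FALSE, length(gr))
        df <- data.frame(
            chrom = as.character(seqnames(gr)),
            start = start(gr),
            end = end(gr),
            length = width(gr),
            retained = retained
        )
        .writeTsv(df, path)
    }
    invisible(path)
}
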