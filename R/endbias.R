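#' @include dyads.R
NULL

# 5' pole of stranded ranges (reads or footprints: for a footprint the 5'
# pole of the calling read is the start on + and the end on -)
.fivePrime <- function(gr) {
    str <- as.character(strand(gr))
    if (any(str == "*")) stop("stranded input required")
    ifelse(str == "+", start(gr), end(gr))
}

# Per-position start counts at positions 1..window from fragment ends.
# Left ends use plus-strand starts, right ends minus-strand starts
# (mirrored), unless bothStrands = TRUE, in which case each window
# position counts starts of either strand (coverage semantics). When
# windows from the two ends of one fragment overlap, the left window
# takes precedence up to the fragment midpoint so no genomic base is
# attributed twice.
.endWindowCounts <- function(gr, fragmentTable, offset, window,
                             bothStrands = FALSE) {
    frs <- fragments(fragmentTable)
    if (!length(frs)) stop("fragment table has no retained fragments")
    if (window > min(width(frs)) / 2) {
        stop(sprintf(
            "window (%d) exceeds half the shortest retained fragment (%d bp)",
            window, min(width(frs))
        ))
    }
    five <- .fivePrime(gr)
    str <- as.character(strand(gr))
    chromR <- as.character(seqnames(gr))
    counts <- numeric(window)
    pcols <- seq_len(window)
    for (chr in seqlevels(frs)) {
        f <- frs[seqnames(frs) == chr]
        if (!length(f)) next
        len <- seqlengths(frs)[[chr]]
        if (is.na(len)) len <- max(end(f))
        onChr <- chromR == chr
        if (!any(onChr)) next
        plusTab <- tabulate(five[onChr & str == "+"], nbins = len)
        minusTab <- tabulate(five[onChr & str == "-"], nbins = len)
        leftTab <- if (bothStrands) plusTab + minusTab else plusTab
        rightTab <- if (bothStrands) plusTab + minusTab else minusTab
        fs <- start(f)
        fe <- end(f)
        mid <- fs + (width(f) - 1L) %/% 2L
        lp <- outer(fs + offset - 1L, pcols, "+")
        lOK <- lp <= pmin(fe, mid)
        lv <- matrix(leftTab[pmax(lp, 1L)], nrow = nrow(lp))
        lv[!lOK] <- 0
        rp <- outer(fe - offset + 1L, pcols, "-")
        rOK <- rp >= pmax(fs, mid + 1L)
        rv <- matrix(rightTab[pmax(rp, 1L)], nrow = nrow(rp))
        rv[!rOK] <- 0
        counts <- counts + colSums(lv) + colSums(rv)
    }
    counts
}

#' Start-ratio end-bias profile
#'
#' For each position p = 1..window from a fragment end (position 1 is the
#' terminal fragment base), counts invitrosome starts sitting exactly
#' there -- plus-strand read starts at left fragment ends and minus-strand
#' read starts at right fragment ends, aggregated into one axis -- and
#' divides by all invitrosome starts in the library. An end-bias-free
#' library is flat; terminal-placement preference shows as a spike at
#' position 1.
#'
#' @param invitrosomes stranded [GenomicRanges::GRanges] of invitrosome
#'   footprints (or raw read 5' positions); the 5' pole is counted.
#' @param fragmentTable a [FragmentTable-class] filtered to >= 147 bp.
#' @param offset residual half-site offset: positions may be counted from
#'   the first base after the half recognition site (2 for RsaI, 3 for
#'   HincII) instead of the terminal base. Default 0: position 1 is the
#'   precise fragment end, where flush-assembled nucleosome starts fall.
#' @param window number of positions, default 73 (half a footprint).
#' @param library,cutsiteSet names recorded on the profile.
#' @return an [EndBiasProfile-class] with metric \code{"start_ratio"}.
#' @seealso [occupancyProfile()], [enrichmentAtPosition()]
#' @export
startRatioProfile <- function(invitrosomes, fragmentTable, offset = 0L,
                              window = 73L, library = "library",
                              cutsiteSet = fragmentTable@enzyme) {
    if (!length(invitrosomes)) stop("empty library")
    window <- as.integer(window)
    offset <- as.integer(offset)
    counts <- .endWindowCounts(invitrosomes, fragmentTable, offset,
        window,
        bothStrands = FALSE
    )
    n <- length(invitrosomes)
    new("EndBiasProfile",
        library = library, cutsiteSet = as.character(cutsiteSet),
        metric = "start_ratio", window = window,
        values = counts / n, counts = counts,
        nTotalStarts = n, offset = offset
    )
}

#' Mean-normalized occupancy end-bias profile
#'
#' Start coverage (reads of either strand whose 5' base sits at the
#' position; 1-bp bins) is scaled to RPKM -- \code{1e9 / (binLength *
#' totalMappedStarts)} per read -- summed over all fragment ends at each
#' position 1..window, then divided by the mean over the window. A value
#' of 1 means occupancy at the average rate; the RPKM factor cancels in
#' the ratio, making the profile invariant to sequencing depth.
#'
#' @inheritParams startRatioProfile
#' @return an [EndBiasProfile-class] with metric
#'   \code{"normalized_occupancy"} (mean exactly 1 over the window).
#' @export
occupancyProfile <- function(invitrosomes, fragmentTable, offset = 0L,
                             window = 73L, library = "library",
                             cutsiteSet = fragmentTable@enzyme) {
    if (!length(invitrosomes)) stop("empty library")
    window <- as.integer(window)
    offset <- as.integer(offset)
    counts <- .endWindowCounts(invitrosomes, fragmentTable, offset,
        window,
        bothStrands = TRUE
    )
    n <- length(invitrosomes)
    rpkm <- counts * 1e9 / (1 * n)
    if (mean(rpkm) == 0) stop("zero mean start coverage in window")
    new("EndBiasProfile",
        library = library, cutsiteSet = as.character(cutsiteSet),
        metric = "normalized_occupancy", window = window,
        values = rpkm / mean(rpkm), counts = counts,
        nTotalStarts = n, offset = offset
    )
}

#' @describeIn startRatioProfile per-position profile values.
#' @param x an [EndBiasProfile-class].
#' @export
setMethod("profileValues", "EndBiasProfile", function(x) x@values)

setMethod("show", "EndBiasProfile", function(object) {
    cat(sprintf(
        "EndBiasProfile: %s vs %s cut sites (%s, window %d, n = %d)\n",
        object@library, object@cutsiteSet, object@metric,
        object@window, object@nTotalStarts
    ))
    cat(sprintf(
        "  value(1) = %.4g; window mean = %.4g\n",
        object@values[1], mean(object@values)
    ))
})

#' Compare libraries at one window position
#'
#' Reports, for each profile, its value at position \code{p} and the ratio
#' to the next-highest profile's value there. Because "percent enrichment"
#' is stated under two conventions in the field, the ratio is reported
#' both as \code{ratio x 100} and as \code{(ratio - 1) x 100}.
#'
#' @param profiles list of [EndBiasProfile-class] objects computed against
#'   the same cut site set.
#' @param p window position to compare (1-based).
#' @return a data.frame with one row per profile: \code{library},
#'   \code{value}, \code{ratioToNextHighest}, \code{ratioPct},
#'   \code{increasePct}.
#' @examples
#' # two libraries with values 0.8 and 0.2 at p = 1 give ratio 4
#' @export
enrichmentAtPosition <- function(profiles, p) {
    if (length(profiles) < 2L) stop("need at least two profiles")
    sets <- vapply(profiles, function(x) x@cutsiteSet, character(1))
    if (length(unique(sets)) != 1L) {
        stop("profiles computed against different cut site sets")
    }
    vals <- vapply(profiles, function(x) x@values[p], numeric(1))
    libs <- vapply(profiles, function(x) x@library, character(1))
    ratio <- vapply(seq_along(vals), function(i) {
        vals[i] / max(vals[-i])
    }, numeric(1))
    data.frame(
        library = libs,
        position = p,
        value = vals,
        ratioToNextHighest = ratio,
        ratioPct = 100 * ratio,
        increasePct = 100 * (ratio - 1)
    )
}

#' Write an end-bias profile as TSV
#'
#' Two columns: window position and profile value (plus the raw start
#' count backing it); metadata is carried in comment header lines.
#'
#' @param profile an [EndBiasProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
        "# library=%s cutsites=%s metric=%s offset=%d n_total_starts=%d ends=both",
        profile@library, profile@cutsiteSet, profile@metric,
        profile@offset, profile@nTotalStarts
    ), con)
    write.table(
        data.frame(
            position = seq_len(profile@window),
            value = profile@values,
            count = profile@counts
        ),
        con,
        sep = "\t", quote = FALSE, row.names = FALSE
    )
    invisible(path)
}
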