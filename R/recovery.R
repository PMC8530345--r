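#' @include endbias.R
NULL

#' Build suspect ranges around fragment ends
#'
#' For each retained fragment, the start region spans the
#' \code{suspectRange} bases beginning \code{offset} bases into the
#' fragment, and the end region mirrors it at the other terminus. Regions
#' are clipped to their fragment, so a fragment shorter than
#' \code{2 * suspectRange} is covered entirely (its two regions overlap).
#'
#' @param fragmentTable a [FragmentTable-class].
#' @param suspectRange suspect distance d in bp (>= 1).
#' @param offset residual half-site offset; 0 (default) anchors the
#'   regions at the terminal fragment base, matching where flush
#'   end-biased footprints actually start. Set to the enzyme's half-site
#'   length (2 for RsaI, 3 for HincII) to skip the residual recognition
#'   bases instead.
#' @return a [SuspectRangeSet-class].
#' @examples
#' ft <- buildFragmentTable(list(chr1 = integer(0)), c(chr1 = 1000L),
#'     minLength = NA)
#' sr <- buildSuspectRanges(ft, 200)
#' startRegions(sr) # [1, 200]
#' endRegions(sr) # [801, 1000]
#' @export
buildSuspectRanges <- function(fragmentTable, suspectRange, offset = 0L) {
    stopifnot(is(fragmentTable, "FragmentTable"))
    d <- as.integer(suspectRange)
    offset <- as.integer(offset)
    if (length(d) != 1L || is.na(d) || d < 1L) {
        stop("'suspectRange' must be a single integer >= 1")
    }
    if (offset < 0L) stop("'offset' must be non-negative")
    frs <- fragments(fragmentTable)
    fs <- start(frs)
    fe <- end(frs)
    sStart <- pmin(fs + offset, fe + 1L)
    sEnd <- pmin(fs + offset + d - 1L, fe)
    eEnd <- pmax(fe - offset, fs - 1L)
    eStart <- pmax(fe - offset - d + 1L, fs)
    keepS <- sStart <= sEnd
    keepE <- eStart <= eEnd
    chrom <- seqnames(frs)
    si <- seqinfo(frs)
    new("SuspectRangeSet",
        startRegions = GRanges(chrom[keepS],
            IRanges(sStart[keepS], sEnd[keepS]),
            seqinfo = si
        ),
        endRegions = GRanges(chrom[keepE],
            IRanges(eStart[keepE], eEnd[keepE]),
            seqinfo = si
        ),
        suspectRange = d, offset = offset
    )
}

#' @describeIn buildSuspectRanges per-fragment start regions.
#' @param x a [SuspectRangeSet-class].
#' @export
setMethod("startRegions", "SuspectRangeSet", function(x) x@startRegions)

#' @describeIn buildSuspectRanges per-fragment end regions.
#' @export
setMethod("endRegions", "SuspectRangeSet", function(x) x@endRegions)

setMethod("show", "SuspectRangeSet", function(object) {
    cat(sprintf(
        "SuspectRangeSet: d = %d bp, offset = %d; %d start / %d end region(s)\n",
        object@suspectRange, object@offset,
        length(object@startRegions), length(object@endRegions)
    ))
})

# TRUE for footprints containing a cut boundary strictly inside, i.e.
# the cut between b and b+1 separates two footprint bases
.spansBoundary <- function(invitrosomes, cutSites) {
    ans <- logical(length(invitrosomes))
    chrom <- as.character(seqnames(invitrosomes))
    for (chr in unique(chrom)) {
        b <- cutSites[[chr]]
        i <- which(chrom == chr)
        if (is.null(b) || !length(b)) next
        b <- sort(b)
        lo <- findInterval(start(invitrosomes)[i] - 1L, b)
        hi <- findInterval(end(invitrosomes)[i] - 1L, b)
        ans[i] <- hi > lo
    }
    ans
}

#' Classify invitrosomes as passed, suspect or inner cut site
#'
#' Three-way, exhaustive and disjoint, evaluated in order:
#' \enumerate{
#'   \item \strong{innercut} -- an own-enzyme cut boundary falls strictly
#'     inside the footprint (an under-digested template: full digestion
#'     would have destroyed this nucleosome's DNA). Independent of the
#'     suspect range by construction.
#'   \item \strong{suspect} -- the footprint start lies in any suspect
#'     start region, or the footprint end in any suspect end region.
#'   \item \strong{passed} -- everything else.
#' }
#' With \code{strict = TRUE} each footprint boundary is additionally
#' tested against the opposite region type (a sensitivity switch; the
#' standard rule matches start to start regions and end to end regions).
#'
#' @param invitrosomes footprint [GenomicRanges::GRanges] from
#'   [callDyads()].
#' @param suspectRanges a [SuspectRangeSet-class] built from the same
#'   enzyme's fragments.
#' @param cutSites the same enzyme's boundaries from [findCutSites()].
#' @param strict also match footprint starts against end regions and vice
#'   versa.
#' @return \code{invitrosomes} with \code{label} filled in
#'   (\code{"passed"}, \code{"suspect"} or \code{"innercut"}).
#' @export
classifyInvitrosomes <- function(invitrosomes, suspectRanges, cutSites,
                                 strict = FALSE) {
    stopifnot(is(suspectRanges, "SuspectRangeSet"))
    chroms <- union(
        seqlevels(startRegions(suspectRanges)), names(cutSites)
    )
    bad <- !(as.character(seqnames(invitrosomes)) %in% chroms)
    if (any(bad)) {
        stop(sprintf(
            "invitrosome chromosome(s) absent from the fragment table: %s",
            paste(unique(as.character(seqnames(invitrosomes))[bad]),
                collapse = ", "
            )
        ))
    }
    inner <- .spansBoundary(invitrosomes, cutSites)
    startPts <- GRanges(
        seqnames(invitrosomes),
        IRanges(start(invitrosomes), width = 1L)
    )
    endPts <- GRanges(
        seqnames(invitrosomes),
        IRanges(end(invitrosomes), width = 1L)
    )
    sus <- overlapsAny(startPts, startRegions(suspectRanges),
        ignore.strand = TRUE
    ) |
        overlapsAny(endPts, endRegions(suspectRanges),
            ignore.strand = TRUE
        )
    if (strict) {
        sus <- sus |
            overlapsAny(startPts, endRegions(suspectRanges),
                ignore.strand = TRUE
            ) |
            overlapsAny(endPts, startRegions(suspectRanges),
                ignore.strand = TRUE
            )
    }
    label <- ifelse(inner, "innercut", ifelse(sus, "suspect", "passed"))
    invitrosomes$label <- label
    invitrosomes
}

#' Recover suspect invitrosomes by cross-library comparison
#'
#' A suspect invitrosome sits near its own library's fragment ends, where
#' end bias could explain it. If the alternate-enzyme library -- whose
#' fragment ends lie elsewhere -- holds a passed or innercut invitrosome
#' at the same position, sequence preference rather than end bias is the
#' parsimonious explanation and the suspect is relabeled
#' \code{"recovered"}; otherwise \code{"biased"}. "Same position" means
#' equal chromosome and dyads within \code{tolerance} bp (default 0,
#' exact; footprint length is fixed, so dyad equality equals
#' footprint-start equality).
#'
#' @param suspect suspect invitrosomes of library A (label
#'   \code{"suspect"}; other labels are passed through unchanged).
#' @param comparison passed plus innercut invitrosomes of library B.
#' @param tolerance maximum dyad distance in bp (>= 0).
#' @return \code{suspect} with labels \code{"recovered"}/\code{"biased"}.
#' @export
crossRecover <- function(suspect, comparison, tolerance = 0L) {
    tolerance <- as.integer(tolerance)
    if (is.na(tolerance) || tolerance < 0L) {
        stop("'tolerance' must be >= 0")
    }
    isSus <- suspect$label == "suspect"
    hit <- logical(length(suspect))
    chromS <- as.character(seqnames(suspect))
    chromC <- as.character(seqnames(comparison))
    for (chr in unique(chromS[isSus])) {
        i <- which(isSus & chromS == chr)
        b <- sort(suspect$dyad[0]) # typed empty
        b <- sort(comparison$dyad[chromC == chr])
        if (!length(b)) next
        lo <- findInterval(suspect$dyad[i] - tolerance - 1L, b)
        hi <- findInterval(suspect$dyad[i] + tolerance, b)
        hit[i] <- hi > lo
    }
    suspect$label[isSus] <- ifelse(hit[isSus], "recovered", "biased")
    suspect
}

#' Assemble recovery sub-libraries
#'
#' \describe{
#'   \item{Raw}{passed + recovered + biased + innercut (everything).}
#'   \item{PreRecovery}{passed only.}
#'   \item{PostRecovery}{passed + recovered + innercut.}
#' }
#'
#' @param invitrosomes footprint [GenomicRanges::GRanges] whose labels are
#'   final (no \code{"unclassified"}/\code{"suspect"} left).
#' @return named list of three [GenomicRanges::GRanges].
#' @export
assembleSublibraries <- function(invitrosomes) {
    lab <- invitrosomes$label
    ok <- c("passed", "recovered", "biased", "innercut")
    if (is.null(lab) || !all(lab %in% ok)) {
        stop(
            "all invitrosomes must carry a final label (passed/recovered/",
            "biased/innercut); run classifyInvitrosomes() and crossRecover()"
        )
    }
    list(
        Raw = invitrosomes,
        PreRecovery = invitrosomes[lab == "passed"],
        PostRecovery = invitrosomes[lab %in%
            c("passed", "recovered", "innercut")]
    )
}

.recoveryCategories <- c(
    "passed", "positionSuspect", "innerCutSite", "allSuspect",
    "recovered", "totalRecovered", "remainingBiased", "postRecovery"
)

#' Recovery accounting report
#'
#' Builds the full accounting from the primary category counts: all
#' suspect = position suspect + inner cut site; total recovered = inner
#' cut site + recovered by comparison; post recovery = passed + total
#' recovered; remaining biased = position suspect - recovered.
#' Percentages are half-up one-decimal fractions of mapped reads (the
#' mapped-read percentage itself is a fraction of total reads). The
#' conservation identities are re-checked on construction and violations
#' raise an error.
#'
#' @param passed,innerCutSite,recovered,biased primary counts; exactly
#'   one of \code{recovered}/\code{biased} may be omitted and is inferred
#'   from \code{mappedReads}.
#' @param mappedReads mapped reads (= classified invitrosomes).
#' @param totalReads sequenced reads; defaults to \code{mappedReads}.
#' @param library,suspectRange bookkeeping fields.
#' @return a [RecoveryReport-class].
#' @examples
#' r <- recoveryReport(
#'     passed = 3529586, innerCutSite = 370753, recovered = 1348245,
#'     mappedReads = 8463490, totalReads = 9489038,
#'     library = "RsaI", suspectRange = 200
#' )
#' reportCounts(r)[["postRecovery"]] # 5248584
#' @export
recoveryReport <- function(passed, innerCutSite, recovered = NULL,
                           biased = NULL, mappedReads,
                           totalReads = mappedReads,
                           library = "library", suspectRange = NA_integer_) {
    positionSuspect <- mappedReads - passed - innerCutSite
    if (is.null(recovered) && is.null(biased)) {
        stop("supply 'recovered' and/or 'biased'")
    }
    if (is.null(recovered)) recovered <- positionSuspect - biased
    if (is.null(biased)) biased <- positionSuspect - recovered
    counts <- c(
        passed = passed,
        positionSuspect = positionSuspect,
        innerCutSite = innerCutSite,
        allSuspect = positionSuspect + innerCutSite,
        recovered = recovered,
        totalRecovered = innerCutSite + recovered,
        remainingBiased = biased,
        postRecovery = passed + innerCutSite + recovered
    )
    if (any(counts < 0)) {
        stop("inconsistent counts: a derived category is negative")
    }
    pct <- roundHalfUp(100 * counts / mappedReads, 1)
    pct <- c(pct, mapped = roundHalfUp(100 * mappedReads / totalReads, 1))
    new("RecoveryReport",
        library = library, suspectRange = as.integer(suspectRange),
        totalReads = as.numeric(totalReads),
        mappedReads = as.numeric(mappedReads),
        counts = counts, percentages = pct
    )
}

#' Tabulate recovery from final labels
#'
#' Counts final labels and delegates to [recoveryReport()]. The mapped
#' read count defaults to the number of labeled invitrosomes; passing a
#' larger value is rejected unless it equals the label count, keeping the
#' conservation identity passed + all suspect = mapped intact.
#'
#' @param invitrosomes labeled footprint [GenomicRanges::GRanges] (or a
#'   character vector of final labels).
#' @param totalReads reads sequenced (for the mapped-percentage row).
#' @param mappedReads optional override; must equal the number of labels.
#' @param library,suspectRange bookkeeping fields.
#' @return a [RecoveryReport-class].
#' @export
tabulateRecovery <- function(invitrosomes, totalReads = NULL,
                             mappedReads = NULL, library = "library",
                             suspectRange = NA_integer_) {
    lab <- if (is.character(invitrosomes)) {
        invitrosomes
    } else {
        invitrosomes$label
    }
    ok <- c("passed", "recovered", "biased", "innercut")
    if (is.null(lab) || !all(lab %in% ok)) {
        stop("labels must all be final (passed/recovered/biased/innercut)")
    }
    n <- length(lab)
    if (is.null(mappedReads)) mappedReads <- n
    if (mappedReads != n) {
        stop(sprintf(
            "mappedReads (%s) does not match the %d labeled invitrosomes",
            format(mappedReads), n
        ))
    }
    if (is.null(totalReads)) totalReads <- mappedReads
    recoveryReport(
        passed = sum(lab == "passed"),
        innerCutSite = sum(lab == "innercut"),
        recovered = sum(lab == "recovered"),
        biased = sum(lab == "biased"),
        mappedReads = mappedReads, totalReads = totalReads,
        library = library, suspectRange = suspectRange
    )
}

#' @describeIn recoveryReport category counts.
#' @param x a [RecoveryReport-class].
#' @export
setMethod("reportCounts", "RecoveryReport", function(x) x@counts)

#' @describeIn recoveryReport category percentages (half-up, one decimal).
#' @export
setMethod("reportPercentages", "RecoveryReport", function(x) x@percentages)

#' Long-format data.frame of a recovery report
#' @param x a [RecoveryReport-class].
#' @param row.names,optional,... ignored; S3 compatibility.
#' @return a data.frame with one row per category.
#' @exportS3Method base::as.data.frame
as.data.frame.RecoveryReport <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(
        library = x@library,
        suspectRange = x@suspectRange,
        category = c("totalReads", "mappedReads", .recoveryCategories),
        count = c(x@totalReads, x@mappedReads, unname(x@counts)),
        percent = c(
            NA, x@percentages[["mapped"]],
            unname(x@percentages[.recoveryCategories])
        )
    )
}

setMethod("show", "RecoveryReport", function(object) {
    cat(sprintf(
        "RecoveryReport: %s at %d-bp suspect range\n",
        object@library, object@suspectRange
    ))
    df <- as.data.frame(object)
    df$count <- format(df$count, big.mark = ",", trim = TRUE)
    print(df, row.names = FALSE)
})

#' Write recovery reports as TSV and JSON
#'
#' @param reports a [RecoveryReport-class] or list of them.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return the two paths, invisibly.
#' @export
writeRecoveryReport <- function(reports, prefix) {
    if (is(reports, "RecoveryReport")) reports <- list(reports)
    df <- do.call(rbind, lapply(reports, as.data.frame))
    tsv <- paste0(prefix, ".tsv")
    .writeTsv(df, tsv)
    js <- paste0(prefix, ".json")
    payload <- lapply(reports, function(r) {
        list(
            library = r@library,
            suspectRange = r@suspectRange,
            totalReads = r@totalReads,
            mappedReads = r@mappedReads,
            counts = as.list(r@counts),
            percentages = as.list(r@percentages)
        )
    })
    write_json(payload, js, auto_unbox = TRUE, digits = NA)
    invisible(c(tsv, js))
}
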