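#' @include utils.R
NULL

.IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' EnzymeDef: a blunt-cutting palindromic type II restriction enzyme
#'
#' Holds an IUPAC recognition pattern and the blunt cut offset (bases from
#' the first recognition base to the cut boundary). Only palindromic
#' patterns (equal to their IUPAC reverse complement) with a central blunt
#' cut are accepted; overhang-producing enzymes are rejected rather than
#' mis-modeled.
#'
#' @slot name enzyme name.
#' @slot recognition IUPAC recognition string, e.g. \code{"GTAC"}.
#' @slot cutOffset integer, bases before the cut; blunt cutters have
#'   \code{cutOffset == nchar(recognition)/2}.
#'
#' @seealso [restrictionEnzyme()], [builtinEnzyme()], [findCutSites()]
#' @exportClass EnzymeDef
setClass("EnzymeDef",
    representation(
        name = "character",
        recognition = "character",
        cutOffset = "integer"
    )
)

setValidity("EnzymeDef", function(object) {
    msg <- character(0)
    rec <- object@recognition
    if (length(rec) != 1L || !nzchar(rec)) {
        return("recognition must be a single non-empty string")
    }
    letters <- strsplit(rec, "")[[1]]
    if (!all(letters %in% names(.IUPAC_SETS))) {
        msg <- c(msg, "recognition contains non-IUPAC characters")
    } else {
        rc <- as.character(reverseComplement(DNAString(rec)))
        if (rc != rec) {
            msg <- c(msg, sprintf(
                "recognition '%s' is not palindromic under IUPAC reverse complement (revcomp is '%s'); non-palindromic enzymes are not supported",
                rec, rc
            ))
        }
    }
    off <- object@cutOffset
    n <- nchar(rec)
    if (length(off) != 1L || is.na(off) || off <= 0L || off >= n) {
        msg <- c(msg, "cutOffset must lie strictly inside the recognition site")
    } else if (n %% 2L != 0L || off != n %/% 2L) {
        msg <- c(msg, sprintf(
            "cut at offset %d of a %d-bp site leaves an overhang; only blunt cutters (offset = length/2) are supported",
            off, n
        ))
    }
    if (length(msg)) msg else TRUE
})

#' FragmentTable: restriction fragments of a genome
#'
#' Fragments tile each chromosome exactly (chromosome termini count as
#' fragment ends). An optional minimum-length filter moves short fragments
#' to a side list: they are excluded from end-bias profiles and
#' suspect-range construction but retained because the recovery logic
#' depends on knowing these loci exist.
#'
#' @slot fragments [GenomicRanges::GRanges] of retained fragments.
#' @slot removed [GenomicRanges::GRanges] of fragments dropped by the
#'   minimum-length filter (empty when no filter applied).
#' @slot minLength integer filter threshold, or \code{NA} when unfiltered.
#' @slot enzyme name of the digesting enzyme (informational).
#'
#' @seealso [buildFragmentTable()], [digestionStats()]
#' @exportClass FragmentTable
setClass("FragmentTable",
    representation(
        fragments = "GRanges",
        removed = "GRanges",
        minLength = "integer",
        enzyme = "character"
    )
)

setValidity("FragmentTable", function(object) {
    msg <- character(0)
    if (length(object@minLength) == 1L && !is.na(object@minLength)) {
        if (length(object@fragments) &&
            any(width(object@fragments) < object@minLength)) {
            msg <- c(msg, "retained fragments shorter than minLength")
        }
        if (length(object@removed) &&
            any(width(object@removed) >= object@minLength)) {
            msg <- c(msg, "removed fragments not shorter than minLength")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SuspectRangeSet: end-proximal suspect regions of a fragment table
#'
#' For every retained fragment, the start region covers the first
#' \code{suspectRange} bases after an optional residual half-site offset,
#' and the end region the mirrored final bases. Regions are clipped to
#' their fragment, so short fragments can be entirely suspect.
#'
#' @slot startRegions [GenomicRanges::GRanges] of per-fragment start regions.
#' @slot endRegions [GenomicRanges::GRanges] of per-fragment end regions.
#' @slot suspectRange integer suspect distance d in bp.
#' @slot offset integer residual half-site offset used.
#'
#' @seealso [buildSuspectRanges()], [classifyInvitrosomes()]
#' @exportClass SuspectRangeSet
setClass("SuspectRangeSet",
    representation(
        startRegions = "GRanges",
        endRegions = "GRanges",
        suspectRange = "integer",
        offset = "integer"
    )
)

#' EndBiasProfile: per-position enrichment at fragment ends
#'
#' Values for positions 1..window counted inward from fragment termini
#' (position 1 is the terminal fragment base), aggregated symmetrically
#' over left and right fragment ends. Metric \code{"start_ratio"} divides
#' per-position invitrosome start counts by all starts in the library;
#' \code{"normalized_occupancy"} is RPKM-scaled start coverage divided by
#' its mean over the window (mean 1 by construction).
#'
#' @slot library library name.
#' @slot cutsiteSet name of the enzyme whose fragment ends are interrogated.
#' @slot metric \code{"start_ratio"} or \code{"normalized_occupancy"}.
#' @slot window integer number of positions (default 73).
#' @slot values numeric vector of length \code{window}.
#' @slot counts raw per-position start counts backing \code{values}.
#' @slot nTotalStarts total mapped starts in the library.
#' @slot offset residual half-site offset used when counting positions.
#'
#' @seealso [startRatioProfile()], [occupancyProfile()],
#'   [enrichmentAtPosition()]
#' @exportClass EndBiasProfile
setClass("EndBiasProfile",
    representation(
        library = "character",
        cutsiteSet = "character",
        metric = "character",
        window = "integer",
        values = "numeric",
        counts = "numeric",
        nTotalStarts = "integer",
        offset = "integer"
    )
)

setValidity("EndBiasProfile", function(object) {
    msg <- character(0)
    if (!object@metric %in% c("start_ratio", "normalized_occupancy")) {
        msg <- c(msg, "unknown metric")
    }
    if (length(object@values) != object@window) {
        msg <- c(msg, "values length must equal window")
    }
    if (object@metric == "start_ratio" &&
        length(object@values) && any(object@values < 0 | object@values > 1)) {
        msg <- c(msg, "start_ratio values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' KmerMatrix: position-specific k-mer frequencies of footprint sequences
#'
#' Frequency of each of the 4^k k-mers at each k-mer start position along
#' equal-length (typically 147-nt) footprint sequences. Windows containing
#' N are excluded from both the numerator and that position's denominator,
#' so each column sums to 1 wherever any valid window exists.
#'
#' @slot k k-mer length.
#' @slot library library or sub-library name.
#' @slot counts integer matrix, 4^k k-mers x positions.
#' @slot freq column-normalized frequency matrix.
#' @slot nSequences number of sequences used.
#'
#' @seealso [positionKmerMatrix()], [correlateKmerMatrices()]
#' @exportClass KmerMatrix
setClass("KmerMatrix",
    representation(
        k = "integer",
        library = "character",
        counts = "matrix",
        freq = "matrix",
        nSequences = "integer"
    )
)

#' RecoveryReport: accounting of the dual-enzyme recovery method
#'
#' Absolute counts and one-decimal percentages for one library at one
#' suspect range, mirroring the published accounting: passed, all suspect
#' (position suspect + inner cut site), inner cut site, recovered by
#' comparison, total recovered (inner cut + comparison), remaining biased,
#' and post recovery (passed + total recovered). All percentages use
#' mapped reads as denominator except the mapped-read percentage itself,
#' which uses total reads.
#'
#' @slot library library name.
#' @slot suspectRange suspect distance d in bp.
#' @slot totalReads reads sequenced.
#' @slot mappedReads reads mapped (= classified invitrosomes).
#' @slot counts named numeric vector of category counts.
#' @slot percentages named numeric vector of half-up one-decimal percentages.
#'
#' @seealso [tabulateRecovery()], [recoveryReport()]
#' @exportClass RecoveryReport
setClass("RecoveryReport",
    representation(
        library = "character",
        suspectRange = "integer",
        totalReads = "numeric",
        mappedReads = "numeric",
        counts = "numeric",
        percentages = "numeric"
    )
)

setValidity("RecoveryReport", function(object) {
    cts <- object@counts
    need <- c(
        "passed", "positionSuspect", "innerCutSite", "allSuspect",
        "recovered", "totalRecovered", "remainingBiased", "postRecovery"
    )
    if (!all(need %in% names(cts))) {
        return(paste("counts must contain:", paste(need, collapse = ", ")))
    }
    msg <- character(0)
    m <- object@mappedReads
    if (cts[["allSuspect"]] !=
        cts[["positionSuspect"]] + cts[["innerCutSite"]]) {
        msg <- c(msg, "allSuspect != positionSuspect + innerCutSite")
    }
    if (cts[["passed"]] + cts[["allSuspect"]] != m) {
        msg <- c(msg, "passed + allSuspect != mappedReads")
    }
    if (cts[["recovered"]] + cts[["remainingBiased"]] !=
        cts[["positionSuspect"]]) {
        msg <- c(msg, "recovered + remainingBiased != positionSuspect")
    }
    if (cts[["totalRecovered"]] !=
        cts[["innerCutSite"]] + cts[["recovered"]]) {
        msg <- c(msg, "totalRecovered != innerCutSite + recovered")
    }
    if (cts[["postRecovery"]] + cts[["remainingBiased"]] != m) {
        msg <- c(msg, "postRecovery + remainingBiased != mappedReads")
    }
    if (length(msg)) msg else TRUE
})
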