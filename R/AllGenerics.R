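#' @include AllClasses.R
NULL

#' Retained fragments of a FragmentTable
#' @param x a [FragmentTable-class].
#' @return a [GenomicRanges::GRanges].
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Fragments removed by the minimum-length filter
#' @param x a [FragmentTable-class].
#' @return a [GenomicRanges::GRanges].
#' @export
setGeneric("removedFragments",
    function(x) standardGeneric("removedFragments"))

#' All fragments, retained and removed, in genomic order
#' @param x a [FragmentTable-class].
#' @return a [GenomicRanges::GRanges].
#' @export
setGeneric("allFragments", function(x) standardGeneric("allFragments"))

#' Suspect start regions
#' @param x a [SuspectRangeSet-class].
#' @return a [GenomicRanges::GRanges].
#' @export
setGeneric("startRegions", function(x) standardGeneric("startRegions"))

#' Suspect end regions
#' @param x a [SuspectRangeSet-class].
#' @return a [GenomicRanges::GRanges].
#' @export
setGeneric("endRegions", function(x) standardGeneric("endRegions"))

#' Per-position values of an end-bias profile
#' @param x an [EndBiasProfile-class].
#' @return numeric vector, one value per position 1..window.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Position-specific k-mer frequency matrix
#' @param x a [KmerMatrix-class].
#' @return numeric matrix, 4^k k-mers x positions; columns sum to 1.
#' @export
setGeneric("kmerFrequencies",
    function(x) standardGeneric("kmerFrequencies"))

#' Position-specific k-mer count matrix
#' @param x a [KmerMatrix-class].
#' @return integer matrix, 4^k k-mers x positions.
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' Category counts of a recovery report
#' @param x a [RecoveryReport-class].
#' @return named numeric vector of counts.
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

#' Category percentages of a recovery report
#' @param x a [RecoveryReport-class].
#' @return named numeric vector of half-up one-decimal percentages.
#' @export
setGeneric("reportPercentages",
    function(x) standardGeneric("reportPercentages"))
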