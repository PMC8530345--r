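#' Round half up
#'
#' Base R's \code{round()} rounds half to even; published tables in this
#' field round half up. Used for all report percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded half-up to \code{digits} decimals.
#' @examples
#' roundHalfUp(c(0.25, 0.35), 1)
#' @export
roundHalfUp <- function(x, digits = 1) {
    scale <- 10^digits
    sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# set.seed only when the caller supplied one; keeps library calls
# composable with an outer set.seed()
.maybeSeed <- function(seed) {
    if (!is.null(seed)) {
        stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
        set.seed(as.integer(seed))
    }
    invisible(NULL)
}

# first whitespace-delimited token of FASTA headers
.cleanSeqNames <- function(x) {
    vapply(strsplit(x, "[ \t]"), `[[`, character(1), 1L)
}

#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to their first token and uppercases the sequence (soft-masked
#' lowercase bases are treated as ordinary bases; hard-masked regions must
#' be N).
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
readGenome <- function(path) {
    dss <- readDNAStringSet(path)
    names(dss) <- .cleanSeqNames(names(dss))
    # DNAStringSet stores lowercase; normalize once here
    DNAStringSet(toupper(dss))
}

.checkGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L) {
        genome <- readGenome(genome)
    }
    if (!is(genome, "DNAStringSet")) {
        stop("'genome' must be a DNAStringSet or a FASTA file path")
    }
    if (is.null(names(genome)) || anyDuplicated(names(genome))) {
        stop("genome sequences must carry unique names")
    }
    genome
}

# named integer vector of chromosome lengths from a DNAStringSet
.genomeSeqlengths <- function(genome) {
    setNames(width(genome), names(genome))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
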