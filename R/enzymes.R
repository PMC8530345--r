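#' @include AllGenerics.R
NULL

#' Define a restriction enzyme
#'
#' Constructs an [EnzymeDef-class] for a blunt-cutting palindromic type II
#' restriction enzyme. The recognition string may use IUPAC degenerate
#' codes; it must equal its own IUPAC reverse complement, and the cut must
#' fall at the center of the site (blunt). Anything else is rejected,
#' because cut-boundary arithmetic is undefined for overhangs and
#' non-palindromes.
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition string, e.g. \code{"GTAC"}.
#' @param cutOffset bases from the first recognition base to the cut;
#'   defaults to the blunt center.
#' @return an [EnzymeDef-class].
#' @examples
#' restrictionEnzyme("RsaI", "GTAC")
#' restrictionEnzyme("HincII", "GTYRAC")
#' @export
restrictionEnzyme <- function(name, recognition,
                              cutOffset = nchar(recognition) %/% 2L) {
    new("EnzymeDef",
        name = as.character(name),
        recognition = toupper(as.character(recognition)),
        cutOffset = as.integer(cutOffset)
    )
}

#' Built-in enzymes
#'
#' The two enzymes used throughout: RsaI (GT^AC) and HincII (GTY^RAC).
#'
#' @return named list of [EnzymeDef-class] objects.
#' @examples
#' builtinEnzymes()
#' @export
builtinEnzymes <- function() {
    list(
        RsaI = restrictionEnzyme("RsaI", "GTAC", 2L),
        HincII = restrictionEnzyme("HincII", "GTYRAC", 3L)
    )
}

#' @rdname builtinEnzymes
#' @param name \code{"RsaI"} or \code{"HincII"} (case-insensitive).
#' @export
builtinEnzyme <- function(name) {
    enz <- builtinEnzymes()
    hit <- match(tolower(name), tolower(names(enz)))
    if (is.na(hit)) {
        stop(sprintf(
            "unknown built-in enzyme '%s'; use restrictionEnzyme() for custom patterns",
            name
        ))
    }
    enz[[hit]]
}

# accept an EnzymeDef, a built-in name, or "custom:PATTERN"
.asEnzyme <- function(enzyme) {
    if (is(enzyme, "EnzymeDef")) return(enzyme)
    if (is.character(enzyme) && length(enzyme) == 1L) {
        if (grepl("^custom:", enzyme)) {
            pat <- sub("^custom:", "", enzyme)
            return(restrictionEnzyme(paste0("custom_", pat), pat))
        }
        return(builtinEnzyme(enzyme))
    }
    stop("'enzyme' must be an EnzymeDef or an enzyme name")
}

#' Locate restriction cut sites in a genome
#'
#' Scans the forward strand of each sequence for the enzyme's IUPAC
#' recognition pattern (case-insensitive; the genome is uppercased on
#' import) and returns the blunt cut boundaries. A boundary value of
#' \code{b} means the enzyme cuts between positions \code{b} and
#' \code{b + 1} (1-based), i.e. \code{b} bases lie to the left of the cut.
#' Because only palindromic sites are allowed, the forward-strand scan
#' finds every site; windows containing N never match, so repeat-masked
#' regions produce no boundaries. Overlapping matches are all reported.
#' Boundaries coinciding with a chromosome terminus (possible only for
#' degenerate custom patterns) are dropped, as they cut nothing.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param enzyme an [EnzymeDef-class], a built-in name, or
#'   \code{"custom:PATTERN"}.
#' @return an [IRanges::IntegerList] of strictly increasing boundaries,
#'   one element per chromosome.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "GGTACC"))
#' findCutSites(g, "RsaI") # boundary 3: GGT | ACC
#' @export
findCutSites <- function(genome, enzyme) {
    genome <- .checkGenome(genome)
    enzyme <- .asEnzyme(enzyme)
    validObject(enzyme)
    res <- lapply(seq_along(genome), function(i) {
        m <- matchPattern(enzyme@recognition, genome[[i]],
            fixed = "subject"
        )
        b <- start(m) - 1L + enzyme@cutOffset
        b <- sort(unique(b))
        b[b >= 1L & b <= length(genome[[i]]) - 1L]
    })
    names(res) <- names(genome)
    ans <- IntegerList(res)
    metadata(ans) <- list(
        enzyme = enzyme@name,
        recognition = enzyme@recognition,
        cutOffset = enzyme@cutOffset,
        seqlengths = .genomeSeqlengths(genome)
    )
    ans
}

#' Export cut sites as BED3
#'
#' Writes each cut boundary as a zero-length BED feature at the boundary
#' (BED start = boundary, BED end = boundary), the conventional encoding
#' of an inter-base position.
#'
#' @param cutSites an [IRanges::IntegerList] from [findCutSites()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportCutSites <- function(cutSites, path) {
    chrom <- rep(names(cutSites), lengths(cutSites))
    b <- unlist(cutSites, use.names = FALSE)
    df <- data.frame(
        chrom = chrom,
        start = if (length(b)) b else integer(0),
        end = if (length(b)) b else integer(0)
    )
    write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

setMethod("show", "EnzymeDef", function(object) {
    rec <- object@recognition
    cat(sprintf(
        "EnzymeDef %s: %s^%s (blunt, %d-bp site)\n",
        object@name,
        substr(rec, 1L, object@cutOffset),
        substr(rec, object@cutOffset + 1L, nchar(rec)),
        nchar(rec)
    ))
})
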