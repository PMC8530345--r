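#' @include fragments.R
NULL

#' Import read 5' positions from BAM or BED6
#'
#' Reduces single-end alignments to the genomic position of the first
#' (5'-most in read orientation) base: the leftmost aligned base for plus
#' reads and the rightmost for minus reads. Unmapped and unstranded
#' records are dropped.
#'
#' @param path a BAM file (uses alignment flags) or BED6 file of read
#'   intervals.
#' @param format \code{"bam"} or \code{"bed"}; guessed from the extension
#'   by default.
#' @return a [GenomicRanges::GRanges] of width-1 5' positions with strand.
#' @export
importReadStarts <- function(path, format = c("auto", "bam", "bed")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
            "bam"
        } else {
            "bed"
        }
    }
    if (format == "bam") {
        p <- ScanBamParam(
            what = c("rname", "pos", "strand", "qwidth"),
            flag = scanBamFlag(isUnmappedQuery = FALSE)
        )
        b <- scanBam(path, param = p)[[1]]
        keep <- b$strand %in% c("+", "-")
        five <- ifelse(b$strand[keep] == "+",
            b$pos[keep],
            b$pos[keep] + b$qwidth[keep] - 1L
        )
        gr <- GRanges(b$rname[keep], IRanges(five, width = 1L),
            strand = b$strand[keep]
        )
    } else {
        gr <- import(path, format = "BED")
        gr <- gr[strand(gr) %in% c("+", "-")]
        gr <- resize(gr, width = 1L, fix = "start")
        mcols(gr) <- NULL
    }
    gr
}

#' Call invitrosome dyads and footprints from read 5' positions
#'
#' Each single-end read stands for one invitrosome: the read 5' base marks
#' one end of the 147-bp footprint, so the dyad sits
#' \code{(footprint - 1)/2} bases inward -- downstream for plus reads,
#' upstream for minus reads. The two reads flanking the same nucleosome
#' therefore map to the same dyad. Footprints extending past a chromosome
#' boundary are dropped and counted in
#' \code{metadata()$droppedAtBoundary}; per-strand input counts are kept
#' in the metadata so the strand interpretation is auditable. Duplicate
#' reads are retained (the accounting counts reads, not unique positions).
#'
#' @param reads a [GenomicRanges::GRanges] with strand \code{+}/\code{-}
#'   (any widths; the 5' pole is used), or a BAM/BED6 path.
#' @param footprint odd footprint length in bp, default 147.
#' @param seqlengths named chromosome lengths; taken from
#'   \code{seqlengths(reads)} when present. Without lengths only the left
#'   boundary can be enforced.
#' @param library library name stored on each invitrosome.
#' @return a [GenomicRanges::GRanges] of footprints with metadata columns
#'   \code{dyad}, \code{library} and \code{label} (\code{"unclassified"}),
#'   strand preserved from the originating read.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, width = 1),
#'     strand = "+")
#' callDyads(r, seqlengths = c(chr1 = 5000L))
#' @export
callDyads <- function(reads, footprint = 147L, seqlengths = NULL,
                      library = "library") {
    if (is.character(reads)) reads <- importReadStarts(reads)
    stopifnot(is(reads, "GRanges"))
    footprint <- as.integer(footprint)
    if (footprint <= 0L || footprint %% 2L == 0L) {
        stop("'footprint' must be odd and positive")
    }
    str <- as.character(strand(reads))
    if (any(str == "*")) stop("reads with unknown strand ('*') not allowed")
    if (is.null(seqlengths)) seqlengths <- seqlengths(reads)
    half <- (footprint - 1L) %/% 2L
    five <- ifelse(str == "+", start(reads), end(reads))
    dyad <- ifelse(str == "+", five + half, five - half)
    fpStart <- dyad - half
    fpEnd <- dyad + half
    chrom <- as.character(seqnames(reads))
    lens <- seqlengths[chrom]
    ok <- fpStart >= 1L
    known <- !is.na(lens)
    ok[known] <- ok[known] & fpEnd[known] <= lens[known]
    nOK <- sum(ok)
    out <- GRanges(chrom[ok], IRanges(fpStart[ok], fpEnd[ok]),
        strand = str[ok],
        dyad = as.integer(dyad[ok]),
        library = rep(as.character(library), nOK),
        label = rep("unclassified", nOK)
    )
    if (!all(is.na(seqlengths))) {
        sl <- seqlengths[!is.na(seqlengths)]
        seqlevels(out) <- union(seqlevels(out), names(sl))
        seqlengths(out)[names(sl)] <- sl
    }
    metadata(out) <- list(
        nReads = length(reads),
        droppedAtBoundary = sum(!ok),
        strandCounts = c(
            plus = sum(str == "+"),
            minus = sum(str == "-")
        ),
        footprint = footprint
    )
    out
}

#' Extract footprint DNA sequences
#'
#' Returns the forward-genomic-strand sequence of each footprint,
#' regardless of the strand of the read that called it (both reads of a
#' nucleosome describe the same duplex). Sequences may contain N where
#' footprints overlap masked regions; position-based k-mer counting
#' excludes such windows downstream.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param invitrosomes footprint [GenomicRanges::GRanges] from
#'   [callDyads()].
#' @return a [Biostrings::DNAStringSet], one sequence per invitrosome.
#' @export
extractFootprints <- function(genome, invitrosomes) {
    genome <- .checkGenome(genome)
    chrom <- as.character(seqnames(invitrosomes))
    bad <- !(chrom %in% names(genome))
    if (any(bad)) {
        stop(sprintf(
            "invitrosome chromosome(s) absent from genome: %s",
            paste(unique(chrom[bad]), collapse = ", ")
        ))
    }
    lens <- .genomeSeqlengths(genome)[chrom]
    if (any(start(invitrosomes) < 1L) || any(end(invitrosomes) > lens)) {
        stop("footprint outside chromosome bounds")
    }
    out <- vector("list", length(genome))
    idx <- split(seq_along(invitrosomes), factor(chrom, names(genome)))
    res <- DNAStringSet(rep("", length(invitrosomes)))
    for (chr in names(genome)) {
        i <- idx[[chr]]
        if (!length(i)) next
        res[i] <- extractAt(genome[[chr]], ranges(invitrosomes)[i])
    }
    names(res) <- NULL
    res
}

#' Export invitrosomes as BED6
#'
#' @param invitrosomes footprint [GenomicRanges::GRanges].
#' @param path output file.
#' @param what \code{"footprints"} (147-bp intervals) or \code{"dyads"}
#'   (width-1 dyad positions). The BED name column carries the library,
#'   score is 0, strand is the calling read's strand.
#' @return the path, invisibly.
#' @export
exportInvitrosomes <- function(invitrosomes, path,
                               what = c("footprints", "dyads")) {
    what <- match.arg(what)
    if (what == "dyads") {
        st <- invitrosomes$dyad
        en <- invitrosomes$dyad
    } else {
        st <- start(invitrosomes)
        en <- end(invitrosomes)
    }
    df <- data.frame(
        chrom = as.character(seqnames(invitrosomes)),
        start = st - 1L,
        end = en,
        name = if (length(invitrosomes)) invitrosomes$library else
            character(0),
        score = if (length(invitrosomes)) 0L else integer(0),
        strand = as.character(strand(invitrosomes))
    )
    write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}
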