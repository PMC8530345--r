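#' @include simulate.R
NULL

.pipelineDefaults <- function() {
    list(
        seed = 1L,
        suspectRanges = c(200L, 11L, 1L),
        tolerance = 0L,
        offset = 0L,
        footprint = 147L,
        window = 73L,
        kmer = list(k = 4L, ends = 7L)
    )
}

.mergeConfig <- function(config) {
    def <- .pipelineDefaults()
    for (nm in names(def)) {
        if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
    }
    if (is.null(config$kmer$k)) config$kmer$k <- 4L
    if (is.null(config$kmer$ends)) config$kmer$ends <- 7L
    if (is.null(config$kmer$suspectRange)) {
        config$kmer$suspectRange <- min(config$suspectRanges)
    }
    config
}

.stageGenome <- function(config) {
    g <- config$genome
    if (!is.null(g$fasta)) {
        return(readGenome(g$fasta))
    }
    if (!is.null(g$simulate)) {
        s <- g$simulate
        return(simulateGenome(
            length = s$length,
            gc = if (is.null(s$gc)) 0.36 else s$gc,
            maskedFraction = if (is.null(s$maskedFraction)) 0 else
                s$maskedFraction,
            seed = config$seed
        ))
    }
    stop("config$genome must provide 'fasta' or 'simulate'")
}

.stageLibrary <- function(name, libConf, genome, config, seedOffset) {
    seed <- config$seed + seedOffset
    if (!is.null(libConf$bed)) {
        reads <- importReadStarts(libConf$bed)
        return(list(reads = reads, library = name))
    }
    type <- libConf$type
    n <- libConf$n
    if (is.null(type) || is.null(n)) {
        stop(sprintf("library '%s' needs 'type' and 'n' (or 'bed')", name))
    }
    switch(type,
        enzyme_digest = simulateEnzymeLibrary(
            genome, libConf$enzyme, n,
            beta = if (is.null(libConf$beta)) 1 else libConf$beta,
            biasWidth = if (is.null(libConf$biasWidth)) 1L else
                libConf$biasWidth,
            footprint = config$footprint, seed = seed, library = name
        ),
        sheared = simulateShearedLibrary(
            genome, n,
            sizeRange = if (is.null(libConf$sizeRange)) c(600L, 800L) else
                unlist(libConf$sizeRange),
            beta = if (is.null(libConf$beta)) 1 else libConf$beta,
            biasWidth = if (is.null(libConf$biasWidth)) 1L else
                libConf$biasWidth,
            footprint = config$footprint, seed = seed, library = name
        ),
        uniform = simulateUniformLibrary(
            genome, n,
            errorRate = if (is.null(libConf$errorRate)) 0 else
                libConf$errorRate,
            seed = seed, library = name
        ),
        stop(sprintf("unknown library type '%s'", type))
    )
}

#' Run the complete end-bias and recovery workflow
#'
#' Orchestrates digestion, dyad calling, classification, dual-enzyme
#' recovery, accounting, end-bias profiling, k-mer composition and the
#' correlation report, writing all results as BED/TSV/JSON under
#' \code{outDir}. Every stage is a plain package function, so any
#' intermediate can be re-run by hand. With fewer than two enzyme
#' libraries, recovery is skipped with a warning and the remaining
#' analyses still run. Outputs are a function of (inputs, config, seed)
#' only.
#'
#' @param config a YAML file path or a nested list with elements
#'   \code{genome} (either \code{fasta} or \code{simulate = list(length,
#'   gc, maskedFraction)}), \code{enzymes} (character vector of enzyme
#'   names to digest with), \code{libraries} (named list; each either
#'   \code{bed = path} or \code{type =
#'   "enzyme_digest"/"sheared"/"uniform"} plus \code{n} and type-specific
#'   fields; an \code{enzyme_digest} library's \code{enzyme} ties it to a
#'   cut site set for recovery), and optional \code{seed},
#'   \code{suspectRanges} (default 200, 11, 1), \code{tolerance},
#'   \code{offset}, \code{kmer = list(k, ends, suspectRange)}.
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with the genome, fragment tables,
#'   invitrosome sets, per-d labeled sets and reports, profiles, k-mer
#'   matrices, correlation tables and the manifest.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L) {
        config <- read_yaml(config)
    }
    config <- .mergeConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("stage '%s' failed: %s", name,
                conditionMessage(e)), call. = FALSE)
        })
    }
    files <- character(0)
    note <- function(path) files <<- c(files, path)

    genome <- stage("genome", .stageGenome(config))
    seqlens <- .genomeSeqlengths(genome)

    enzymes <- config$enzymes
    if (is.null(enzymes)) {
        enzymes <- unique(unlist(lapply(
            config$libraries, `[[`, "enzyme"
        )))
    }
    digests <- stage("digest", {
        out <- list()
        for (enz in enzymes) {
            cs <- findCutSites(genome, enz)
            ft <- buildFragmentTable(cs,
                minLength = config$footprint,
                enzyme = .asEnzyme(enz)@name
            )
            p1 <- file.path(outDir, sprintf("%s.cutsites.bed", enz))
            p2 <- file.path(outDir, sprintf("%s.fragments.bed", enz))
            p3 <- file.path(outDir, sprintf("%s.fragments.tsv", enz))
            exportCutSites(cs, p1)
            exportFragments(ft, p2, format = "bed", which = "retained")
            exportFragments(ft, p3, format = "tsv", which = "all")
            note(c(p1, p2, p3))
            out[[enz]] <- list(cutSites = cs, fragmentTable = ft)
        }
        out
    })

    libs <- stage("libraries", {
        out <- list()
        i <- 0L
        for (nm in names(config$libraries)) {
            i <- i + 1L
            out[[nm]] <- .stageLibrary(
                nm, config$libraries[[nm]], genome, config, 1000L + i
            )
        }
        out
    })

    invitro <- stage("dyads", {
        out <- list()
        for (nm in names(libs)) {
            inv <- callDyads(libs[[nm]]$reads,
                footprint = config$footprint,
                seqlengths = seqlens, library = nm
            )
            p <- file.path(outDir, sprintf("%s.dyads.bed", nm))
            exportInvitrosomes(inv, p, what = "dyads")
            note(p)
            out[[nm]] <- inv
        }
        out
    })

    enzymeOf <- vapply(names(libs), function(nm) {
        e <- config$libraries[[nm]]$enzyme
        if (is.null(e)) NA_character_ else e
    }, character(1))
    enzLibs <- names(libs)[!is.na(enzymeOf)]
    refLibs <- names(libs)[is.na(enzymeOf)]

    recovery <- NULL
    if (length(enzLibs) >= 2L) {
        recovery <- stage("recovery", {
            a <- enzLibs[1]
            b <- enzLibs[2]
            perD <- list()
            for (d in config$suspectRanges) {
                labeled <- list()
                for (pair in list(c(a, b), c(b, a))) {
                    own <- pair[1]
                    alt <- pair[2]
                    dOwn <- digests[[enzymeOf[[own]]]]
                    dAlt <- digests[[enzymeOf[[alt]]]]
                    srOwn <- buildSuspectRanges(
                        dOwn$fragmentTable, d, config$offset
                    )
                    srAlt <- buildSuspectRanges(
                        dAlt$fragmentTable, d, config$offset
                    )
                    cls <- classifyInvitrosomes(
                        invitro[[own]], srOwn, dOwn$cutSites
                    )
                    clsAlt <- classifyInvitrosomes(
                        invitro[[alt]], srAlt, dAlt$cutSites
                    )
                    comparison <- clsAlt[clsAlt$label %in%
                        c("passed", "innercut")]
                    labeled[[own]] <- crossRecover(
                        cls, comparison, config$tolerance
                    )
                }
                reports <- list()
                subs <- list()
                for (nm in c(a, b)) {
                    lv <- labeled[[nm]]
                    for (lab in c(
                        "passed", "innercut", "recovered", "biased"
                    )) {
                        p <- file.path(outDir, sprintf(
                            "%s.d%d.%s.bed", nm, d, lab
                        ))
                        exportInvitrosomes(lv[lv$label == lab], p)
                        note(p)
                    }
                    reports[[nm]] <- tabulateRecovery(
                        lv,
                        totalReads = metadata(invitro[[nm]])$nReads,
                        library = nm, suspectRange = d
                    )
                    subs[[nm]] <- assembleSublibraries(lv)
                }
                pre <- file.path(outDir, sprintf("recovery.d%d", d))
                note(writeRecoveryReport(reports, pre))
                perD[[as.character(d)]] <- list(
                    labeled = labeled, reports = reports,
                    sublibraries = subs
                )
            }
            perD
        })
    } else {
        warning(
            "fewer than two enzyme-digest libraries: recovery skipped"
        )
    }

    profiles <- stage("endbias", {
        out <- list()
        for (nm in names(invitro)) {
            for (enz in names(digests)) {
                for (metric in c("ratio", "occupancy")) {
                    fun <- if (metric == "ratio") {
                        startRatioProfile
                    } else {
                        occupancyProfile
                    }
                    pr <- fun(
                        invitro[[nm]], digests[[enz]]$fragmentTable,
                        offset = config$offset, window = config$window,
                        library = nm, cutsiteSet = enz
                    )
                    p <- file.path(outDir, sprintf(
                        "endbias.%s.at_%s.%s.tsv", nm, enz, metric
                    ))
                    writeProfileTsv(pr, p)
                    note(p)
                    out[[sprintf("%s|%s|%s", nm, enz, metric)]] <- pr
                }
            }
        }
        out
    })

    kmers <- stage("kmer", {
        kk <- config$kmer$k
        dK <- config$kmer$suspectRange
        subMatrices <- list()
        if (!is.null(recovery)) {
            subs <- recovery[[as.character(dK)]]$sublibraries
            for (nm in names(subs)) {
                subMatrices[[nm]] <- list(
                    Raw = positionKmerMatrix(
                        extractFootprints(genome, subs[[nm]]$Raw),
                        k = kk, library = paste0(nm, ".Raw")
                    ),
                    Passed = positionKmerMatrix(
                        extractFootprints(genome, subs[[nm]]$PreRecovery),
                        k = kk, library = paste0(nm, ".Passed")
                    ),
                    PostRecovery = positionKmerMatrix(
                        extractFootprints(
                            genome, subs[[nm]]$PostRecovery
                        ),
                        k = kk, library = paste0(nm, ".PostRecovery")
                    )
                )
            }
        }
        refMatrices <- list()
        for (nm in refLibs) {
            refMatrices[[nm]] <- positionKmerMatrix(
                extractFootprints(genome, invitro[[nm]]),
                k = kk, library = nm
            )
        }
        for (nm in names(subMatrices)) {
            for (sub in names(subMatrices[[nm]])) {
                p <- file.path(outDir, sprintf(
                    "kmer.%s.%s.tsv", nm, sub
                ))
                writeKmerMatrixTsv(subMatrices[[nm]][[sub]], p)
                note(p)
            }
        }
        for (nm in names(refMatrices)) {
            p <- file.path(outDir, sprintf("kmer.%s.tsv", nm))
            writeKmerMatrixTsv(refMatrices[[nm]], p)
            note(p)
        }
        corr <- NULL
        if (length(subMatrices) && length(refMatrices)) {
            corr <- correlationReport(
                subMatrices, refMatrices,
                endsN = config$kmer$ends
            )
            p1 <- file.path(outDir, "kmer.correlations.between.tsv")
            p2 <- file.path(outDir, "kmer.correlations.within.tsv")
            .writeTsv(corr$betweenLibraries, p1)
            .writeTsv(corr$withinLibraries, p2)
            note(c(p1, p2))
        }
        list(
            subLibraries = subMatrices, references = refMatrices,
            correlations = corr
        )
    })

    manifest <- stage("manifest", {
        counts <- lapply(invitro, function(x) {
            c(
                metadata(x)[c("nReads", "droppedAtBoundary")],
                list(invitrosomes = length(x))
            )
        })
        man <- list(
            tool = "invitroRescue",
            version = as.character(packageVersion("invitroRescue")),
            seed = config$seed,
            config = config,
            libraryCounts = counts,
            outputs = data.frame(
                file = basename(files),
                md5 = unname(md5sum(files))
            )
        )
        p <- file.path(outDir, "manifest.json")
        write_json(man, p, auto_unbox = TRUE, digits = NA, force = TRUE)
        man
    })

    invisible(list(
        genome = genome, digests = digests, libraries = libs,
        invitrosomes = invitro, recovery = recovery,
        profiles = profiles, kmers = kmers, manifest = manifest,
        outDir = outDir
    ))
}
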